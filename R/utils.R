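# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Lower median
#'
#' Median using the lower-median convention: for an even number of values the
#' smaller of the two central order statistics is returned, so the result is
#' always an observed value (integer medians stay integers, no interpolation).
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return A length-one value of the same type as `x`, or `NA` when `x` is
#'   empty after `NA` removal.
#' @export
#' @examples
#' lower_median(c(3, 5, 7))   # 5
#' lower_median(c(2, 4, 6, 8)) # 4, not 5
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[[ceiling(n / 2)]]
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed per named stream, kept inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

stop_omopetl <- function(..., class = "omopetl_error") {
  rlang::abort(paste0(...), class = class)
}

# Collapse a set of columns into a single matching key (used for joins,
# deduplication and membership tests). NA prints distinctly from "NA".
tuple_key <- function(df, cols) {
  if (nrow(df) == 0L) return(character(0))
  parts <- lapply(cols, function(cl) {
    v <- df[[cl]]
    out <- as.character(v)
    out[is.na(v)] <- "\r<NA>"
    out
  })
  do.call(paste, c(parts, sep = "\r"))
}

as_date_strict <- function(x, format = "%Y-%m-%d", what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = format)
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0L) {
    stop_omopetl(
      "unparseable ", what, " at row ", bad[[1L]], ": '", x[[bad[[1L]]]], "'",
      class = "omopetl_parse_error"
    )
  }
  out[!is.na(x) & x == ""] <- NA
  out
}
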