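---
title: "Mapping claims data to the OMOP CDM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping claims data to the OMOP CDM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omopetl)
```

## The problem

Claims data collected for accounting — patients, deaths, drug
prescriptions, hospital stays, diagnoses — are a major resource for drug
safety research, but every national source uses its own schema and code
systems. The OMOP Common Data Model standardizes both: a fixed relational
schema and a set of vocabularies in which every clinical fact is keyed to
a *Standard Concept*. `omopetl` implements the full standardization
pipeline for an Austrian-style five-table claims source: vocabulary
mapping, table mapping/ETL into the CDM v6.0 subset such a source can
populate, and a validation protocol that demonstrates the transform lost
nothing. Because real claims extracts and the full vocabulary release are
access-restricted, the package ships seeded generators that emulate the
source's shape at desk scale with known ground truth; every claim the test
suite makes is a property of that stated synthetic world, not a statement
about any real cohort.

## Vocabulary mapping

### The state model

A local code is classified relative to a concept store holding concepts,
`Maps to` / `Concept replaced by` relationships, and vocabularies:

* **S1** if the code occurs verbatim in a *compatible* vocabulary and
  resolves directly to a standard concept — the concept is standard
  itself, or carries a `Maps to` edge to one (the usual situation for
  ICD-10 and ATC entries, which are non-standard concepts mapped to
  SNOMED-like and RxNorm-like standards).
* **S2** if equivalence needs one extra step: a deprecated verbatim
  concept whose `Concept replaced by` chain (followed transitively,
  cycle-safe, breadth-first) reaches a concept that resolves as above —
  the pattern left behind when a code system retires a code in favour of a
  successor — or a *hint*, a manually curated `(local code, standard
  concept)` pair. Hints model the human-in-the-loop USAGI step: fuzzy
  matches are never auto-accepted, a person has to confirm them.
* **S3** otherwise: no equivalent standard concept. S3 codes travel
  through the ETL with concept id 0 and their source value preserved.

One boundary case deserves a note: a code may be present verbatim yet
resolve to nothing directly — a deprecated concept. We deliberately do
*not* call this S1. "Included one-to-one" is read as *currently included*:
presence plus direct resolvability. A deprecated concept is exactly the S2
situation, and its replacement chain (or a hint) decides whether an
equivalent exists at all. This keeps the three states a partition while
matching how vocabulary maintenance actually manifests in the store.

### Vocabulary compatibility and precedence

Local vocabularies are checked against an ordered list of store
vocabularies (`default_vocab_compat()`). Austrian ICD-10 is checked first
against the WHO-style `ICD10` vocabulary, then against `ICD10CM`; the
order encodes precedence for codes present in both — the WHO edition is
the natural parent of the national variant, and most codes match it. Ties
within one vocabulary break by ascending concept id. The map is an
argument, not a constant, so other sources can redefine it.

The local vocabulary ids (`ICD10-BMSG`, `ATC-AT`, `PRN`,
`ProfessionalGroup`, `SEI`) are deliberately distinct from the store
vocabularies they are checked against. Import creates new concepts *under
the local vocabulary id*; keeping the namespaces disjoint preserves the
store's `(vocabulary_id, concept_code)` uniqueness even for S1 codes whose
spelling is identical to the store entry they match.

### Candidate suggestion

`suggest_candidates()` ranks concepts by Jaccard similarity between
character-trigram sets built over the lower-cased, punctuation-stripped
token sets of the query and each concept name (tokens shorter than three
characters contribute themselves). The metric is crude by design — it is a
screen for the manual S2 step, not a decision rule — and has the
properties that matter for reproducibility: a name identical after
normalization scores 1, disjoint names score 0 and are omitted, and the
ranking is a total order (score descending, concept id ascending), so
permuting the store never changes the result.

### Import

`import_local_vocabulary()` turns every S1/S2 assessment into one
non-standard concept with exactly one `Maps to` edge to its resolved
standard concept. Ids are assigned sequentially from the reserved local
range starting at 2,000,000,000 (the OHDSI convention for site-local
concepts), in sorted `(vocabulary_id, code)` order, making ids a pure
function of the assessed set. Codes already present under their local
vocabulary are skipped, which makes the operation idempotent. S3 codes are
reported, never imported: inventing standard concepts is a community
process, not an ETL step.

## The ETL

The transform is staged and deterministic; identical inputs give
byte-identical outputs. Design choices that were genuinely open:

* **Deduplication key.** Duplicate hospital-stay and diagnosis records
  (an artifact of claims accounting) are removed by full field tuple
  excluding the synthetic row key — the minimal reading of "duplicate
  records". A `business_key` mode (person, dates, code; ignoring the stay
  link for diagnoses) exists as a config option for sources where the
  stricter reading is wrong. First occurrence wins, in stable input
  order. When a duplicate stay is removed, diagnoses referencing its key
  are re-pointed to the kept representative before diagnosis
  deduplication; otherwise the removal would orphan them.
* **Observation period.** The source has no enrolment data, so every
  person gets one period spanning the configured study window (default
  2008-01-01 to 2011-12-31), independent of their events.
* **Virtual providers.** Only the prescriber's professional group is
  known, and a CDM provider has exactly one specialty; one provider per
  distinct group reconciles the two without information loss. Provider
  ids follow sorted specialty order; unmapped groups get concept 0.
* **Drug exposure end date.** Not in the source. Set equal to the start
  date — the least-information choice that satisfies the schema's
  `end >= start`, and flagged in the report under defaulted fields.
* **Event date precedence.** A diagnosis carries its own date when the
  source provides one; otherwise it inherits the linked stay's admission
  date. The more specific datum wins.
* **Routing default.** Diagnoses whose code has no standard concept go to
  `condition_occurrence` (configurable): in claims practice an ICD-coded
  fact is a condition unless its concept says otherwise.
* **SEI.** One observation row per patient with an index: concept 0
  (S3), numeric value preserved, dated at the study start because the
  source records no date for it.
* **Zero, not NULL.** Race, ethnicity, provider gender and every unmapped
  concept field carry concept id 0, the CDM's designated "no information"
  concept.

## Validation

Three checks, each exact by construction, aggregated into one verdict:

1. **Count reconciliation** — per table pair, `cdm = source − removed`,
   with the dedup allowance taken from the run's own report. Clinical
   events are counted across all four event tables; SEI observations
   (recognizable by a non-missing `value_as_number`) are excluded from
   the diagnosis pairing.
2. **Record-wise equivalence** — a source-shaped view is reconstructed
   from the CDM's preserved source values (`person_source_value`, the
   stay key in `visit_source_value`, the ICD code in the event source
   values, the PRN in `drug_source_value`, specialty via the provider)
   and compared field-for-field against the deduplicated source. Tables
   with stable keys are joined by key; prescriptions and diagnoses,
   whose row keys are not carried into the CDM, are compared as
   multisets of full field tuples.
3. **Descriptive statistics** — percent female, median age at study
   start, median hospitalizations per person (among persons with ≥ 1
   stay), median prescriptions per person (≥ 1), and median length of
   stay, computed with identical conventions on both sides and required
   to be exactly equal.

Conventions, fixed once and applied to both sides so the comparison is
convention-invariant: the *lower median* (for an even count, the smaller
central order statistic — integer data stay integer, no interpolation);
age referenced at the study period start; length of stay as discharge
minus admission in calendar days (same-day = 0); duplicate stays removed
before counting on *both* sides, since the duplicates are accounting
artifacts rather than clinical facts. Whether per-person medians should
include persons with zero records is ambiguous; both denominators are
computed and reported (`*_incl_zero`), and the headline indicator uses
the ≥ 1 population. An empty cohort yields undefined (`NA`) indicators,
never zeros.

Two known blind spots, accepted and documented rather than papered over:
the ATC code of a prescription is recoverable from the CDM only through
its imported source concept, so for S3 (unimported) ATC codes the
equivalence check cannot compare that one field and restricts the tuple
accordingly; and the SEI *observation row's* value is validated through
the person record that carries the same index, not independently.

## The synthetic world

`generate_source()` draws a cohort whose shape mirrors an elderly claims
extract: ages 70–100 at study start (long-tailed toward the early 70s),
female probability 0.508, death probability 0.15 over the four-year
window, Poisson event counts (means: 20 prescriptions and 2 stays per
patient, 2 diagnoses per stay plus ~1 ambulatory diagnosis per patient),
stay lengths Poisson with mean 5 days, Zipf-distributed code usage over
pools of 50 ICD-10-like, 30 ATC-like and 60 PRN-like codes and 10
professional groups of which 2 are unmappable, SEI missing in 10% and sex
in 2% of patients, and verbatim duplicate stay/diagnosis rows injected at
rate 0.05 each. Scale parameters are desk-scale by intent — a full run
takes under a second — because every validated property (conservation,
equivalence, statistic equality, determinism) is scale-invariant; the
event-frequency means are therefore chosen for runtime, not to reproduce
any real cohort's medians. Accidental duplicates are removed before
injection so the ground-truth duplicate list is exhaustive. All
randomness flows from a single seed through per-table derived
sub-streams.

`generate_vocabulary_fixture()` builds a store in which the ground-truth
state of every local code is known: configurable S1/S2/S3 fractions for
the ICD and ATC pools (S2 realized as deprecated concepts with
`Concept replaced by` successors), a seeded minority of ICD codes present
only in the CM-like vocabulary, hints for all mappable professional
groups and half the PRNs, nothing for SEI, plus the inpatient-visit and
gender concepts the ETL configuration references.

What a green test establishes: the pipeline's algebra — classification
semantics, conservation, reconstruction, determinism — on data with the
stated shape. What it does not establish: fidelity to real Austrian
coding practice (no clinical drug–diagnosis correlation, no real
vocabulary content, uniform dates rather than seasonal patterns), and no
statement about the mapping coverage of any real vocabulary release.

## Numerical and degenerate-input choices

Dates are ISO-8601 throughout; `death_datetime` is the death date at
midnight UTC. Ids are integers assigned sequentially in deterministic
source order. Empty inputs are first-class: five empty tables transform
to an empty, valid CDM with an all-zero report. Classification of an
empty code, an empty candidate-search term, an S2 assessment without a
standard concept, a referential violation, or an unparseable date are
errors that name the offender; equivalence checking, by contrast, never
errors on discrepant data — discrepancies are its output.

## Limitations

Beyond the validation blind spots above: the package does not model
costs, care sites, locations or eras; SNOMED-level semantic mapping of S3
vocabularies is out of scope (a community effort, not a tool feature);
and the `business_key` dedup mode is provided without a claim about which
key real accounting systems duplicate on. The concept-store reader
expects Athena-style tab-separated files and ignores validity-date
columns — temporal vocabulary versioning is not modelled beyond the
`Concept replaced by` chains themselves.
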