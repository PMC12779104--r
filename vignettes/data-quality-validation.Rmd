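---
title: "Dynamic data-quality validation of integrated patient records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic data-quality validation of integrated patient records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgqc)
```

## The problem

Health data reach secondary use through a pipeline: source tables are
standardized, mapped to a graph representation, and merged patient by
patient into a longitudinal record. Quality defects — missing fields,
transposed dates, demographically impossible codes — can be introduced or
exposed at any of these steps, and a single end-of-pipeline audit cannot
say *where*. `kgqc` models the middle of that pipeline (source-graph
construction and integration into a per-patient knowledge graph) and
applies declarative validation rules after every integration step, so
quality can be tracked as a trajectory rather than a snapshot.

Because real critical-care datasets are access-controlled, the package is
built around a synthetic cohort generator: all experiments run on data
whose every defect was planted deliberately and recorded in a ledger.

## Data model

Four tables mirror the core of a critical-care relational schema:
`PATIENTS` (gender as a terminology code, birth date), `ADMISSIONS`
(admission/discharge timestamps and locations), `CPTEVENTS` (procedure
code and chart date), `DIAGNOSES_ICD` (diagnosis code). All timestamps use
the ISO 8601 profile `YYYY-MM-DDThh:mm:ss+zz:zz`; the empty string is the
missing sentinel. Keys (`SUBJECT_ID`, `HADM_ID`) are structural and never
corrupted, which keeps referential integrity intact under any noise
setting and makes runs comparable.

The mini reference ontology has four classes connected through
`Admission` — `Patient`, `Admission`, `Procedure`, `Diagnosis` — one typed
datatype property per table column (`dateTime`, `code` or `text`) and two
object properties (`ofPatient`, `ofAdmission`). Mapping emits one node per
row, one triple per non-missing cell, and type/link triples derived from
keys. Two deliberate choices:

* **Invalid date strings survive mapping** as *untyped* literals instead of
  being rejected at parse time. A transposed date like `2103-25-03` is
  exactly what the datatype rule category exists to find; rejecting it at
  the boundary would blind the validator.
* **Age is never stored.** It is derived at validation time as completed
  years between birth date and the admission time of the event under
  scrutiny (falling back to the procedure's chart date when the admission
  time is missing or unparseable). Storing age would create an update
  anomaly and hide birth-date corruption.

## The noise model

Corruption is controlled by two proportions. With `n` eligible cells
(every non-key cell), `round(noise_level * n)` cells are altered;
`round(completeness_ratio * altered)` of those are deleted and the rest
made inconsistent. Rounding is half-away-from-zero, applied to the altered
count first. Selection is uniform without replacement from a single seeded
permutation, which has a useful side effect: at a fixed seed and noise
level the deletion sets are *nested* across completeness ratios, so
essential completeness is provably non-increasing in the ratio — a
property the test suite exercises.

The inconsistency operator is dispatched by the targeted column:

| column | operator |
|---|---|
| `GENDER` | swap of the two gender codes |
| `DOB` | move to a different age group |
| `ADMITTIME`, `DISCHTIME` | admit/discharge swap or day/month transposition (fair coin) |
| `CHARTDATE` | day/month transposition |
| `CPT_CD`, `ICD9_CODE` | uniform substitution from the ruleset |
| locations | uniform substitution from the location vocabulary |

Notes on the operators:

* The gender swap is a single categorical draw between the two codes with
  equal probability; the age alteration is a single categorical draw over
  the remaining age groups ([0,1), [1,12), [12,56), [56,124]) weighted by
  their empirical frequency in the dataset, renormalized after excluding
  the patient's current group, with the new age uniform within the chosen
  group. (Stated distributions over a binary and a four-way choice are
  implemented as single draws.)
* The day/month transposition is *textual* and never re-parsed; months
  above 12 are the detectable case, transpositions of symmetric dates are
  ledgered fixed points, and day/month pairs both ≤ 12 yield valid but
  chronologically shifted dates that may or may not be detectable.
* The admit/discharge swap touches two cells for one target; both cells
  are ledgered, with a `targeted` flag marking the selected one, so the
  invariant "every changed cell has a ledger entry" holds exactly.
* Location cells have no constraining rule, so their substitution is
  benign by construction; it exists so that the altered-cell count is
  exact under uniform cell selection.

Deletion simply blanks the targeted cell. Because targets are uniform over
each table's non-key cells, the per-field deletion shares inside a table
follow its cell layout: half/half for `PATIENTS` and `CPTEVENTS`, a
quarter each for the four `ADMISSIONS` fields, and always the code for
`DIAGNOSES_ICD` — the acceptance script measures these shares empirically.

Targets are disjoint cells: one cell receives at most one operation per
run, though a row may receive several on different cells. The ledger
records table, row, key, field, kind (`missing`/`inconsistent`), operator
and the before/after values; it is the oracle every detection metric is
scored against.

## Rule categories and scoring

Shapes are compiled from two inputs: the ontology (mandatory properties,
typed properties, temporal relations) and a table of code constraints,
each code carrying its allowed genders and an inclusive age interval in
completed years. Gender compatibility expands to one shape per (code,
allowed gender) pairing; age compatibility to one shape per code. The
bundled mini rulesets (20 diagnosis, 15 procedure codes, including
gender-specific and age-specific entries of both kinds) keep the same
structure as production-scale shape libraries at toy size. The two
bundled gender codes are SNOMED CT 248153007/248152002; the field is an
open code string, so other codes pass format checks.

The engine evaluates shapes as set logic over the triple store — min-count,
datatype conformance, pairwise temporal comparison, conditional
implication, set membership — and rolls violations up to admissions: an
admission violating any shape of a category counts once there. Scores are
`1 − violations/checked`. The checked denominator is the full admission
roster for essential/conditional completeness, datatype and time-sequence
rules; for the four code-demographic categories it is the set of
admissions that actually carry at least one relevant code *and* the
demographic the rule needs (a recorded gender, or a computable age). Three
boundary rules prevent double counting and spurious perfection:

* temporal comparisons are skipped when an operand is missing or
  unparseable — the datatype category owns unparseable values;
* an admission whose birth date is missing drops out of the age
  categories' checked sets (the gap surfaces under completeness instead);
* a category with zero checkable admissions reports `N/A`, never a perfect
  score. Conditional completeness is `N/A` by design at every stage before
  the last, since its cross-source dependency (a recorded diagnosis
  requires a recorded gender) cannot be meaningfully evaluated earlier.

Percentages are rendered with truncation toward zero at two decimals
(13,593/13,607 prints as 99.89%), centralized in `format_percent()`.
Truncation versus rounding is ambiguous at one printed cell of the
reference output; tests accept either within ±0.01 percentage points.

## Observability and detection metrics

Not every injected inconsistency is detectable: a substituted code may be
compatible with the patient anyway, a transposed symmetric date is a
no-op, and deleting the gender field afterwards removes the evidence a
gender swap would need. `check_observability()` classifies each ledgered
inconsistency by intersecting the operator's sphere of influence (which
categories it can perturb, at which admissions) with the frame-level
violation predicates shared with the engine; fixed points are never
observable. `verify_against_ledger()` then reports per-category recall on
observable errors and the precision of violations against the ledger. The
structural check that the *engine itself* is right is separate: the test
suite contains an independent brute-force evaluator (nested loops applying
each constraint literally to raw triples) and requires set-identical
violations across one hundred seeded corrupted cohorts.

## Synthetic-data realism and limits

The generator draws gender uniformly, age groups from configurable weights
(defaults 5/10/55/30% for infants/children/adults/seniors, a plausible
inpatient mix), shifted-Poisson counts for admissions, procedures and
diagnoses per entity (means 1.6/1.8/2.2 by default — the reference cohort's
distributions are not published, so these are exposed as configuration
rather than fixed), admission episodes of 1–30 days separated by 30–400
day gaps in the years 2100–2120 (echoing the shifted-era feel of
deidentified critical-care data while keeping age arithmetic meaningful),
and codes sampled only from demographically compatible entries, so every
admission retains at least one diagnosis and one procedure — the
inclusion criterion applied to the source data ("admissions lacking
relevant diagnosis or procedure codes are excluded") holds by
construction, and `apply_inclusion_filter()` re-imposes it on arbitrary
input.

What passing tests on this cohort do *not* show: real EHR noise is not
uniform at cell level (missingness is context-dependent, errors are
human-biased and correlated), disease co-occurrence is not modelled,
free-text fields and the long tail of real code vocabularies are absent.
The package measures a validation framework's mechanics under a
controlled error model, not the error epidemiology of any hospital.

## Numerical and design choices

* One top-level seed fans out into labelled substream seeds
  (`derive_seed()`), so extending an experiment grid does not reshuffle
  unrelated draws; generation, target selection and operator draws are
  separate streams.
* Source knowledge graphs are kept per patient per source; per-patient
  graphs are disjoint, so validation parallelizes trivially and the test
  suite checks that pooling per-patient validations in reversed patient
  order reproduces the whole-cohort result.
* IRIs are minted deterministically from table keys (event nodes numbered
  by order of appearance within their admission), making graphs
  comparable across runs; Turtle output is sorted, hence byte-stable.
* The admission roster (derived from key columns, which are never
  corrupted) supplies the scoring denominator even at stages where
  `ADMISSIONS` is not yet integrated.
* Each experiment grid cell corrupts the cohort once and reuses the same
  corrupted tables for every integration order, so order-invariance
  claims compare identical inputs; the final integrated graph is
  set-identical across orders, which makes final-stage scores exactly
  equal rather than approximately so.
* Degenerate inputs: empty tables yield empty selections, graphs and
  reports rather than errors; an age partition with fewer than two groups
  or a substitution pool with fewer than two codes is a hard error; a
  failing experiment cell is caught and reported without aborting the
  grid.

## Problem sizes

The test suite validates staged pipelines at up to 200 patients
(≈ 300 admissions, ≈ 1,800 graph-mapped rows), runs the engine-versus-oracle
equivalence at 6 patients × 100 seeds, and the distributional checks of
the operators at 10,000 draws; the acceptance script measures deletion
shares over ≈ 12,000 admission rows. These sizes were chosen so the whole
cycle runs on a laptop in about a minute while keeping every empirical
check well inside its statistical tolerance.

## Known limitations

The conditional-completeness category is represented by a single
dependency shape (diagnosis ⇒ gender); production deployments would carry
many. The Turtle reader covers the subset the writer emits, not arbitrary
RDF. The engine deduplicates at admission level, so per-violation-instance
counts within a category are not reported. Timeliness and uniqueness
dimensions are out of scope, as is any repair or curation of flagged
records.
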