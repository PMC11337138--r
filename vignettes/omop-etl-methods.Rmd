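---
title: "Methods: standardizing primary care EHR exports into the OMOP CDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardizing primary care EHR exports into the OMOP CDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omopetl)
```

## The problem

Primary-care patient-monitoring software accumulates years of consultations,
prescriptions, laboratory results and free-text observations in
vendor-specific structures and local vocabularies. Reusing these data for
audit or observational research requires standardizing both the *structure*
(tables and columns) and the *semantics* (codes and labels) into a common
data model. This package implements that standardization for a source that
exports one hierarchical XML document per patient — the shape used by French
primary-care EHRs — targeting a 15-table subset of the OMOP CDM v5.4
(12 clinical/administrative tables plus CONCEPT, CONCEPT_RELATIONSHIP and
VOCABULARY).

The source model it expects is a multidisciplinary health center where a
consultation unfolds in four steps: a free-text reason for the visit, a
free-text interview, structured biometric measurements (label, value, unit
typed by the physician), and an outcome carrying an optional free-text
diagnosis, CIP-coded drug prescriptions with dosage attributes, and optional
referral/vaccination notes. Laboratory results arrive from external
laboratories that each use their own variable spellings and units; medical
histories are partly ICD-10-coded and mostly free text.

Because no such export can be published, the package ships a synthetic
generator that emulates the source, together with a ground-truth manifest.
Every downstream stage is tested against that manifest.

## Semantic mapping

Local vocabulary items are classified into four mapping difficulty levels:

1. the item's code already is a standard concept (e.g. ICD-10 history
   codes in the bundled vocabulary);
2. the item is non-standard but a mapping to the standard vocabulary
   pre-exists (e.g. ATC codes with ATC-to-RxNorm links);
3. the item is structured but unmapped — manual annotation is required
   (laboratory labels to LOINC, biometric labels to SNOMED, units to UCUM,
   sex values, CIP codes);
4. the item is free text, out of mapping scope; it is preserved verbatim in
   NOTE rather than coded.

### Label normalization

Laboratory and biometric labels are cleaned before matching, in a fixed
order: leading chapter/line numbers are stripped; punctuation and special
characters are removed (intra-word hyphens are kept, so expanded names such
as "c-reactive protein" survive re-normalization); abbreviations are
expanded against a dictionary (whole-token, case-insensitive, longest key
first — `CRP` becomes `C-reactive protein`); text is case-folded; stop
words are removed; whitespace is collapsed. The number-stripping rule is
re-applied wherever an earlier step can expose a new leading number, which
makes the whole function idempotent — a property the test suite checks on
random noise. The default stop-word list contains French/English filler
words *and* unit tokens, because units travel in their own field in this
source; both the dictionary and the stop-word list are plain configuration
arguments and can be replaced per site.

### Drug mapping

CIP presentation codes map in two hops: CIP to its ATC parent, then ATC to
RxNorm using pre-existing links. The result records both hops; a missing
hop leaves the prescription unmapped (concept 0) with the CIP code
preserved in `drug_source_value`. The bundled vocabulary fixture includes
20 CIP codes of which 17 have complete chains, so tests exercise both
outcomes.

### Dual annotation and agreement

Level 2/3 items are annotated by two annotators and reconciled: agreement
fixes the consensus, disagreement is settled by a third adjudicator and
flagged. Agreement is quantified with Cohen's unweighted kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$, where $p_o$ is the observed agreement and
$p_e = \sum_c p^A_c\, p^B_c$ the chance agreement from the annotators'
marginals. The implementation returns the statistic's true range
$[-1, 1]$; reporting conventions that clip at 0 are left to the caller.
$\kappa$ is defined as 1 in the degenerate all-identical single-category
case. A brute-force contingency-table computation and an independent
library implementation serve as oracles in the tests.

For a pipeline that runs end to end without humans, `annotate_ledger()`
emulates the two annotators deterministically: annotator A matches the
normalized label exactly (order-insensitive on tokens) against normalized
standard concept names of the feature's target vocabulary; annotator B
takes the best fuzzy candidate at 0.85 normalized edit similarity.
Disagreements are adjudicated in favour of the exact match. The fuzzy
helper only ever *proposes* candidates; nothing is auto-accepted below the
exact-match bar without the (emulated) adjudication step.

Every structured item additionally registers a *local* concept with an
identifier strictly greater than 2,000,000,000, allocated from a monotonic
sequence; re-registering an identical (label, vocabulary, domain) triple
returns the existing concept. Standard and local identifier ranges never
overlap, and every "Maps to" link crosses from a local concept to a
standard one — both enforced by the store and asserted in tests.

### Coverage reporting

Concept and record coverage is reported per (feature, source vocabulary)
as n/N with a percentage rounded to one decimal, **half away from zero**
(base R's `round()` rounds half to even, which would mis-reproduce ratios
such as 91.45 → 91.5). Level-4 rows carry no fractions.

## Structural mapping

Each consultation becomes one VISIT_OCCURRENCE row with visit concept
38004247 (Ambulatory Primary Care Clinic/Center) and start = end date:
primary-care visits are single-day. Biometrics and laboratory results both
land in MEASUREMENT, typed "from physical examination" (44818701) and Lab
(32856) respectively; an added `measurement_source_type_id` column records
which source table a row came from. Prescriptions become DRUG_EXPOSURE
rows; free text (reason, interview, diagnosis, referral, vaccination,
supplementary information, free-text histories, external clinical reports)
becomes NOTE rows whose note-class concept encodes provenance; ICD-10-coded
histories become OBSERVATION rows. Unmapped items load as concept 0 with
the raw string in the `*_source_value` column — they feed the completeness
checks instead of being dropped.

All primary keys are fresh sequential integers from per-table sequences;
source identifiers survive only in `*_source_value` columns. The patient's
registration with a family physician has no native CDM field, so it is
materialized as a dated OBSERVATION row with a registered local concept;
this gives the validation queries' registration-cutoff rule a
warehouse-side counterpart.

### Derived tables

**OBSERVATION_PERIOD** is the `[min, max]` span of each person's dated
events (visits, measurements, drug exposures, notes, observations); a
person without dated events gets no period. **DRUG_ERA** follows the OHDSI
convention: exposures are resolved to ingredient level through
"RxNorm has ingredient" links (a combination product contributes to one
era stream per ingredient, so eras can outnumber exposures; a concept
without ingredient links stands for itself), then merged greedily per
(person, ingredient) in start-date order whenever the next exposure starts
on or before the running era end plus a persistence window. The window
defaults to 30 days and is configurable; the exposure end date defaults to
start + days_supply − 1 when a days' supply is present, else the start
date. Uncovered days inside an era accumulate in `gap_days`; exposures
ending before they start are excluded and logged. A brute-force
interval-union oracle (union-find over the pairwise
"starts within reach" relation, whose transitive closure equals the greedy
partition) checks the derivation on thousands of randomized instances.

### Outlier filtering

Plausibility ranges (per standard measurement concept, in the unit the
source reports) can be applied at transform time, excluding out-of-range
values into an itemized rejection log so that every row drop is
attributable (`rows_in = rows_out + rejections`, asserted exactly). The
same ranges drive the quality layer's range check, which judges whatever
was actually loaded — so a warehouse built *without* the transform-time
filter still surfaces implausible values as check failures.

## The warehouse

The environment this package targets has no relational database driver, so
the warehouse is a schema-validating tabular store implemented in the
package: typed empty tables materialized from the schema definition,
enforcement of required columns, primary-key uniqueness and foreign-key
resolution at load time, itemized rejections, per-table load timing, and
CSV-per-table persistence. Creating a store over a non-empty directory is
an explicit error. Load order is fixed (vocabulary, administrative tables,
visits, event tables, derived tables), and loading a clinical table before
the vocabulary is an ordering error. A test cross-checks the validator's
verdicts against a real relational engine (sqlite with foreign keys
enabled) on defective fixtures.

## Quality assessment

Checks live in a data-driven registry grouped into the three Kahn
categories, run in a Verification context: Conformance (key uniqueness,
referential integrity, required fields, concept-domain agreement, the
visit-concept rule), Completeness (unmapped-concept fractions, missing
demographics and dates) and Plausibility (value ranges, birth-year bounds,
events after death, events after the extraction date, exposure
chronology). Every check reports exact violating counts over totals and a
sample of offending keys. The default severity threshold is 0 — any
violation fails the check — and the post-death grace period defaults to 0
days; both are configurable, since neither has a canonical value. An empty
warehouse passes everything vacuously with totals of 0.

The defect model is a closed set of five kinds the generator can inject
(event after death, out-of-range value, implausible birth year, dangling
visit reference, missing required field). The suite asserts 100% recall —
each kind trips at least one corresponding check with a violating count
that equals a manifest-based recount — and zero false alarms on clean
builds. One known cascade is intentional: re-dating a consultation past a
death near the end of the observation window can also push it past the
extraction date, so the post-death injection may additionally trip the
extraction-date check.

## Validation queries and dashboard

Five parameterized queries compare warehouse answers with ground truth:
registered patients per physician (registrations after the cutoff
excluded), consultations per period, patients exposed to each of two drug
ingredients in a period, and patients with a laboratory value above a
threshold in a period. The concrete defaults (metformin, amoxicillin,
potassium > 5 mmol/L) are chosen to keep result sets small and
hand-checkable; the laboratory query uses an analyte whose configured
variants share one unit, so the threshold is well-defined. Mismatches in
the concordance report carry a mandatory explanation slot; the tests
exercise both the all-match case and an explained mismatch (outliers
removed by the transform-time filter that the source still counts).
The dashboard export produces three datasets — activity per physician per
year, exposures per ATC class per year, and a distribution summary per
laboratory concept — as CSV and JSON; any front end is a consumer of these
files, not part of the tested surface.

## The synthetic generator

The generator emulates the *statistics* of a two-decade primary-care
warehouse, scaled to the requested patient count: 32.2 consultations per
patient (Poisson), 1.56 prescriptions per consultation, biometrics at
roughly 0.3 records per consultation, ~8.5 laboratory panels per patient,
a 3.6% coded-history rate, a 2.3% death rate, 8 physicians, and a
2013-01-01 to 2021-06-30 window. Rates without an obvious source-side
analogue (referral 10%, vaccination 5%, diagnosis 50%, interview
missingness 10%, town missingness 5%) were fixed once at values a
practice-based dataset would plausibly show. Laboratory heterogeneity is
modelled by assigning each patient one of three laboratories, each with a
fixed spelling/unit variant per analyte; values are normal draws per
variant (potassium 4.2 ± 0.4 mmol/L, creatinine 80 ± 15 umol/L or
9 ± 1.7 mg/L depending on the reporting laboratory, and so on). Events are
capped at the death date and birth years are drawn no later than the
registration year, so defect-free builds are chronologically clean by
construction — implausible chronology only ever enters through the defect
model.

Free-text fields are template-drawn French snippets. They exist to be
stored in NOTE and counted, not to be parsed: passing tests demonstrate
count conservation, routing and provenance coding, *not* any ability to
extract meaning from clinical narrative. Real exports would additionally
contain misspellings beyond the configured variants, physicians who merge
all four consultation steps into one field, richer address churn, and
free-text volumes an order of magnitude larger — none of which the
generator reproduces, and results on synthetic data should be read with
that in mind.

Determinism is a contract: identical configuration and seed yield
byte-identical documents and manifest, which is why the writer serializes
XML through fixed templates with explicit number formatting (parsing uses
a standard XML library). The manifest carries exact counts, per-physician
registration counts, per-patient event-date extents, relational truth
tables for the five queries, and the list of injected defects with their
locations.

## Numerical and degenerate-input choices

- Percentages: one decimal, half away from zero (see above).
- Identifier sequences: per-table, starting at 1, never reused; local
  concept ids start at 2,000,000,001.
- Tie-breaks: era merging sorts by (start, end); equal starts merge into
  one era for any window ≥ 0. Exact duplicate consultation identifiers
  keep the first occurrence.
- Dates: ISO calendar dates throughout; unparseable staging dates are kept
  raw with a validity flag and surface as completeness failures, not
  extraction errors.
- Degenerate inputs: zero-activity patients produce a document with empty
  sections and no observation period; an empty warehouse passes all checks
  with totals 0 and exports empty, headered dashboard datasets; an empty
  normalized label is allowed and flagged by the caller.
- Kappa: `p_e = 1` with perfect agreement returns 1.

## Problem sizes in the shipped tests

The suite runs the full chain at 500 synthetic patients (~16,000
consultations, ~29,000 measurements, ~25,000 exposures) for the end-to-end
recovery check, 30-40 patients for the shared pipeline fixtures, 1,000
randomized era instances across four persistence windows, 500 randomized
kappa instances plus a 10,000-pair chance-level simulation, and
1,000-patient visit-free exports for missingness calibration. These sizes
were chosen so the whole suite exercises every contract at full depth in a
few minutes on one core.

## Known limitations

- Level-4 free text is stored, never interpreted; no NLP is attempted.
- The bundled vocabularies are small synthetic stand-ins with OMOP column
  shapes, sufficient for the mapping logic but not clinical content; a
  deployment would load the real OHDSI vocabulary distribution through the
  same fixture interface.
- The warehouse is file-backed and in-memory; it validates constraints
  itself rather than delegating to a database server.
- CONDITION_OCCURRENCE and PROCEDURE_OCCURRENCE are not populated: in this
  source, diagnoses live in free text and are routed to NOTE.
- The deterministic annotator emulation is a stand-in for human experts;
  on real labels its exact-match arm would leave far more level-3 items
  unmapped, which is the expected behaviour (they become local concepts
  with concept 0 standard mappings), not a failure mode.
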