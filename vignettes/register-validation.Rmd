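---
title: "Constructing and validating EMR-derived patient registers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating EMR-derived patient registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Primary-care electronic medical records (EMRs) hold structured modules
(diagnoses, prescriptions, laboratory analyses, contacts, biometrics,
documents, measurements) and narrative journal text filed under
subheadings. Research registers are built from such stores in two steps:
**case finding** (step 1), which scans the structured modules for patients
meeting at least one inclusion criterion and assigns each included record a
personal identification number (PIN), and **extraction** (step 2), which
materializes selected data for those PINs into a nine-table register, one
table per source module.

An extraction tool is only as credible as its validation. `registerforge`
implements both the construction machinery and the validation protocol used
to audit it: diagnostic accuracy of the case finding against a reference
extraction, and an item-level *congruity* audit of the extracted data
against the source records on a stratified random sample of PINs.

## Case definition

The worked case definition is type 2 diabetes mellitus (T2DM), expressed as
three criterion families, any one of which suffices for inclusion:

* **Diagnosis**: version-qualified ICD code prefixes. Defaults: ICD-10
  `E11`, ICD-9 `250`. The code vocabularies are fixed by the criterion; the
  concrete prefixes are configuration, since T2DM coding practice varies by
  site.
* **Prescription**: ATC code prefixes. Default `A10B`, the oral
  blood-glucose-lowering drugs.
* **Laboratory**: threshold rules on fasting glucose. Defaults follow the
  WHO 1999 diabetes classification: fasting plasma glucose >= 7.0 mmol/L or
  fasting whole-blood glucose >= 6.1 mmol/L, comparator `>=`, fasting status
  required as an explicit flag on the entry. A single qualifying value
  suffices; no confirmatory repeat is required. Entries whose unit differs
  from the rule's are skipped with a warning rather than silently compared.

Code matching is case-insensitive and whitespace-trimmed throughout.

## Soft deletion, and why it matters

In the source system a caregiver can delete an entry, which hides it from
the normal record view while it stays physically stored. Tools differ in
whether they see such entries, and `inclusion_criteria()` therefore carries
a `deletion_mode`:

* `deletion_blind` — deleted entries still count (a tool reading the
  physical store);
* `deletion_aware` — deleted entries are ignored (the EMR's own integrated
  search engine).

Because the blind view is a superset of the aware view, the blind caseset
always contains the aware caseset; the difference is exactly the patients
whose only qualifying entries are deleted. The same mechanism surfaces in
the congruity audit: a deletion-blind extraction emits register items that
a reviewer cannot find in the normal source view (*extraction-only* items)
until deleted data are consulted with administrator access.

## The validation protocol

**Diagnostic accuracy.** Two casesets over the same population of
`n_total` persons are compared as a 2x2 confusion matrix with the reference
treated as truth: `tp = |test ∩ ref|`, `fp = |test \\ ref|`,
`fn = |ref \\ test|`, `tn = n_total − tp − fp − fn`, from which
sensitivity, specificity, positive and negative predictive value are exact
ratios. We report raw proportions and percentages rounded half-up to one
decimal (plain `round()` rounds half to even, which does not match how such
tables are conventionally printed).

**Stratified audit sampling.** For each criterion in a configured order
(default diagnosis, laboratory, prescription), the criterion's PINs are
shuffled with a seeded RNG; each PIN is assigned to the calendar period
containing its *first qualifying event* (default periods 1993–1997,
1998–2001, 2002–2005); the first 7 per period are taken; and all previously
selected PINs are excluded before the next criterion step, so no PIN is
audited twice. With sufficient strata this yields 63 distinct PINs, 21 per
criterion. Period assignment by first qualifying event is one of two
defensible readings of such a design; the alternative — auditing only the
items dated within the assigned period — is available via
`sampling_plan(restrict_to_period = TRUE)`, with the first reading as the
default because it audits each sampled patient's full register.

**Congruity.** Every register row of a sampled PIN is one *item* (the
patient's static row included — each sampled patient contributes data to
all nine tables). Each item is located in the source by its deterministic
identifier (module, PIN, date, within-day ordinal) and classified by
*occurrence* and *coherence*: `matched` when a non-deleted source entry
with equal field values exists (equality after whitespace and number
normalization), `source_only` when the entry exists but a field differs
(the diff is recorded), `extraction_only` when the item is only locatable
among deleted entries or not at all. The congruity rate is
`matched / compared`; the post-audit rate re-matches extraction-only items
against deleted source entries, reproducing a review that gains access to
deleted data.

## The synthetic EMR generator

No real patient data ship with the package; every analysis runs on
generated stores. `synth_config()` defaults describe the study conditions
the package targets:

* 10,753 patient records opened 1993–2005; true-case prevalence 4%.
* Per-case documentation probabilities for the three criterion signatures,
  calibrated by `calibrate_documentation_probs()` so the expected marginal
  fractions among *detected* cases are 53% (diagnosis), 38% (prescription)
  and 91% (laboratory). With independent documentation this is the fixed
  point `p_i = m_i (1 − q)`, `q = prod(1 − p_i)`, giving approximately
  0.509 / 0.365 / 0.875; about 3.9% of true cases then carry no signature
  at all and are undetectable by design, which is the realistic situation
  for structured-data case finding.
* Glucose model: detected hyperglycaemia lognormal with median 9 mmol/L
  (sdlog 0.3; planted laboratory signatures are truncated above the plasma
  threshold so a documented signature always qualifies); normoglycaemia
  centred at 5 mmol/L plasma / 4.5 mmol/L whole blood with sdlog 0.09,
  keeping threshold exceedance among non-cases below 0.1%. No distributional
  claim is inherited from any study; these are modelling choices that make
  signature planting controllable, and all parameters are configurable.
* Background event rates per patient-year (contacts 1.0, diagnoses 0.35,
  prescriptions 0.40, laboratory analyses 0.35, and smaller rates for the
  remaining modules) chosen as plausible primary-care volumes; they shape
  runtime and audit item counts, not case finding.
* Soft-deletion phenomena: each non-case carries an oral antidiabetic
  prescription destined for deletion with probability 0.0012 (about 12 per
  10,300 non-cases — inaccurate entries later removed by a caregiver), and
  each contact entry is deleted with probability 0.01. Both accept exact
  quotas for reproducing known deletion counts.
* One derived RNG stream per generation stage (patients, truth, events,
  signatures, deletions), so toggling deletion injection does not perturb
  the rest of the store, and identical configuration gives byte-identical
  on-disk output.

What the generator does **not** emulate: realistic narrative language
(template sentences only), coding-practice drift over time, within-patient
clinical correlation beyond the case/non-case distinction, record closure
(all patients remain observable over the whole period), and ICD/ATC
catalogues beyond the handful of codes the criteria touch. Tests passing on
this generator therefore demonstrate the *mechanics* of extraction and
validation — set semantics, deletion handling, exact bookkeeping — not
performance on real clinical data.

## Exact fixtures

Three deterministic constructions complement the stochastic generator:

* `generate_fixture_from_marginals()` builds a population on which case
  finding returns an exact union size and per-criterion marginals. The
  seven Venn region counts are solved by `solve_venn_regions()`: every
  member first receives one membership (criteria filled in order up to
  their marginals), then remaining memberships are stacked onto members
  lacking them. This is feasible precisely when each marginal is at most
  the union and the marginal sum is at least the union; infeasible requests
  error. Explicit region counts can be supplied instead and are
  cross-checked.
* `generate_study_fixture()` reproduces a validated extraction's full
  efficacy geometry: 433 reference cases with marginals 231/161/404 found
  in both deletion modes, plus 12 patients whose only qualifying entries
  are soft-deleted — split 3 deleted diagnoses / 8 deleted prescriptions /
  1 deleted laboratory value so that the blind-mode marginals come out at
  exactly 234/169/405 — inside a population of 10,753. The split across
  entry types is forced by requiring both marginal sets simultaneously;
  deleted prescriptions remain the dominant mechanism.
* `generate_congruity_fixture()` makes the audit sample seed-invariant:
  three mutually exclusive criterion groups of 21 patients, 7 per period,
  so every (criterion, period) stratum holds exactly the stratum quota and
  the sampler must select all 63 PINs at any seed. Per-group register item
  totals are exact by construction (defaults 1,060 / 1,216 / 769 = 3,045),
  achieved by distributing each group's total over its patients with fixed
  small allocations per module and contacts absorbing the remainder; 13
  contact entries are soft-deleted. Exact item totals require
  seed-invariant sampling, which is why the congruity replication runs on
  its own fixture rather than inside the efficacy population. Background
  glucose values in this fixture are recorded as non-fasting so that no
  patient can stray into a second criterion group.

## Numerical and degenerate-input choices

* Percent rounding: half-up to one decimal (`pct1()`), applied only at the
  reporting boundary; all internal comparisons use exact ratios.
* Date sorting in registers is stable: ties keep source order.
* A zero-patient run produces an empty but valid report (prevalence is
  reported as missing rather than dividing by zero).
* Stratum shortfalls in sampling warn and return a partial sample, never
  silently pad.
* `validate_database()` returns violations as data rather than raising, so
  an audit enumerates every problem.
* Databases are fingerprinted (content hash) and a register extraction
  refuses a caseset computed on different content.

## Problem sizes in the test suite

The suite exercises the oracle comparisons on small randomized databases
(8 patients, dozens of entries; 25–30 seeds), the deletion-mode
monotonicity property on 3,000 randomized databases, the 63-PIN sampling
invariant on 1,000 seeds, and generator calibration at the full 10,753
patients — sizes chosen to give the properties real coverage while keeping
a default test run comfortable on a laptop.

## Limitations

* Case finding searches structured data only; narrative text is extracted
  (step 2) but never used for inclusion.
* The congruity audit counts every register row as one item; a study that
  counted field groups differently would shift the absolute item counts but
  not the classification logic.
* The reference extraction in the accuracy comparison is itself a tool
  (the deletion-aware view), not clinical truth; with the synthetic
  generator, ground truth is available separately for simulation studies.
* No confidence intervals are attached to the reported proportions; the
  protocol reports point estimates.
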