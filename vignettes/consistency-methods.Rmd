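---
title: "Methods: classifying and modelling consistency of repeated lifetime IPV reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and modelling consistency of repeated lifetime IPV reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipvconsist)
```

## The problem

A lifetime survey item — *"Have you ever been in a violent relationship
with a partner/spouse?"* — admits only one truthful trajectory: once the
answer is *yes* it must stay *yes*. When the item is asked at six waves
(1996, 2004, 2007, 2010, 2013, 2016), a *no* that follows an earlier *yes*
is therefore evidence of misreporting at one wave or the other, and the
pattern of such reversals across a cohort says something about how reliable
single cross-sectional prevalence estimates can be. This package implements
the full analysis chain for that question: sequence classification,
covariate derivation, descriptive tables, a multinomial regression, and a
generative model that makes the misreporting mechanism explicit.

## The classification rule and its edge cases

Eligibility requires an answer at wave 1 and at least two of waves 2–6
(hence at least three answers). Classification looks only at the answered
subsequence `r` (length `n`, `y` YES answers); a *drop* is a YES occurring
before a later NO (equivalently: first YES position < last NO position).

* no drop — `y = n` → Consistent IPV; `y = 0` → Consistent never IPV;
  otherwise → Consistent later IPV;
* drop — `y = n − 1` → Mainly IPV; `y = 1` → Mainly no IPV; otherwise →
  Mixed IPV.

Three boundary decisions deserve explanation because the verbal definitions
of the classes are not quite a partition:

1. **Monotone sequences are always consistent.** `NYY` has exactly one NO,
   which a literal "all but one survey" reading would call Mainly IPV; but
   a NO *before* the first YES contradicts nothing, and the canonical
   examples for *Consistent later IPV* include exactly such sequences. The
   rule therefore checks for a drop first.
2. **`YYN` is Mainly IPV, not Mixed.** The sequence appears in both example
   lists in the source material; we treat the Mixed listing as a
   typographical slip, because `YYN` satisfies "IPV at all but one survey"
   exactly and Mixed is reserved for the residual class. This is the only
   genuine contradiction in the verbal rule; the enumeration oracle
   (`enumerate_class_counts()`) verifies that the implemented rule is a
   partition either way.
3. **`NYN` is Mainly no IPV.** A literal reading of "IPV at one survey
   followed by no IPV at all other surveys" excludes it (the first NO
   precedes the YES), but the canonical example list includes it, so the
   implemented condition is simply *exactly one YES, with a drop*.

Inconsistent sequences with ≥ 2 YES and ≥ 2 NO are always Mixed, even
one-directional ones like `YYNN`. A corollary used as a structural test:
Mixed is impossible with exactly three answers, which is why the
three-answers row of the class-by-answers table contains a structural zero.

Classification ignores missing waves entirely (MISSING-insertion
invariance), which the tests check by property: spreading any answered
string across arbitrary waves (wave 1 fixed) never changes the class.

## Derived covariates

* **Relationship trajectory** uses separated/divorced status at the first
  and last *answered* wave plus an ever-flag: never, remained, became
  partnered (exited separation/divorce by the last answered wave, whether
  or not re-partnered), became separated/divorced. Multi-transition
  histories (e.g. separated → married → separated) are resolved by the
  first/last rule; widowed and single count as "not separated/divorced".
* **Sustained stress** is TRUE when the item was affirmed at ≥ half of the
  waves at which it was answered, ties inclusive; the denominator is the
  number of answered stress items, the stricter and directly testable
  reading of "completed surveys".
* **Design weights** are 1 for major-city and 0.5 for all other areas,
  reflecting the two-fold intentional oversampling of rural and remote
  women. Weights enter descriptive percentages only; percentages are
  invariant to global rescaling, so raw (unnormalised) weights suffice.
  The regression is unweighted by default — the published modelling made
  no mention of weighting — with a `weights` argument for sensitivity
  checks.
* **Survey-count category**: 6 → SIX, 5 → FIVE, 3–4 → THREE_FOUR, from the
  answered count of the IPV item.

## The regression

`fit_consistency_model()` fits a baseline-category multinomial logit with
*Consistent IPV* as the reference outcome and declared reference levels for
each covariate (major city, less than year 12, never separated/divorced,
no sustained stress, six surveys). The likelihood is maximised by
`nnet::multinom` (BFGS, relative tolerance 1e-10, at most 200 iterations);
confidence intervals are Wald on the log-odds scale with z = 1.959964, the
default of the multinomial routines contemporary with the analysis.
Records with any missing model covariate are dropped and counted —
complete-case analysis, reported in `n_dropped`, never silent. The 0.05
significance threshold only annotates the odds-ratio table; nothing is
selected on it.

Two failure modes are made explicit rather than hidden: non-convergence
(warning plus `converged = FALSE`) and (quasi-)separation, flagged when any
non-intercept coefficient exceeds 15 in absolute value — with an empty
outcome-by-level cell the MLE diverges, the Hessian is near-singular, and
the affected rows are reported with `NA` standard errors where the variance
estimate is unusable. Tests pin the estimator to two independent oracles: a
saturated two-outcome fit must equal the closed-form cross-product odds
ratio of the 2×2 table, and a two-class fit must reproduce
`stats::glm(..., family = binomial)` coefficients.

## The generative model

`simulate_cohort()` draws, per woman:

1. **Latent truth**: ever-IPV with probability `prev_ever`; conditional on
   ever, an onset wave in 0..6 (0 = before the first survey). Truth is
   absorbing, so the truthful answer at wave `w` is YES iff onset ≤ `w`;
   every simulated inconsistency is reporting error by construction. A
   woman whose onset falls after her last answered wave is observationally
   a never-case.
2. **Stress propensity** `s` (a woman-level income-stress latent), more
   common given ever-IPV, which shifts the false-negative rate, the
   false-positive rate and attrition on the log-odds scale. Keeping all
   covariate feedback in one binary latent is what makes the exact
   enumeration below possible.
3. **Attrition**: the answered count (3/4/5/6 or an ineligible pattern) is
   drawn directly from `answer_margins` — the published 8.5/10.7/15.7/65.1
   split scaled by the eligible fraction — tilted towards fewer waves when
   `s = 1`. Within a count the pattern is the monotone prefix with
   probability `monotone_mix` (default 0.7), otherwise uniform over
   wave-1-answered patterns: a monotone-dropout versus intermittent-
   skipping mixture. Ineligible mass splits into wave-1-only (0.69, the
   published share of ineligible women responding once), wave-1 plus one,
   and wave-1-missing shapes. Drawing margins directly, rather than
   deriving them from a geometric dropout process, removes one calibration
   layer and makes the margins exact by construction.
4. **Reports**: at an answered wave, YES with probability `1 − fn(s)` if
   the truthful answer is YES, else `fp(s)`.
5. **Descriptive covariates**: area and qualification from fixed category
   probabilities; relationship trajectory drawn conditionally on ever-IPV
   and then expanded into a consistent per-wave status history; per-wave
   partner stress elevated while IPV is true; per-wave income stress driven
   by `s`. These shape the characteristics table but do not feed back into
   the response mechanism beyond `s`.

`exact_class_distribution()` computes the implied class distribution
*exactly* by summing over onset (8 states) × stress (2) × eligible answered
patterns (26) × response strings (≤ 2^6), conditioning on eligibility — a
few milliseconds, used as the oracle for the simulator (agreement within
binomial sampling error is a standing property test) and as the objective
for calibration.

`cross_sectional_bias()` contrasts, among the responders of a single wave,
the apparent lifetime prevalence with the true lifetime-to-date prevalence.
Both quantities condition on answering that wave, so the statistic isolates
*measurement* bias: with `fp = fn = 0` it is exactly zero at every wave
even though attrition still correlates with the latent state; with `fn > 0`
and `fp = 0` it is negative (net under-reporting) by construction.

## Calibration and its limits

`calibrate_error_rates()` grid-searches `(fp, fn, prev_ever, onset-0 mass)`
— attrition and covariate effects fixed — minimising squared distance
between the exact class percentages and a target, with one refinement pass
around the best coarse cell. The shipped `paper_like` preset is the result
of calibrating to the published six-class percentages; its parameters
(`fp = 0.016`, `fn = 0.13`, `prev_ever = 0.165`, 89% of onsets before wave
1) are the generator defaults.

The calibrated fit is deliberately imperfect, and the reason is
instructive: under homogeneous per-wave error, a woman whose truth is
all-YES produces a single-NO (Mainly IPV) sequence with probability of
order `n·fn·(1−fn)^(n−1)` and an all-YES sequence with probability
`(1−fn)^n`, so the ratio of Consistent-IPV to Mainly-IPV counts pins `fn`
near `(1 + 6·ratio)^{-1}` — far smaller than the value needed to generate
the observed Mixed share, which requires at least two errors in one
sequence. Real inconsistency is therefore *over-dispersed* relative to
independent per-wave error: some women are far more error-prone than
others. The single binary stress latent adds a little heterogeneity but
cannot close the gap, so the calibrated preset under-produces Mixed and
over-produces Mainly IPV relative to the target. The calibrated error
rates are illustrative values implied by this error model, not estimates of
the source cohort's true rates.

## What the generator does and does not emulate

Emulated: the eligibility structure and answer margins; a realistic
ever-reporting share (≈ 23%); absorbing lifetime truth with onset; both
monotone and intermittent missingness; false positives and false negatives
with covariate-linked heterogeneity; group differences in trajectory and
stress of the kind seen in the characteristics table.

Not emulated: recall windows or genuine IPV cessation (the truth is
absorbing by design); informative nonresponse beyond the stress latent;
within-woman persistence of the per-wave stress items (they are drawn
independently given the latent, which makes *sustained* partner stress
rarer than in real data — one consequence is an occasional empty
class-by-stress cell in simulated regressions, duly flagged as suspected
separation); and the over-dispersed error process noted above. Passing
tests on simulated cohorts therefore demonstrate correctness of the
machinery under a known mechanism, not that the mechanism captures
everything in the real cohort.

## Numerical conventions and problem sizes

* Table percentages round half-up (`round_half_up()`): 587/10,966 prints as
  5.4, matching the published tables; base `round()` would give 5.3. Six
  rounded cells can drift up to ±0.3 from 100 in adversarial cases; the
  cross-tab tests allow ±0.2, which holds for all tables exercised.
* The eligibility filter is idempotent; record conservation
  (eligible + excluded = input) is asserted on every pipeline run.
* Determinism: one integer seed fixes a cohort bit-for-bit; the pipeline
  manifest (config + seed + version) suffices to reproduce every output
  byte-identically.
* Default test and validation sizes were chosen to make Monte-Carlo error
  negligible relative to the effects tested: 30,000-woman cohorts for
  oracle agreement in the property tests (100,000 in the acceptance
  script, 3-standard-error bands), 5,000 records × 100 replicates for
  confidence-interval coverage of an injected coefficient, and exhaustive
  enumeration (no sampling at all) wherever the classifier itself is under
  test.
* The preset seed 20191029 is an arbitrary date-derived constant; all
  user-facing entry points accept an explicit seed.

## Known limitations

* Complete-case covariate handling only; no imputation of missing waves or
  covariates (out of scope by design).
* Wald intervals can be poor in sparse cells; the separation flag marks
  where, but no penalised or exact alternative is provided.
* The classifier is defined for six waves; the enumeration oracle accepts
  3–6 answers but nothing longer.
* Calibration searches four parameters on a grid; it reports the achieved
  distance honestly and will simply return a poor best fit for infeasible
  targets rather than erroring.
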