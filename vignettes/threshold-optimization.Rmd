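---
title: "Linking achievable sensitivity to clinical alert rates: subgroup-specific AI threshold optimization"
author: "ThreshLink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking achievable sensitivity to clinical alert rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThreshLink)
```

## The problem

A diagnostic AI system for chest radiographs emits a continuous
confidence score per pathology; deployment requires a decision
threshold. Vendors ship fixed defaults, and the classical alternative —
maximizing Youden's J on a validation set — is deliberately
prevalence-independent, so neither reflects what a threshold does in a
particular clinical population: the *alert rate*, the fraction of
routine examinations flagged positive, which is what radiologists
actually experience and which differs sharply between, say, inpatients
(high disease prevalence, complex films) and outpatients.

ThreshLink implements a dual-cohort optimization strategy:

1. **Enriched cohort.** A pathology-enriched validation set, read by a
   panel of radiologists on a 5-point Likert scale (0 no suspicion ...
   4 certain). Ratings are pooled into four nested binary reference
   standards: RFS I counts only rating 4 as positive, RFS II ratings
   ≥ 3, RFS III ≥ 2, and RFS IV ≥ 1 — the two endpoints fix the
   interior levels as the only monotone completion. Per reader and
   RFS level, the AI score yields an empirical ROC curve; because
   sensitivity and specificity are prevalence-free, the enrichment is
   harmless here.
2. **Clinical cohort.** A large consecutive routine sample, scored by
   the same AI but (mostly) unread. Any threshold has a directly
   measurable alert rate in each subgroup.
3. **Linkage.** Sweeping a grid of target sensitivities (default 0 to
   100% in 1% steps), each reader's ROC curve is inverted to the
   least-sensitizing threshold achieving the target, and that
   threshold's alert rate is measured in the clinical subgroup. The
   across-reader mean curve of alert rate against achievable
   sensitivity is the object of optimization.
4. **Slope criterion.** The target sensitivity is the first grid point
   at which one more percentage point of sensitivity costs *more* than
   one percentage point of alert rate. Beyond that point the marginal
   alert is dominated by false positives and further sensitization
   buys no net discrimination. The optimized threshold (OT) is the
   mean of the per-reader thresholds at the common target; because the
   linkage curve depends on the subgroup's score distribution, OTs are
   subgroup-specific (outpatient- and inpatient-optimized thresholds).

A small expert-read random sample of the clinical cohort (the *sample
reading*, 200 cases per subgroup by default) then provides
prevalence-dependent metrics — sensitivity, specificity, accuracy,
predictive values, with 95% Wald intervals — to compare the OT against
the vendor default (AIDT) and Youden thresholds.

## Conventions and numerical choices

* **Positive call: score ≥ threshold.** The inequality is isolated in
  one predicate; candidate thresholds are the unique observed scores
  plus a sentinel one representable increment above the maximum, which
  yields the sensitivity-0/specificity-1 corner. Tied scores collapse
  to a single operating point — the curve is the exact empirical step
  function, with no interpolation or binormal smoothing.
* **AUC** is the trapezoid over the collapsed operating points, which
  equals the Mann–Whitney statistic with ties counted ½.
* **Youden tie-break:** among thresholds maximizing J, the highest
  (most specific, fewest alerts) is returned.
* **Sensitivity inversion:** the largest threshold whose sensitivity
  meets the target. On a step-function ROC a requested grid
  sensitivity maps to the next achievable operating point; the
  realized sensitivity is stored alongside the requested one.
* **Aggregation:** per-reader OTs inherit the common target found on
  the mean alert curve (per-reader targets would conflate reader
  variability with the subgroup effect); the aggregate is the
  arithmetic mean of per-reader thresholds, with the median available.
* **Wald intervals** use z = 1.959964 and clip to [0, 100]; this is
  the form that reproduces published diagnostic-accuracy brackets
  exactly, with Wilson available behind a flag. Projected subgroup
  counts use the ceiling, the rounding consistent with published
  projected-count tables.
* **Proportion comparisons** use the continuity-corrected chi-square
  test, with Fisher's exact test when an expected cell is below 5.

## The slope estimator

The criterion is defined through forward differences of the mean alert
curve on the sensitivity grid. On *empirical* curves the raw forward
difference is a poor estimator: the mean alert curve is a step function
whose increments are driven by the spacings of the enriched cohort's
positive score order statistics. Those spacings have a coefficient of
variation near one, so in a high-prevalence subgroup (where the true
slope is already close to the prevalence) single-interval slopes exceed
one spuriously long before the real transition; measured on synthetic
inpatient cohorts at realistic sizes, a raw forward-difference scan
lands the threshold a median 0.6 score units away from the ground
truth.

Whenever the score likelihood ratio is monotone — true for the Beta
families used in simulation and a standard assumption for confidence
scores — the exact linkage curve is convex: its slope,
$\pi + (1-\pi)\,f_0(t)/f_1(t)$ in percent per percent, increases along
the grid. The default estimator therefore takes slopes from the
greatest convex minorant of the empirical curve (weighted
pool-adjacent-violators on the forward differences). This is
parameter-free, reduces *exactly* to the raw forward differences on any
already-convex curve (so closed-form examples are unaffected), and on
a convex curve the first minorant slope above one coincides with the
point maximizing sensitivity − alert. The raw estimator remains
available (`findTargetSensitivity(..., method = "forward")`). With the
default estimator the recovered threshold sits within 0.02 score units
(median) of the analytic optimum at realistic cohort sizes.

When the slope never exceeds one — e.g. a perfectly separating score —
the maximum grid sensitivity is returned flagged
`criterion_triggered = FALSE`: the OT is an upper bound of justifiable
sensitization, not an interior optimum.

## The synthetic generator

No image cohorts can ship with the package, so `genParams()` /
`genEnrichedCohort()` / `genClinicalCohort()` emulate the study
conditions and provide closed-form oracles.

* **Cohort structure.** Defaults mirror the motivating study: a
  563-case enriched cohort with per-pathology prevalences
  0.249/0.259/0.103/0.084 (pleural effusion, consolidation,
  pneumothorax, nodule), read by six readers (three board-certified,
  three residents); a clinical cohort of 3,619 outpatient and 11,900
  inpatient examinations with subgroup prevalences
  0.235/0.235/0.025/0.080 and 0.465/0.290/0.125/0.055; a 200-case
  expert sample reading per subgroup whose labels are the simulated
  ground truth (a noise-free expert read).
* **Scores.** Diseased and healthy scores follow Beta mixtures —
  bounded support matches the [0, 1] score scale without the clipping
  a binormal model would need. The shared default, diseased
  Beta(2.2, 2.8) against healthy Beta(1.2, 14), was chosen once for
  realism: AUC 0.966 against noise-free truth, a slope-criterion
  target near 88% sensitivity, and alert rates of roughly 26%
  (outpatient) and 45% (inpatient) at the optimized threshold — the
  operating region the published pleural-effusion results occupy.
* **Reader model.** Each diseased case carries a latent severity
  $s \sim U(0,1)$ (0 for healthy) that drives both the AI score, via
  quantile coupling $\mathrm{score} = Q_{\mathrm{diseased}}(s)$, and
  every reader's perception $s + N(0, \sigma_r)$, mapped to Likert
  ratings by strictly increasing cutpoints (a rating requires
  perception strictly above the cutpoint). This induces the
  reader–AI correlation real panels show; `coupling < 1` mixes in
  independent score draws while preserving the marginals.
* **Reader defaults and reference-standard bias.** Cutpoints default
  to (0.05, 0.35, 0.65, 0.9) with $\sigma_r = 0.03$. The first
  cutpoint and noise level jointly control two opposing distortions of
  the RFS IV reference standard: readers *miss* low-severity disease
  (severity below the first cutpoint) and *over-call* healthy cases
  whose perception noise exceeds it. False-positive ratings dilute the
  reference affinely — they carry scores independent of the AI's
  diseased channel and leave the sensitivity-to-threshold
  correspondence intact — whereas missed disease is
  severity-correlated and distorts the curve precisely when the missed
  scores reach the operating region. The defaults keep the missed mass
  below it ($Q_{\mathrm{diseased}}(c_1 + 2\sigma_r)$ well under the
  optimized threshold) and produce a ~5% healthy over-call rate at
  RFS IV, so the simulated RFS IV enriched prevalence (≈ 0.26 for
  pleural effusion) slightly exceeds the design prevalence — the same
  pattern the motivating study's reference readings show. With
  $\sigma_r = 0$ and a zero first cutpoint, every reader reproduces
  the ground truth exactly; that is the regime in which the analytic
  oracles below are exact.
* **Oracles.** For noise-free truth-reading cohorts the linkage curve
  has a closed form in the Beta survival functions
  (`analyticLinkage()`), and the slope-criterion optimum is computed
  exactly (`analyticOt()`); on the exact curve the trigger point is
  where the healthy score density first exceeds the diseased one, so
  it is prevalence-independent while the alert rate at the OT is not —
  which is why, with a shared score model, the inpatient OT equals the
  outpatient OT but flags roughly twice the examinations.
* **Determinism.** One global seed; every (purpose, subgroup,
  pathology) stream derives its own sub-seed by a stable string hash,
  so runs are reproducible across platforms and adding a pathology
  does not perturb the others.

What the generator does *not* emulate: image content, device
artifacts (drains mimicking pneumothorax), co-occurring pathologies,
subgroup-specific score distributions (real inpatient films differ in
complexity, not just prevalence), or calibrated reader correlation
structure — no published reader-agreement statistics were available to
fit one. Passing synthetic checks therefore validates the pipeline's
statistical machinery, not the AI system or the transferability of
enriched-cohort sensitivity to any particular clinic.

## Worked example

```{r example, eval = FALSE}
params <- genParams()
enriched <- genEnrichedCohort(params, seed = 17)
clinical <- genClinicalCohort(params, seed = 17)

out <- optimizeThreshold(enriched, clinical, "outpatient",
                         "pleural_effusion", aidt = 0.145)
out
inp <- optimizeThreshold(enriched, clinical, "inpatient",
                         "pleural_effusion", aidt = 0.145)

# prevalence-dependent metrics at the optimized threshold
tab <- confusionFromReading(clinical, "pleural_effusion",
                            optimizedThreshold(out),
                            subgroup = "outpatient")
diagnosticMetrics(tab)

# reconstruct a published 2x2 from its printed summary row
diagnosticMetrics(reconstructTable(46.8, 98.0, 23.5, 200))
```

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle: ROC
curves, AUC, Youden cutpoints and sensitivity inversion against
brute-force enumeration over all operating points (a thousand random
cohorts of up to 100 cases, heavy ties included); diagnostic metrics
against textbook recomputation; table reconstruction against exact
integer search; the analytic linkage against a $10^6$-draw Monte Carlo
and a $10^4$-point threshold mesh; and the full pipeline against the
analytic optimum — within one 1%-grid step of target sensitivity on a
noise-free 20,000-case enriched / 100,000-case clinical configuration,
and within 0.05 score units (median over 20 seeds) at the default
cohort sizes of 563 / 15,519. These sizes keep the whole suite in the
minutes range while leaving the estimators' finite-sample behaviour
visible.

## Limitations

* The slope criterion is a marginal-cost rule established by expert
  consensus, not a decision-theoretic optimum; the package treats it
  as given and focuses on estimating it well.
* Published p-values comparing thresholds on the same sample reading
  are reproduced only in order of magnitude: the underlying test in
  such tables is rarely stated, and a paired design would require the
  per-case calls. The package's `compareProportions()` is an unpaired
  test and says so.
* Wald intervals misbehave near 0/100% (they clip); they are the
  published convention, not the recommendation — use
  `method = "wilson"` for analysis work.
* Alert-rate linkage assumes the enriched cohort's
  sensitivity-threshold relationship transfers to the clinic; image
  quality or severity shifts between cohorts bias it. The vignette's
  synthetic checks share one score model across cohorts and cannot
  detect such shifts.
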