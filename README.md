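# ThreshLink

Subgroup-specific decision-threshold optimization for diagnostic AI
scores, by linking the sensitivity achievable on a pathology-enriched,
multi-reader validation cohort to the alert rate the same threshold
produces in clinical-routine subgroups.

## The problem

Chest-radiograph AI systems emit a confidence score per pathology;
using them requires a threshold. Vendor defaults are fixed, and the
classical Youden cutpoint (maximizing J = sensitivity + specificity −
1) is deliberately prevalence-independent — neither reflects what a
threshold *does* in a given clinical population, namely the **alert
rate**: the share of routine examinations flagged positive. ThreshLink
implements a dual-cohort strategy:

- per-reader ROC curves of the AI score on an enriched cohort, against
  binary reference standards pooled from 5-point Likert ratings
  (RFS I: only "certain" is positive, …, RFS IV: "unlikely" and above);
- a **linkage curve** per clinical subgroup: for each target
  sensitivity *s* on a 1% grid, invert each reader's ROC to the
  least-sensitizing threshold achieving *s*, measure its alert rate
  *A(s)* in the subgroup, and average across readers;
- the **slope criterion**: the optimized threshold (OT) sits at the
  first grid sensitivity where ΔA/Δs exceeds 1 — beyond it, each
  additional percentage point of sensitivity costs more than a
  percentage point of alerts. Slopes are estimated from the greatest
  convex minorant of the empirical curve (the raw forward difference
  is available as an option);
- diagnostic 2×2 metrics with 95% Wald intervals against a small
  expert sample reading, comparing OT, vendor default (AIDT) and
  Youden thresholds, plus reconstruction of 2×2 tables from published
  summary percentages.

A seeded synthetic generator (Beta score mixtures coupled to a
latent-severity reader model) emulates both cohorts and provides
closed-form oracles for the linkage curve and the true optimized
threshold.

## Worked example

```r
library(ThreshLink)

params   <- genParams()                      # study-sized defaults
enriched <- genEnrichedCohort(params, seed = 17)   # 563 cases, 6 readers
clinical <- genClinicalCohort(params, seed = 17)   # 3,619 + 11,900 cases

optimizeThreshold(enriched, clinical, "outpatient", "pleural_effusion",
                  aidt = 0.145)
#> OptimizationResult [pleural_effusion | outpatient | RFS IV]
#>   target sensitivity 83.0% (criterion triggered)
#>   OT 0.1706, alert rate at OT 27.4%, AIDT 0.1450
```

The slope criterion stops at 83% achievable sensitivity: sensitizing
past that point would add alerts faster than true detections. The
optimized threshold 0.171 would flag 27.4% of outpatient films; the
same computation for `"inpatient"` returns the same threshold region
but an alert rate near 47%, because prevalence there is twice as high
— the reason subgroup-specific thresholds are worth inspecting at all.
Against the 200-case expert sample reading,

```r
tab <- confusionFromReading(clinical, "pleural_effusion", 0.1706,
                            subgroup = "outpatient")
diagnosticMetrics(tab)
```

reports sensitivity/specificity/accuracy (with Wald CIs) at the OT, and
`reconstructTable(46.8, 98.0, 23.5, 200)` recovers the integer 2×2
behind a published summary row (tp 22, fp 3, fn 25, tn 150 — accuracy
86.0%).

A thin command-line launcher covering the same pipeline
(`simulate`, `validate`, `roc`, `linkage`, `optimize`, `evaluate`,
`reconstruct`, `run`) is installed at
`system.file("scripts", "threshlink", package = "ThreshLink")`.

## Documentation

See the methods vignette
(`vignettes/threshold-optimization.Rmd`) for the model, the estimator
and generator design choices, and known limitations.
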