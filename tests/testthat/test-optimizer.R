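# hand-built linkage curve with a single pseudo-reader whose alert
# series follows a prescribed function of the sensitivity grid
curveFromFunction <- function(f, grid = seq(0, 100, 1)) {
    alert <- matrix(f(grid), ncol = 1, dimnames = list(NULL, "R1"))
    new("LinkageCurve", pathology = "pleural_effusion",
        subgroup = "outpatient", rfs = "IV", sens_grid = grid,
        per_reader_alert = alert,
        per_reader_threshold = matrix(seq(1, 0, length.out = length(grid)),
                                      ncol = 1, dimnames = list(NULL, "R1")),
        per_reader_sens = matrix(grid, ncol = 1,
                                 dimnames = list(NULL, "R1")),
        mean_alert = as.numeric(alert))
}

test_that("the slope criterion fires exactly where marginal cost exceeds one", {
    # linear curve, slope = prevalence 0.3: never fires
    lin <- curveFromFunction(function(s) 0.3 * s)
    got <- findTargetSensitivity(lin)
    expect_false(got$criterion_triggered)
    expect_identical(got$target_sensitivity, 100)
    # quadratic alert curve: forward difference (51^2 - 50^2)/100 = 1.01
    # is the first to exceed one, so the target is the 50% grid point
    quad <- curveFromFunction(function(s) s^2 / 100)
    for (m in c("gcm", "forward")) {
        got <- findTargetSensitivity(quad, method = m)
        expect_true(got$criterion_triggered)
        expect_identical(got$target_sensitivity, 50)
    }
})

test_that("convex-minorant slopes damp local jitter but keep convex curves", {
    # convex curve plus one local step that the raw forward difference
    # misreads as an early trigger: the interval from 30 to 31 gains an
    # extra 0.6 points of alert, raw slope 0.61 + 0.6 = 1.21 > 1, while
    # the minorant spreads the step over the following intervals (their
    # pooled slope stays below 1) and keeps the true transition at 50
    bump <- function(s) s^2 / 100 + 0.6 * (s >= 31)
    raw <- findTargetSensitivity(curveFromFunction(bump), method = "forward")
    gcm <- findTargetSensitivity(curveFromFunction(bump), method = "gcm")
    expect_identical(raw$target_sensitivity, 30)  # fooled by the step
    expect_identical(gcm$target_sensitivity, 50)  # recovers the transition
})

test_that("per-reader thresholds aggregate at the common target", {
    co <- toyEnriched(scores = c(0.9, 0.7, 0.5, 0.3, 0.1),
                      likert_by_reader = list(R1 = c(4L, 4L, 0L, 0L, 0L),
                                              R2 = c(4L, 4L, 4L, 0L, 0L)))
    rocs <- readerRocCurves(co, "pleural_effusion")
    # hand enumeration: at target 100%, R1 needs 0.7 (its lowest
    # positive), R2 needs 0.5; the aggregate is their mean
    ot <- deriveOt(rocs, 100)
    expect_equal(unname(ot$per_reader_ot), c(0.7, 0.5))
    expect_equal(ot$ot, 0.6)
    expect_equal(deriveOt(rocs, 100, aggregate = "median")$ot, 0.6)
    # at target 50%, R1 keeps only its top case (sens 50% reached at
    # 0.9... enumeration: R1 has 2 positives so 50% = 1 of 2 at 0.9;
    # R2 has 3 positives, 50% needs 2 of 3 at 0.7
    ot50 <- deriveOt(rocs, 50)
    expect_equal(unname(ot50$per_reader_ot), c(0.9, 0.7))
    # target 0%: every reader sits at the sentinel, above every score
    ot0 <- deriveOt(rocs, 0)
    expect_true(all(ot0$per_reader_ot > 0.9))
    expect_gt(ot0$ot, max(aiScores(co)))
    # identical readers collapse onto a single threshold
    co2 <- toyEnriched(scores = c(0.9, 0.7, 0.5, 0.3),
                       likert_by_reader = list(R1 = c(4L, 4L, 0L, 0L),
                                               R2 = c(4L, 4L, 0L, 0L)))
    ot2 <- deriveOt(readerRocCurves(co2, "pleural_effusion"), 100)
    expect_identical(unname(ot2$per_reader_ot[1L]), ot2$ot)
})

test_that("a perfect AI never triggers the criterion end to end", {
    # disjoint empirical score supports in both cohorts, truth-reading
    pos <- seq(0.6, 0.95, length.out = 8)
    neg <- seq(0.02, 0.3, length.out = 12)
    co <- toyEnriched(scores = c(pos, neg),
                      likert_by_reader = list(R1 = rep(c(4L, 0L), c(8, 12))))
    cl <- toyClinical(c(rep(pos, 2), rep(neg, 6)))  # prevalence 0.18
    res <- optimizeThreshold(co, cl, "outpatient", "pleural_effusion")
    expect_false(criterionTriggered(res))
    expect_identical(targetSensitivity(res), 100)
    # OT is the lowest threshold achieving 100% sensitivity
    expect_equal(optimizedThreshold(res), min(pos))
    expect_equal(res@alert_at_ot, 100 * 16 / (16 + 72))
})

test_that("optimization recovers subgroup-dependent alert rates", {
    p <- genParams()
    e <- genEnrichedCohort(p, 21)
    cl <- genClinicalCohort(p, 21)
    out <- optimizeThreshold(e, cl, "outpatient", "pleural_effusion",
                             aidt = 0.145)
    inp <- optimizeThreshold(e, cl, "inpatient", "pleural_effusion",
                             aidt = 0.145)
    # shared score model, higher inpatient prevalence: more alerts at
    # the optimized threshold
    expect_gt(inp@alert_at_ot, out@alert_at_ot)
    expect_identical(out@aidt, 0.145)
    expect_length(out@per_reader_ot, 6L)
    expect_length(out@youden_by_reader, 6L)
    # deterministic: same seed and config give an identical result
    res2 <- optimizeThreshold(genEnrichedCohort(p, 21),
                              genClinicalCohort(p, 21),
                              "outpatient", "pleural_effusion", aidt = 0.145)
    expect_equal(out, res2)
    # lowering the aggregate threshold can only raise the alert rate
    lower <- alertRate(cl, "outpatient", "pleural_effusion",
                       optimizedThreshold(out) * 0.8)[["percent"]]
    expect_gte(lower, out@alert_at_ot)
})

test_that("stage failures surface with the failing stage's name", {
    p <- effusionParams(n_enriched = 60L,
                        n_subgroup = c(outpatient = 50L, inpatient = 50L),
                        sample_n = 10L)
    e <- genEnrichedCohort(p, 2); cl <- genClinicalCohort(p, 2)
    expect_error(optimizeThreshold(e, cl, "outpatient", "nodule"),
                 "stage 'roc_curve'")
    expect_error(optimizeThreshold(e, cl, "other", "pleural_effusion"),
                 "stage 'linkage_curve'")
})

test_that("results serialize to the documented JSON contract", {
    co <- toyEnriched(scores = c(0.9, 0.7, 0.4, 0.2),
                      likert_by_reader = list(R1 = c(4L, 3L, 1L, 0L)))
    cl <- toyClinical(runif(40))
    res <- optimizeThreshold(co, cl, "outpatient", "pleural_effusion",
                             aidt = 0.5)
    f <- withr::local_tempfile(fileext = ".json")
    optimizationAsList(res, f)
    back <- jsonlite::read_json(f)
    expect_identical(back$pathology, "pleural_effusion")
    expect_identical(back$rfs, "IV")
    expect_equal(back$target_sensitivity_pct, targetSensitivity(res))
    expect_equal(back$ot, optimizedThreshold(res))
    expect_equal(back$aidt, 0.5)
    expect_named(back$per_reader_ot, "R1")
})
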