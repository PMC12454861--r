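test_that("generation is deterministic under a fixed seed", {
    p <- effusionParams(n_enriched = 120L,
                        n_subgroup = c(outpatient = 150L, inpatient = 200L),
                        sample_n = 30L)
    e1 <- genEnrichedCohort(p, 17); e2 <- genEnrichedCohort(p, 17)
    expect_identical(SummarizedExperiment::assay(e1, "likert"),
                     SummarizedExperiment::assay(e2, "likert"))
    expect_identical(aiScores(e1), aiScores(e2))
    c1 <- genClinicalCohort(p, 17); c2 <- genClinicalCohort(p, 17)
    expect_identical(as.data.frame(sampleReading(c1)),
                     as.data.frame(sampleReading(c2)))
    # byte-identical CSV emission
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    f1 <- writeEnrichedCohort(e1, d1); f2 <- writeEnrichedCohort(e2, d2)
    expect_identical(readLines(f1[1L]), readLines(f2[1L]))
    expect_identical(readLines(f1[2L]), readLines(f2[2L]))
    # a different seed changes the draw
    expect_false(identical(aiScores(genEnrichedCohort(p, 18)), aiScores(e1)))
})

test_that("empirical prevalences track the configured fractions", {
    p <- effusionParams(prev_enriched = 0.15, n_enriched = 10000L)
    e <- genEnrichedCohort(p, 23)
    tr <- S4Vectors::metadata(e)$truth
    # within 3 binomial standard deviations of 0.15
    expect_gt(mean(tr$diseased), 0.139)
    expect_lt(mean(tr$diseased), 0.161)
})

test_that("clinical subgroup sizes are exact and sampling reproducible", {
    p <- genParams()
    cl <- genClinicalCohort(p, 11)
    sg <- table(subgroups(cl))
    expect_identical(as.integer(sg[["inpatient"]]), 11900L)
    expect_identical(as.integer(sg[["outpatient"]]), 3619L)
    # 200 sampled cases per subgroup, each read for all four pathologies
    sr <- as.data.frame(sampleReading(cl))
    expect_identical(nrow(sr), 2L * 200L * 4L)
    # higher configured inpatient prevalence shows up empirically
    tr <- S4Vectors::metadata(cl)$truth
    tr$subgroup <- subgroups(cl)[tr$case_id]
    eff <- tr[tr$pathology == "pleural_effusion", ]
    expect_gt(mean(eff$diseased[eff$subgroup == "inpatient"]),
              mean(eff$diseased[eff$subgroup == "outpatient"]))
    expect_error(genClinicalCohort(genParams(sample_n = 5000L), 1),
                 "sample_n")
})

test_that("noise-free readers agree with each other", {
    p <- effusionParams(n_enriched = 300L, sigma_r = 0, n_readers = 3L,
                        n_subgroup = c(outpatient = 10L, inpatient = 10L),
                        sample_n = 5L)
    e <- genEnrichedCohort(p, 3)
    lk <- SummarizedExperiment::assay(e, "likert")
    expect_identical(lk[, 1L], lk[, 2L])
    expect_identical(lk[, 1L], lk[, 3L])
    # zero prevalence: every reader label negative under the most
    # sensitive standard
    p0 <- effusionParams(prev_enriched = 0, n_enriched = 200L, sigma_r = 0,
                         n_subgroup = c(outpatient = 10L, inpatient = 10L),
                         sample_n = 5L)
    e0 <- genEnrichedCohort(p0, 4)
    lab <- buildReferenceStandard(e0, "BCR1", "pleural_effusion", "IV")
    expect_false(any(lab))
})

test_that("parameter validation rejects infeasible configurations", {
    expect_error(genParams(cutpoints = c(0.5, 0.4, 0.6, 0.8)), "increasing")
    expect_error(genParams(prev_enriched = 1.2), "prevalence")
    expect_error(genParams(score_diseased = c(1, 9), score_healthy = c(9, 1)),
                 "exceed")
    expect_error(genParams(coupling = 2), "coupling")
})

test_that("GenParams round-trip through YAML", {
    p <- genParams(sigma_r = 0.05, sample_n = 150L)
    f <- withr::local_tempfile(fileext = ".yaml")
    writeGenParams(p, f)
    p2 <- readGenParams(f)
    expect_equal(p2$prev_subgroup, p$prev_subgroup)
    expect_identical(p2$n_subgroup, p$n_subgroup)
    expect_identical(p2$sigma_r, p$sigma_r)
    expect_identical(p2$cutpoints, p$cutpoints)
})

test_that("analytic linkage endpoints and interior match Monte Carlo", {
    p <- effusionParams()
    lk <- analyticLinkage(p, "outpatient", sens_grid = c(0, 50, 88, 100))
    expect_equal(lk$alert_pct[lk$sens_pct == 100], 100)
    expect_equal(lk$alert_pct[lk$sens_pct == 0], 0, tolerance = 1e-9)
    expect_true(all(diff(lk$alert_pct) >= 0))
    # interior point against a 10^6-draw Monte-Carlo oracle
    set.seed(99)
    n <- 1e6
    pi <- p$prev_subgroup["pleural_effusion", "outpatient"]
    dis <- runif(n) < pi
    x <- numeric(n)
    x[dis] <- rbeta(sum(dis), 2.2, 2.8)
    x[!dis] <- rbeta(sum(!dis), 1.2, 14)
    t88 <- lk$threshold[lk$sens_pct == 88]
    mc <- mean(x >= t88)
    se <- sqrt(mc * (1 - mc) / n)
    expect_lt(abs(mc - lk$alert_pct[lk$sens_pct == 88] / 100), 3 * se)
    expect_error(analyticLinkage(p, "outpatient", sens_grid = c(-5, 50)),
                 "\\[0, 100\\]")
})

test_that("analytic optimized threshold matches a dense-mesh brute force", {
    p <- genParams(pathologies = "x", prev_enriched = 0.25,
                   prev_subgroup = cbind(outpatient = 0.25),
                   score_diseased = c(6, 2), score_healthy = c(2, 6),
                   n_subgroup = c(outpatient = 100L), sample_n = 10L)
    got <- analyticOt(p, "outpatient")
    # brute force on a 10^4-point threshold mesh, independent formulas
    mesh <- seq(0, 1, length.out = 10001)
    S <- 1 - pbeta(mesh, 6, 2)
    A <- 0.25 * S + 0.75 * (1 - pbeta(mesh, 2, 6))
    grid <- seq(0, 100, by = 1)
    t_at <- vapply(grid, function(s) mesh[which(S * 100 >= s - 1e-9)
                                          [sum(S * 100 >= s - 1e-9)]],
                   numeric(1))  # largest mesh threshold reaching s
    A_at <- 100 * (0.25 * (1 - pbeta(t_at, 6, 2)) +
                   0.75 * (1 - pbeta(t_at, 2, 6)))
    sl <- diff(A_at) / diff(grid)
    k <- which(sl > 1)[1L]
    expect_identical(got$target_sensitivity, grid[k])
    expect_true(got$criterion_triggered)
    expect_equal(got$threshold, t_at[k], tolerance = 2e-4)
    # near-disjoint score supports: on the whole separating range the
    # slope is the prevalence (< 1), so the criterion cannot fire before
    # the terminal grid step where the threshold collapses to zero
    psep <- genParams(pathologies = "x", prev_enriched = 0.3,
                      prev_subgroup = cbind(outpatient = 0.3),
                      score_diseased = c(60, 3), score_healthy = c(3, 60),
                      n_subgroup = c(outpatient = 100L), sample_n = 10L)
    sep <- analyticOt(psep, "outpatient")
    expect_gte(sep$target_sensitivity, 99)
    lks <- analyticLinkage(psep, "outpatient", "x", sens_grid = seq(5, 95, 5))
    sl <- diff(lks$alert_pct) / diff(lks$sens_pct)
    expect_true(all(abs(sl - 0.3) < 0.01))
})
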