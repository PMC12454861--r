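# Independent brute-force oracles. These deliberately use naive
# per-threshold counting loops (no shared code with the package's
# vectorized implementations).

bruteRocPoints <- function(scores, labels) {
    labels <- as.logical(labels)
    thr <- c(max(scores) * (1 + 1e-9) + 1e-12, sort(unique(scores),
                                                    decreasing = TRUE))
    do.call(rbind, lapply(thr, function(t) {
        call <- scores >= t
        data.frame(threshold = t,
                   sensitivity = sum(call & labels) / sum(labels),
                   specificity = sum(!call & !labels) / sum(!labels))
    }))
}

# Mann-Whitney AUC: mean pairwise comparison with ties counted 1/2
bruteAuc <- function(scores, labels) {
    labels <- as.logical(labels)
    pos <- scores[labels]; neg <- scores[!labels]
    tot <- 0
    for (x in pos) tot <- tot + sum(x > neg) + 0.5 * sum(x == neg)
    tot / (length(pos) * length(neg))
}

bruteYouden <- function(scores, labels) {
    p <- bruteRocPoints(scores, labels)
    j <- p$sensitivity + p$specificity - 1
    best <- which(j > max(j) - 1e-12)   # floating-point-tolerant ties
    c(threshold = max(p$threshold[best]), youden_j = max(j))
}

bruteThresholdForSens <- function(scores, labels, target_pct) {
    p <- bruteRocPoints(scores, labels)
    ok <- p$sensitivity * 100 >= target_pct - 1e-9
    max(p$threshold[ok])
}

# Textbook recomputation of diagnostic ratios (second implementation)
bruteMetrics <- function(tp, fp, fn, tn) {
    c(sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp),
      accuracy = 100 * (tp + tn) / (tp + fp + fn + tn),
      ppv = 100 * tp / (tp + fp),
      npv = 100 * tn / (tn + fn),
      fnr = 100 * fn / (fn + tp),
      fpr = 100 * fp / (fp + tn))
}

# Small enriched cohort built by hand from explicit tables
toyEnriched <- function(scores, likert_by_reader, pathology = "pleural_effusion") {
    n <- length(scores)
    ids <- sprintf("T%03d", seq_len(n))
    sc <- data.frame(case_id = ids, pathology = pathology, ai_score = scores)
    rd <- do.call(rbind, lapply(names(likert_by_reader), function(r)
        data.frame(case_id = ids, reader_id = r, pathology = pathology,
                   likert = likert_by_reader[[r]])))
    enrichedCohort(sc, rd)
}

toyClinical <- function(scores, subgroup = "outpatient",
                        pathology = "pleural_effusion", reference = NULL) {
    n <- length(scores)
    ids <- sprintf("K%03d", seq_len(n))
    sr <- if (!is.null(reference))
        data.frame(case_id = ids, pathology = pathology,
                   reference_positive = as.integer(reference))
    clinicalCohort(data.frame(case_id = ids, subgroup = subgroup,
                              pathology = pathology, ai_score = scores), sr)
}

# single-pathology generator parameters (Table-1-style prevalences
# unless overridden), optionally at reduced size for speed
effusionParams <- function(...) {
    args <- list(...)
    base <- list(pathologies = "pleural_effusion", prev_enriched = 0.249,
                 prev_subgroup = cbind(outpatient = 0.235,
                                       inpatient = 0.465))
    do.call(genParams, utils::modifyList(base, args))
}

# the analytic-oracle reading regime: noise-free readers whose labels
# equal the ground truth (zero first cutpoint, strict rating rule)
truthReaderArgs <- function() {
    list(sigma_r = 0, cutpoints = c(0, 0.25, 0.5, 0.75), n_readers = 1L)
}
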