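#' Alert rate of a threshold in a clinical subgroup
#'
#' The fraction of subgroup cases whose AI score is at or above the
#' threshold — the share of routine examinations the AI would flag.
#'
#' @param clinical a \linkS4class{ClinicalCohort}.
#' @param subgroup subgroup name, or \code{"overall"} for the whole cohort.
#' @param pathology pathology name.
#' @param threshold decision threshold.
#' @return named numeric: \code{percent}, \code{count}, \code{n}.
#' @examples
#' cl <- clinicalCohort(data.frame(case_id = as.character(1:4),
#'     subgroup = "outpatient", pathology = "nodule",
#'     ai_score = c(0.1, 0.2, 0.6, 0.9)))
#' alertRate(cl, "outpatient", "nodule", 0.5)  # 50% (2 of 4)
#' @export
alertRate <- function(clinical, subgroup, pathology, threshold) {
    stopifnot(is(clinical, "ClinicalCohort"))
    sc <- clinical@scores
    keep <- sc$pathology == pathology &
        (subgroup == "overall" | sc$subgroup == subgroup)
    n <- sum(keep)
    if (n == 0L) stop("empty subgroup: ", subgroup, " / ", pathology)
    count <- sum(sc$ai_score[keep] >= threshold)
    c(percent = 100 * count / n, count = count, n = n)
}

#' Alert rate and Wald confidence interval from printed counts
#'
#' Summary arithmetic for published alert tallies: the percentage of
#' flagged cases and its 95% Wald interval from a count and a subgroup
#' size.
#'
#' @param count flagged cases.
#' @param n subgroup size.
#' @param level confidence level (default 0.95).
#' @return named numeric: \code{percent}, \code{lower}, \code{upper}.
#' @examples
#' alertRateFromCounts(1592, 3619)  # 44.0% of outpatient cases
#' @export
alertRateFromCounts <- function(count, n, level = 0.95) {
    ci <- waldCi(count, n, level)
    c(percent = 100 * count / n, lower = ci[["lower"]], upper = ci[["upper"]])
}

#' Link achievable sensitivity to clinical alert rates
#'
#' For each reader and each grid sensitivity: invert the reader's ROC
#' curve to the least-sensitizing threshold achieving that sensitivity
#' on the enriched cohort, then measure the alert rate this threshold
#' produces in the clinical subgroup. The across-reader mean is taken
#' pointwise on alert rates at fixed target sensitivity (not on
#' thresholds); grid sensitivities unreachable exactly on the
#' step-function ROC map to the next achievable operating point, whose
#' realized sensitivity is stored alongside.
#'
#' @param rocs list of per-reader \linkS4class{RocCurve} sharing
#'   pathology and reference-standard level (see [readerRocCurves()]).
#' @param clinical a \linkS4class{ClinicalCohort}.
#' @param subgroup clinical subgroup name.
#' @param sens_grid ascending sensitivity grid in percent (default 0 to
#'   100 by 1, the resolution the slope criterion is phrased in).
#' @return a \linkS4class{LinkageCurve}.
#' @export
linkageCurve <- function(rocs, clinical, subgroup,
                         sens_grid = seq(0, 100, by = 1)) {
    if (is(rocs, "RocCurve")) rocs <- list(rocs)
    stopifnot(length(rocs) >= 1L, all(vapply(rocs, is, TRUE, "RocCurve")))
    pt <- unique(vapply(rocs, function(r) r@pathology, character(1)))
    rfs <- unique(vapply(rocs, function(r) r@rfs, character(1)))
    if (length(pt) != 1L || length(rfs) != 1L)
        stop("all ROC curves must share pathology and rfs")
    if (any(sens_grid < 0 | sens_grid > 100) ||
        is.unsorted(sens_grid, strictly = TRUE) || length(sens_grid) < 2L)
        stop("sens_grid must be strictly ascending within [0, 100]")
    rdr <- unname(vapply(rocs, function(r) r@reader_id, character(1)))
    ng <- length(sens_grid)
    thr <- sens_real <- alert <- matrix(NA_real_, ng, length(rocs),
                                        dimnames = list(NULL, rdr))
    sc <- clinical@scores
    keep <- sc$pathology == pt &
        (subgroup == "overall" | sc$subgroup == subgroup)
    if (!sum(keep)) stop("empty subgroup: ", subgroup, " / ", pt)
    sorted <- sort(sc$ai_score[keep])
    nsub <- length(sorted)
    for (j in seq_along(rocs)) {
        p <- rocs[[j]]@points
        # first operating point at or above each target sensitivity
        idx <- findInterval(sens_grid - 1e-9, 100 * p$sensitivity,
                            left.open = TRUE) + 1L
        thr[, j] <- p$threshold[idx]
        sens_real[, j] <- 100 * p$sensitivity[idx]
        # alert rate: share of subgroup scores at or above the threshold
        alert[, j] <- 100 * (nsub - findInterval(thr[, j], sorted,
                                                 left.open = TRUE)) / nsub
    }
    new("LinkageCurve", pathology = pt, subgroup = subgroup, rfs = rfs,
        sens_grid = as.numeric(sens_grid), per_reader_alert = alert,
        per_reader_threshold = thr, per_reader_sens = sens_real,
        mean_alert = rowMeans(alert))
}
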