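#' Target sensitivity by the slope criterion
#'
#' Scans the linkage curve's sensitivity grid upward and computes the
#' forward-difference slope of the mean alert rate against sensitivity
#' (percent per percent). The target sensitivity is the first grid
#' point at which the slope exceeds one: beyond it, each additional
#' percentage point of sensitivity costs more than a percentage point
#' of alert rate, so further sensitization no longer buys net
#' discrimination. If the slope never exceeds one, the maximum grid
#' sensitivity is returned with the criterion flagged as not triggered
#' (the curve then represents an upper bound of justifiable
#' sensitization rather than an interior optimum).
#'
#' On empirical curves the raw forward difference is noisy: the mean
#' alert curve is a step function driven by the enriched cohort's score
#' order statistics, and single-interval slopes spuriously exceed one
#' long before the true transition, especially in high-prevalence
#' subgroups. Since the exact linkage curve is convex whenever the
#' score likelihood ratio is monotone, the default estimator
#' (\code{method = "gcm"}) takes slopes from the greatest convex
#' minorant of the empirical curve (pool-adjacent-violators on the
#' forward differences), which irons out local jitter without any
#' bandwidth parameter and reduces to the raw forward differences on
#' any already-convex curve. \code{method = "forward"} uses the raw
#' differences.
#'
#' @param curve a \linkS4class{LinkageCurve}.
#' @param method slope estimator: \code{"gcm"} (convex-minorant,
#'   default) or \code{"forward"} (raw forward differences).
#' @return list with \code{target_sensitivity} (percent) and
#'   \code{criterion_triggered} (logical).
#' @export
findTargetSensitivity <- function(curve, method = c("gcm", "forward")) {
    stopifnot(is(curve, "LinkageCurve"))
    method <- match.arg(method)
    g <- curve@sens_grid
    if (is.unsorted(g, strictly = TRUE)) stop("sens_grid must be ascending")
    sl <- if (method == "gcm") .gcmSlopes(g, curve@mean_alert)
          else diff(curve@mean_alert) / diff(g)
    k <- which(sl > 1)[1L]
    if (is.na(k))
        list(target_sensitivity = g[length(g)], criterion_triggered = FALSE)
    else
        list(target_sensitivity = g[k], criterion_triggered = TRUE)
}

# Slopes of the greatest convex minorant: weighted pool-adjacent-
# violators on the forward-difference slopes (weights = grid spacing),
# expanded back to one slope per original grid interval.
.gcmSlopes <- function(s, A) {
    sl <- diff(A) / diff(s)
    w <- diff(s)
    vs <- vw <- numeric(0)
    vn <- integer(0)
    for (k in seq_along(sl)) {
        cs <- sl[k]; cw <- w[k]; cn <- 1L
        while (length(vs) && vs[length(vs)] > cs) {
            j <- length(vs)
            cs <- (cs * cw + vs[j] * vw[j]) / (cw + vw[j])
            cw <- cw + vw[j]
            cn <- cn + vn[j]
            vs <- vs[-j]; vw <- vw[-j]; vn <- vn[-j]
        }
        vs <- c(vs, cs); vw <- c(vw, cw); vn <- c(vn, cn)
    }
    rep(vs, times = vn)
}

#' Per-reader and aggregate optimized thresholds at a target sensitivity
#'
#' Inverts each reader's ROC curve at the common target sensitivity and
#' aggregates the per-reader thresholds by their arithmetic mean
#' (optionally the median) — the collective operating threshold the
#' reader panel implies.
#'
#' @param rocs list of per-reader \linkS4class{RocCurve}.
#' @param target_sensitivity percent in [0, 100].
#' @param aggregate \code{"mean"} (default) or \code{"median"}.
#' @return list with \code{per_reader_ot} (named numeric) and \code{ot}.
#' @export
deriveOt <- function(rocs, target_sensitivity, aggregate = c("mean", "median")) {
    aggregate <- match.arg(aggregate)
    if (is(rocs, "RocCurve")) rocs <- list(rocs)
    per <- vapply(rocs, function(r)
        as.numeric(thresholdForSensitivity(r, target_sensitivity)), numeric(1))
    names(per) <- vapply(rocs, function(r) r@reader_id, character(1))
    list(per_reader_ot = per,
         ot = if (aggregate == "mean") mean(per) else stats::median(per))
}

#' End-to-end subgroup-specific threshold optimization
#'
#' Composes the full pipeline for one pathology and clinical subgroup:
#' pool each reader's Likert ratings into a binary reference standard,
#' compute per-reader ROC curves on the enriched cohort, link achievable
#' sensitivities to clinical alert rates, find the slope-criterion
#' target sensitivity on the mean linkage curve, derive per-reader and
#' aggregate optimized thresholds, and measure the alert rate at the
#' aggregate OT. Per-reader Youden thresholds and the vendor default
#' threshold (AIDT) are recorded for comparison.
#'
#' @param enriched an \linkS4class{EnrichedCohort}.
#' @param clinical a \linkS4class{ClinicalCohort}.
#' @param subgroup clinical subgroup name.
#' @param pathology pathology name.
#' @param rfs reference-standard level (default the most sensitive,
#'   \code{"IV"}).
#' @param aidt vendor default threshold, \code{NA} when unknown.
#' @param sens_grid sensitivity grid in percent.
#' @param aggregate threshold aggregation, \code{"mean"} or
#'   \code{"median"}.
#' @param slope_method slope estimator for the criterion, see
#'   [findTargetSensitivity()].
#' @return an \linkS4class{OptimizationResult}.
#' @export
optimizeThreshold <- function(enriched, clinical, subgroup, pathology,
                              rfs = "IV", aidt = NA_real_,
                              sens_grid = seq(0, 100, by = 1),
                              aggregate = "mean", slope_method = "gcm") {
    stopifnot(is(enriched, "EnrichedCohort"), is(clinical, "ClinicalCohort"))
    stage <- function(what, expr) tryCatch(expr, error = function(e)
        stop("stage '", what, "': ", conditionMessage(e), call. = FALSE))
    rocs <- stage("roc_curve",
                  readerRocCurves(enriched, pathology, rfs))
    lk <- stage("linkage_curve",
                linkageCurve(rocs, clinical, subgroup, sens_grid))
    tgt <- stage("find_target_sensitivity",
                 findTargetSensitivity(lk, method = slope_method))
    ot <- stage("derive_ot",
                deriveOt(rocs, tgt$target_sensitivity, aggregate))
    alert <- stage("alert_rate",
                   alertRate(clinical, subgroup, pathology, ot$ot))
    youden <- vapply(rocs, function(r) youdenThreshold(r)[["threshold"]],
                     numeric(1))
    new("OptimizationResult", pathology = pathology, subgroup = subgroup,
        rfs = rfs, target_sensitivity = tgt$target_sensitivity,
        criterion_triggered = tgt$criterion_triggered,
        per_reader_ot = ot$per_reader_ot, ot = ot$ot,
        alert_at_ot = alert[["percent"]], aidt = as.numeric(aidt),
        youden_by_reader = youden, linkage = lk,
        slope_method = slope_method)
}
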