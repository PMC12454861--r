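#' Empirical ROC curve of AI scores against a binary reference
#'
#' Builds the full set of operating points by sweeping the candidate
#' thresholds (the unique observed scores plus a sentinel just above the
#' maximum, yielding the sensitivity-0/specificity-1 corner). A case is
#' called positive when its score is greater than or equal to the
#' threshold; tied scores collapse to a single operating point, so the
#' curve is the exact empirical step function with no interpolation.
#'
#' @param scores numeric AI scores in [0, 1].
#' @param labels binary reference labels (logical or 0/1), aligned to
#'   \code{scores}; both classes must be present.
#' @param reader_id,pathology,rfs identifiers carried into the result.
#' @return a \linkS4class{RocCurve}.
#' @examples
#' rc <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' rocAuc(rc)              # 1: perfect separation
#' youdenThreshold(rc)     # threshold 0.8, J = 1
#' @export
rocCurve <- function(scores, labels, reader_id = "reader",
                     pathology = "pathology", rfs = "IV") {
    stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
    labels <- as.logical(labels)
    n_pos <- sum(labels); n_neg <- sum(!labels)
    if (n_pos == 0L) stop("degenerate cohort: no positive cases in reference")
    if (n_neg == 0L) stop("degenerate cohort: no negative cases in reference")
    thr <- sort(unique(scores), decreasing = TRUE)
    # sentinel: smallest representable value above the maximum score
    sentinel <- max(scores) + max(.Machine$double.eps,
                                  abs(max(scores)) * .Machine$double.eps)
    thr <- c(sentinel, thr)
    # positive call iff score >= threshold; cumulative counts down the
    # sorted score list give exact tp/fp per candidate threshold
    ord <- order(scores, decreasing = TRUE)
    tp_cum <- cumsum(labels[ord])
    fp_cum <- cumsum(!labels[ord])
    # index of the last case with score >= each threshold
    n_at <- length(scores) -
        findInterval(thr, sort(scores), left.open = TRUE)
    tp <- ifelse(n_at == 0L, 0L, tp_cum[pmax(n_at, 1L)])
    fp <- ifelse(n_at == 0L, 0L, fp_cum[pmax(n_at, 1L)])
    sens <- tp / n_pos
    spec <- 1 - fp / n_neg
    pts <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec, youden_j = sens + spec - 1)
    auc <- .trapezoidAuc(pts$sensitivity, pts$specificity)
    new("RocCurve", reader_id = reader_id, pathology = pathology, rfs = rfs,
        points = pts, auc = auc, n_pos = as.integer(n_pos),
        n_neg = as.integer(n_neg))
}

# Trapezoid over (1 - specificity, sensitivity); with ties collapsed to
# single operating points this equals the Mann-Whitney statistic with
# ties counted one half.
.trapezoidAuc <- function(sens, spec) {
    fpr <- 1 - spec
    sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

#' Youden-optimal operating point
#'
#' Returns the threshold maximizing Youden's J = sensitivity +
#' specificity - 1. Among tied maximizers the highest threshold (the
#' most specific operating point, hence the fewest alerts) is returned.
#'
#' @param curve a \linkS4class{RocCurve}.
#' @return named numeric: \code{threshold} and \code{youden_j}.
#' @export
youdenThreshold <- function(curve) {
    stopifnot(is(curve, "RocCurve"))
    p <- curve@points
    # ties within floating-point noise count as ties; the first index
    # among them is the highest threshold
    best <- which(p$youden_j > max(p$youden_j) - 1e-12)[1L]
    c(threshold = p$threshold[best], youden_j = p$youden_j[best])
}

#' Least-sensitizing threshold achieving a target sensitivity
#'
#' The largest threshold whose sensitivity meets or exceeds the target,
#' i.e. the minimal amount of sensitization that achieves it on the
#' step-function ROC. The realized sensitivity at that threshold (the
#' next achievable operating point at or above the request) is attached
#' as an attribute.
#'
#' @param curve a \linkS4class{RocCurve}.
#' @param target_sens target sensitivity in percent, in [0, 100].
#' @return the threshold, with attribute \code{sensitivity} (realized,
#'   percent).
#' @export
thresholdForSensitivity <- function(curve, target_sens) {
    stopifnot(is(curve, "RocCurve"))
    if (is.na(target_sens) || target_sens < 0 || target_sens > 100)
        stop("target sensitivity must lie in [0, 100] percent")
    p <- curve@points
    k <- which(p$sensitivity * 100 >= target_sens - 1e-9)[1L]
    out <- p$threshold[k]
    attr(out, "sensitivity") <- 100 * p$sensitivity[k]
    out
}

#' Per-reader ROC curves for one pathology
#'
#' Convenience wrapper: pools each reader's Likert ratings under the
#' given reference-standard level and computes the six (or however
#' many) per-reader ROC curves of the AI score.
#'
#' @param cohort an \linkS4class{EnrichedCohort}.
#' @param pathology pathology name.
#' @param rfs reference-standard level (default \code{"IV"}).
#' @return named list of \linkS4class{RocCurve}, one per reader.
#' @export
readerRocCurves <- function(cohort, pathology, rfs = "IV") {
    sc <- aiScores(cohort, pathology)
    out <- lapply(readers(cohort), function(r) {
        lab <- buildReferenceStandard(cohort, r, pathology, rfs)
        rocCurve(sc, lab, reader_id = r, pathology = pathology, rfs = rfs)
    })
    stats::setNames(out, readers(cohort))
}
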