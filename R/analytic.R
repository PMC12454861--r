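#' Closed-form sensitivity and alert-rate curves for the score model
#'
#' For the Beta score mixtures of [genParams()] (and noise-free readers,
#' so reference labels equal the truth), the operating characteristics
#' have closed forms in the threshold t: sensitivity is the diseased
#' survival function \code{S1(t) = 1 - pbeta(t, a1, b1)} and the alert
#' rate in a subgroup with prevalence pi is
#' \code{A(t) = pi * S1(t) + (1 - pi) * S0(t)} with \code{S0} the healthy
#' survival function. These serve as exact oracles for the empirical
#' linkage pipeline.
#'
#' @param params a [genParams()] object.
#' @param pathology pathology name.
#' @param threshold numeric threshold(s) in [0, 1].
#' @return numeric fraction(s).
#' @name analytic-curves
NULL

#' @rdname analytic-curves
#' @export
analyticSensitivity <- function(params, pathology, threshold) {
    sh <- params$score_diseased[[pathology]]
    1 - stats::pbeta(threshold, sh[1], sh[2])
}

#' @rdname analytic-curves
#' @param subgroup clinical subgroup name (a column of
#'   \code{params$prev_subgroup}).
#' @export
analyticAlertRate <- function(params, subgroup, pathology, threshold) {
    pi <- params$prev_subgroup[pathology, subgroup]
    sh0 <- params$score_healthy[[pathology]]
    pi * analyticSensitivity(params, pathology, threshold) +
        (1 - pi) * (1 - stats::pbeta(threshold, sh0[1], sh0[2]))
}

#' Exact sensitivity-to-alert-rate linkage curve
#'
#' Evaluates, for each grid sensitivity, the threshold achieving it on
#' the diseased score distribution and the exact alert rate at that
#' threshold in the subgroup; the closed-form counterpart of
#' [linkageCurve()] under noise-free readers.
#'
#' @param params a [genParams()] object.
#' @param subgroup clinical subgroup name.
#' @param pathology pathology name (defaults to the first configured).
#' @param sens_grid ascending grid of sensitivities in percent.
#' @return data.frame with columns \code{sens_pct}, \code{threshold},
#'   \code{alert_pct}.
#' @export
analyticLinkage <- function(params, subgroup,
                            pathology = params$pathologies[1L],
                            sens_grid = seq(0, 100, by = 1)) {
    if (any(sens_grid < 0 | sens_grid > 100))
        stop("sens_grid must lie in [0, 100] percent")
    if (is.unsorted(sens_grid, strictly = TRUE))
        stop("sens_grid must be strictly ascending")
    sh1 <- params$score_diseased[[pathology]]
    thr <- stats::qbeta(1 - sens_grid / 100, sh1[1], sh1[2])
    data.frame(sens_pct = sens_grid, threshold = thr,
               alert_pct = 100 * analyticAlertRate(params, subgroup,
                                                   pathology, thr))
}

# First ascending grid index whose forward-difference slope of alert
# (percent) against sensitivity (percent) exceeds 1; NA when none does.
.firstSlopeExceeding <- function(sens_pct, alert_pct, limit = 1) {
    sl <- diff(alert_pct) / diff(sens_pct)
    k <- which(sl > limit)
    if (length(k)) k[1L] else NA_integer_
}

#' Ground-truth optimized threshold under the analytic model
#'
#' Applies the slope criterion to the exact linkage curve: scanning the
#' sensitivity grid upward, the target sensitivity is the first grid
#' point whose forward-difference slope of alert rate against
#' sensitivity exceeds one percent per percent. On the exact curve this
#' happens where the healthy score density first exceeds the diseased
#' density, so the trigger point is prevalence-independent while the
#' alert rate at the optimized threshold is not. When the slope never
#' exceeds one (e.g. perfectly separated score supports), the maximum
#' grid sensitivity is returned with \code{criterion_triggered = FALSE}.
#'
#' @inheritParams analyticLinkage
#' @param grid_step sensitivity grid step in percent.
#' @return list with \code{target_sensitivity}, \code{threshold},
#'   \code{alert_pct}, \code{criterion_triggered}.
#' @export
analyticOt <- function(params, subgroup,
                       pathology = params$pathologies[1L], grid_step = 1) {
    stopifnot(grid_step > 0, grid_step <= 100)
    grid <- seq(0, 100, by = grid_step)
    lk <- analyticLinkage(params, subgroup, pathology, grid)
    k <- .firstSlopeExceeding(lk$sens_pct, lk$alert_pct)
    triggered <- !is.na(k)
    if (!triggered) k <- nrow(lk)
    list(target_sensitivity = lk$sens_pct[k], threshold = lk$threshold[k],
         alert_pct = lk$alert_pct[k], criterion_triggered = triggered)
}
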