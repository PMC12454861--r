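#' Figure panels mirroring the pipeline's graphical report
#'
#' Base-graphics panels: per-reader ROC curves, the clinical score
#' histogram with threshold markers, per-reader alert bars at the
#' optimized thresholds, and the sensitivity-to-alert-rate linkage
#' curve with the slope-criterion target annotated.
#'
#' @name threshlink-plots
NULL

.readerCols <- function(n) grDevices::hcl.colors(max(n, 2L), "Dark 3")[seq_len(n)]

#' @rdname threshlink-plots
#' @param rocs named list of per-reader \linkS4class{RocCurve}.
#' @param result optional \linkS4class{OptimizationResult} whose target
#'   sensitivity is marked.
#' @export
plotRoc <- function(rocs, result = NULL) {
    if (is(rocs, "RocCurve")) rocs <- list(rocs)
    cols <- .readerCols(length(rocs))
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("%s (RFS %s)", rocs[[1L]]@pathology,
                                  rocs[[1L]]@rfs))
    graphics::abline(0, 1, col = "grey70", lty = 3)
    for (j in seq_along(rocs)) {
        p <- rocs[[j]]@points
        graphics::lines(1 - p$specificity, p$sensitivity, col = cols[j])
    }
    if (!is.null(result))
        graphics::abline(h = result@target_sensitivity / 100, lty = 2)
    graphics::legend("bottomright", bty = "n", cex = 0.7, col = cols, lwd = 1,
        legend = sprintf("%s AUC %.2f",
                         vapply(rocs, function(r) r@reader_id, character(1)),
                         vapply(rocs, rocAuc, numeric(1))))
    invisible(NULL)
}

#' @rdname threshlink-plots
#' @param clinical a \linkS4class{ClinicalCohort}.
#' @param subgroup subgroup name or \code{"overall"}.
#' @param pathology pathology name.
#' @param thresholds named numeric thresholds to mark.
#' @export
plotScoreHistogram <- function(clinical, subgroup, pathology,
                               thresholds = numeric()) {
    sc <- clinical@scores
    keep <- sc$pathology == pathology &
        (subgroup == "overall" | sc$subgroup == subgroup)
    x <- sc$ai_score[keep]
    graphics::hist(x, breaks = 50, col = "grey85", border = "white",
                   xlab = "AI score", main = sprintf("%s scores, %s",
                                                     pathology, subgroup))
    if (length(thresholds)) {
        cols <- c("black", "red3", "green4", .readerCols(length(thresholds)))
        for (i in seq_along(thresholds))
            graphics::abline(v = thresholds[i], col = cols[i], lwd = 2)
        graphics::legend("topright", bty = "n", cex = 0.7,
                         col = cols[seq_along(thresholds)], lwd = 2,
                         legend = sprintf("%s = %.3f", names(thresholds),
                                          thresholds))
    }
    invisible(NULL)
}

#' @rdname threshlink-plots
#' @export
plotAlertBars <- function(result) {
    stopifnot(is(result, "OptimizationResult"))
    lk <- result@linkage
    k <- match(result@target_sensitivity, lk@sens_grid)
    vals <- c(lk@per_reader_alert[k, ], mean = lk@mean_alert[k])
    cols <- c(.readerCols(ncol(lk@per_reader_alert)), "black")
    graphics::barplot(vals, col = cols, las = 2, cex.names = 0.7,
                      ylab = "alert rate (%)",
                      main = sprintf("positives at reader OTs, %s",
                                     result@subgroup))
    invisible(NULL)
}

#' @rdname threshlink-plots
#' @param curve a \linkS4class{LinkageCurve}.
#' @export
plotLinkage <- function(curve, result = NULL) {
    stopifnot(is(curve, "LinkageCurve"))
    if (ncol(curve@per_reader_alert) == 0L)
        stop("linkage curve has no readers")
    cols <- .readerCols(ncol(curve@per_reader_alert))
    graphics::plot(NA, xlim = c(0, 100), ylim = c(0, 100),
                   xlab = "achievable sensitivity (%)",
                   ylab = "clinical alert rate (%)",
                   main = sprintf("%s, %s (RFS %s)", curve@pathology,
                                  curve@subgroup, curve@rfs))
    for (j in seq_len(ncol(curve@per_reader_alert)))
        graphics::lines(curve@sens_grid, curve@per_reader_alert[, j],
                        col = cols[j], lty = 3)
    graphics::lines(curve@sens_grid, curve@mean_alert, lwd = 2)
    if (!is.null(result)) {
        graphics::points(result@target_sensitivity, .alertAtTarget(result),
                         pch = 19)
        graphics::legend("topleft", bty = "n", cex = 0.8, legend = sprintf(
            "target sens %.0f%%\nalert %.1f%%%s", result@target_sensitivity,
            .alertAtTarget(result),
            if (result@criterion_triggered) "" else "\n(criterion not triggered)"))
    }
    invisible(NULL)
}

.alertAtTarget <- function(result) {
    k <- match(result@target_sensitivity, result@linkage@sens_grid)
    result@linkage@mean_alert[k]
}

#' Render the linkage panel to a figure file
#'
#' Writes the sensitivity-to-alert-rate panel (per-reader dotted
#' curves, emphasized mean curve, annotated target sensitivity and
#' alert rate) as a PDF.
#'
#' @param curve a \linkS4class{LinkageCurve}.
#' @param result the matching \linkS4class{OptimizationResult}.
#' @param file output PDF path.
#' @return the file path, invisibly.
#' @export
renderLinkagePanel <- function(curve, result, file) {
    stopifnot(is(curve, "LinkageCurve"), is(result, "OptimizationResult"))
    if (curve@pathology != result@pathology ||
        curve@subgroup != result@subgroup)
        stop("curve and result refer to different pathology/subgroup")
    grDevices::pdf(file, width = 5, height = 5)
    on.exit(grDevices::dev.off())
    plotLinkage(curve, result)
    invisible(file)
}

#' @rdname threshlink-plots
#' @param results list of \linkS4class{OptimizationResult} per subgroup
#'   for one pathology.
#' @param file optional PDF path; plotted to the active device when NULL.
#' @export
plotThresholdComparison <- function(clinical, pathology, results,
                                    file = NULL) {
    if (!is.null(file)) {
        grDevices::pdf(file, width = 6, height = 4.5)
        on.exit(grDevices::dev.off())
    }
    thr <- c()
    for (sg in names(results)) {
        r <- results[[sg]]
        thr[paste0("OT_", sg)] <- r@ot
        if (!is.na(r@aidt)) thr["AIDT"] <- r@aidt
        thr[paste0("Youden_", sg)] <- mean(r@youden_by_reader)
    }
    plotScoreHistogram(clinical, "overall", pathology, thr)
    invisible(NULL)
}

.renderFourPanel <- function(rocs, clinical, res, file) {
    grDevices::pdf(file, width = 5, height = 14)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(4, 1), mar = c(4, 4, 2, 1))
    plotRoc(rocs, res)
    thr <- c(OT = res@ot, AIDT = res@aidt,
             Youden = unname(mean(res@youden_by_reader)))
    plotScoreHistogram(clinical, res@subgroup, res@pathology,
                       thr[!is.na(thr)])
    plotAlertBars(res)
    plotLinkage(res@linkage, res)
    invisible(file)
}
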