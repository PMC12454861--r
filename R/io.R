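#' Read and write the cohort CSV schemas
#'
#' Four UTF-8, header-row CSV schemas move cohorts in and out of the
#' pipeline: \code{enriched_scores.csv} (case_id, pathology, ai_score),
#' \code{readings.csv} (case_id, reader_id, pathology, likert),
#' \code{clinical_scores.csv} (case_id, subgroup, pathology, ai_score)
#' and \code{sample_reading.csv} (case_id, pathology,
#' reference_positive).
#'
#' @param scores_file,readings_file,clinical_file,sample_file CSV paths.
#' @return [readEnrichedCohort()] an \linkS4class{EnrichedCohort};
#'   [readClinicalCohort()] a \linkS4class{ClinicalCohort}.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
readEnrichedCohort <- function(scores_file, readings_file) {
    enrichedCohort(utils::read.csv(scores_file),
                   utils::read.csv(readings_file))
}

#' @rdname cohort-io
#' @export
readClinicalCohort <- function(clinical_file, sample_file = NULL) {
    sr <- if (!is.null(sample_file)) utils::read.csv(sample_file)
    clinicalCohort(utils::read.csv(clinical_file), sr)
}

#' @rdname cohort-io
#' @param x cohort to serialize.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return writers return the written paths, invisibly.
#' @export
writeEnrichedCohort <- function(x, dir, prefix = "enriched") {
    stopifnot(is(x, "EnrichedCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rd <- as.data.frame(rowData(x))
    lk <- assay(x, "likert")
    long <- data.frame(case_id = rep(rd$case_id, ncol(lk)),
                       reader_id = rep(colnames(lk), each = nrow(lk)),
                       pathology = rep(rd$pathology, ncol(lk)),
                       likert = as.vector(lk))
    paths <- c(file.path(dir, paste0(prefix, "_scores.csv")),
               file.path(dir, paste0(prefix, "_readings.csv")))
    utils::write.csv(rd[, c("case_id", "pathology", "ai_score")], paths[1L],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(long, paths[2L], row.names = FALSE, quote = FALSE)
    invisible(paths)
}

#' @rdname cohort-io
#' @export
writeClinicalCohort <- function(x, dir, prefix = "clinical") {
    stopifnot(is(x, "ClinicalCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, paste0(prefix, "_scores.csv"))
    utils::write.csv(as.data.frame(x@scores), paths, row.names = FALSE,
                     quote = FALSE)
    if (nrow(x@sampleReading)) {
        p2 <- file.path(dir, paste0(prefix, "_sample_reading.csv"))
        utils::write.csv(as.data.frame(x@sampleReading), p2,
                         row.names = FALSE, quote = FALSE)
        paths <- c(paths, p2)
    }
    invisible(paths)
}

#' Export per-reader ROC curves as CSV
#'
#' One row per operating point with columns reader_id, pathology, rfs,
#' threshold, sensitivity, specificity, youden_j.
#'
#' @param rocs a single \linkS4class{RocCurve} or a list of them.
#' @param file output CSV path.
#' @return the combined data.frame, invisibly.
#' @export
exportRoc <- function(rocs, file) {
    if (is(rocs, "RocCurve")) rocs <- list(rocs)
    df <- do.call(rbind, lapply(rocs, function(r)
        cbind(reader_id = r@reader_id, pathology = r@pathology, rfs = r@rfs,
              r@points)))
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(df)
}

#' Export a linkage curve as CSV
#'
#' Long format: pathology, subgroup, rfs, sens_target,
#' sens_realized_mean, reader_id, threshold, alert_pct, mean_alert_pct.
#'
#' @param curve a \linkS4class{LinkageCurve}.
#' @param file output CSV path.
#' @return the data.frame, invisibly.
#' @export
exportLinkage <- function(curve, file) {
    stopifnot(is(curve, "LinkageCurve"))
    g <- curve@sens_grid
    rdr <- colnames(curve@per_reader_alert)
    df <- data.frame(
        pathology = curve@pathology, subgroup = curve@subgroup,
        rfs = curve@rfs, sens_target = rep(g, length(rdr)),
        sens_realized_mean = rep(rowMeans(curve@per_reader_sens), length(rdr)),
        reader_id = rep(rdr, each = length(g)),
        threshold = as.vector(curve@per_reader_threshold),
        alert_pct = as.vector(curve@per_reader_alert),
        mean_alert_pct = rep(curve@mean_alert, length(rdr)))
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(df)
}

#' Serialize an OptimizationResult to JSON
#'
#' @param x an \linkS4class{OptimizationResult}.
#' @param file optional path; when given the JSON is written there.
#' @return the result as a plain list (also the JSON payload), invisibly
#'   when written.
#' @export
optimizationAsList <- function(x, file = NULL) {
    stopifnot(is(x, "OptimizationResult"))
    out <- list(pathology = x@pathology, subgroup = x@subgroup, rfs = x@rfs,
                target_sensitivity_pct = x@target_sensitivity,
                criterion_triggered = x@criterion_triggered,
                ot = x@ot, per_reader_ot = as.list(x@per_reader_ot),
                alert_at_ot_pct = x@alert_at_ot, aidt = x@aidt,
                youden_by_reader = as.list(x@youden_by_reader))
    if (!is.null(file)) {
        jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                             na = "null")
        return(invisible(out))
    }
    out
}
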