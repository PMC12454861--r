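#' Construct an EnrichedCohort from tabular scores and readings
#'
#' Assembles the pathology-enriched validation cohort from its two
#' tables: per-(case, pathology) AI confidence scores and
#' per-(case, reader, pathology) 5-point Likert ratings. Every
#' (case, pathology) pair must carry a score and a rating from every
#' reader; missing cells are hard errors, not imputed.
#'
#' @param scores data.frame with columns \code{case_id}, \code{pathology},
#'   \code{ai_score}.
#' @param readings data.frame with columns \code{case_id}, \code{reader_id},
#'   \code{pathology}, \code{likert}.
#' @return an \linkS4class{EnrichedCohort}. Readers are ordered as first
#'   encountered in \code{readings}.
#' @examples
#' sc <- data.frame(case_id = c("a", "b"), pathology = "nodule",
#'                  ai_score = c(0.8, 0.1))
#' rd <- expand.grid(case_id = c("a", "b"), reader_id = c("R1", "R2"),
#'                   pathology = "nodule", stringsAsFactors = FALSE)
#' rd$likert <- c(4L, 0L, 3L, 1L)
#' enrichedCohort(sc, rd)
#' @export
enrichedCohort <- function(scores, readings) {
    scores <- as.data.frame(scores)
    readings <- as.data.frame(readings)
    .checkCols(scores, c("case_id", "pathology", "ai_score"), "scores")
    .checkCols(readings, c("case_id", "reader_id", "pathology", "likert"),
               "readings")
    bad <- !readings$likert %in% 0:4
    if (any(bad))
        stop("likert out of range 0..4 for case(s): ",
             paste(unique(readings$case_id[bad]), collapse = ", "))
    rdr <- unique(as.character(readings$reader_id))
    key <- paste(scores$case_id, scores$pathology, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicated (case_id, pathology) in scores")
    rkey <- paste(readings$case_id, readings$pathology, sep = "\r")
    lk <- matrix(NA_integer_, nrow(scores), length(rdr),
                 dimnames = list(key, rdr))
    idx <- cbind(match(rkey, key), match(as.character(readings$reader_id), rdr))
    if (anyNA(idx[, 1L]))
        stop("readings refer to (case, pathology) pairs absent from scores")
    if (anyDuplicated(idx))
        stop("duplicated (case_id, reader_id, pathology) ratings")
    lk[idx] <- as.integer(readings$likert)
    if (anyNA(lk)) {
        miss <- which(is.na(lk), arr.ind = TRUE)
        stop("missing rating cell(s), e.g. case/pathology '",
             rownames(lk)[miss[1L, 1L]], "' reader '",
             colnames(lk)[miss[1L, 2L]], "'")
    }
    se <- SummarizedExperiment(
        assays = list(likert = lk),
        rowData = DataFrame(case_id = as.character(scores$case_id),
                            pathology = as.character(scores$pathology),
                            ai_score = as.numeric(scores$ai_score)),
        colData = DataFrame(reader_id = rdr, row.names = rdr))
    rownames(se) <- gsub("\r", ":", key, fixed = TRUE)
    new("EnrichedCohort", se)
}

#' Construct a ClinicalCohort
#'
#' @param scores data.frame with columns \code{case_id}, \code{subgroup},
#'   \code{pathology}, \code{ai_score}.
#' @param sample_reading optional data.frame with columns \code{case_id},
#'   \code{pathology}, \code{reference_positive} (0/1) for the expert-read
#'   subset; defaults to none.
#' @return a \linkS4class{ClinicalCohort}.
#' @export
clinicalCohort <- function(scores, sample_reading = NULL) {
    scores <- as.data.frame(scores)
    .checkCols(scores, c("case_id", "subgroup", "pathology", "ai_score"),
               "scores")
    if (is.null(sample_reading))
        sample_reading <- data.frame(case_id = character(),
                                     pathology = character(),
                                     reference_positive = integer())
    sample_reading <- as.data.frame(sample_reading)
    new("ClinicalCohort",
        scores = DataFrame(case_id = as.character(scores$case_id),
                           subgroup = as.character(scores$subgroup),
                           pathology = as.character(scores$pathology),
                           ai_score = as.numeric(scores$ai_score)),
        sampleReading = DataFrame(
            case_id = as.character(sample_reading$case_id),
            pathology = as.character(sample_reading$pathology),
            reference_positive = as.integer(sample_reading$reference_positive)))
}

.checkCols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
    invisible(TRUE)
}

#' @describeIn EnrichedCohort-class reader identifiers, in reading order.
#' @export
setMethod("readers", "EnrichedCohort", function(x) colnames(x))

#' @describeIn EnrichedCohort-class pathologies present in the cohort.
#' @export
setMethod("pathologies", "EnrichedCohort",
    function(x) unique(rowData(x)$pathology))

#' @describeIn ClinicalCohort-class pathologies scored in the cohort.
#' @export
setMethod("pathologies", "ClinicalCohort",
    function(x) unique(x@scores$pathology))

#' @describeIn EnrichedCohort-class AI scores, named by case, optionally
#'   restricted to one pathology.
#' @export
setMethod("aiScores", "EnrichedCohort", function(x, pathology = NULL) {
    rd <- rowData(x)
    keep <- if (is.null(pathology)) rep(TRUE, nrow(rd))
            else rd$pathology == pathology
    stats::setNames(rd$ai_score[keep], rd$case_id[keep])
})

#' @describeIn ClinicalCohort-class AI scores, named by case, optionally
#'   restricted to one pathology.
#' @export
setMethod("aiScores", "ClinicalCohort", function(x, pathology = NULL) {
    sc <- x@scores
    keep <- if (is.null(pathology)) rep(TRUE, nrow(sc))
            else sc$pathology == pathology
    stats::setNames(sc$ai_score[keep], sc$case_id[keep])
})

#' @describeIn ClinicalCohort-class named character vector mapping case_id
#'   to subgroup (one entry per case).
#' @export
setMethod("subgroups", "ClinicalCohort", function(x) {
    sc <- x@scores
    first <- !duplicated(sc$case_id)
    stats::setNames(sc$subgroup[first], sc$case_id[first])
})

#' @describeIn ClinicalCohort-class the expert-read subset as a DataFrame.
#' @export
setMethod("sampleReading", "ClinicalCohort", function(x) x@sampleReading)

setMethod("show", "ClinicalCohort", function(object) {
    sg <- subgroups(object)
    cat("ClinicalCohort with", length(sg), "cases,",
        length(pathologies(object)), "pathologies\n")
    print(table(sg))
    cat(nrow(object@sampleReading), "sample-reading rows\n")
})

setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve [%s | %s | RFS %s]: %d operating points, AUC %.3f (%d+/%d-)\n",
                object@reader_id, object@pathology, object@rfs,
                nrow(object@points), object@auc, object@n_pos, object@n_neg))
})

setMethod("show", "LinkageCurve", function(object) {
    cat(sprintf("LinkageCurve [%s | %s | RFS %s]: %d grid points, %d readers\n",
                object@pathology, object@subgroup, object@rfs,
                length(object@sens_grid), ncol(object@per_reader_alert)))
})

setMethod("show", "OptimizationResult", function(object) {
    cat(sprintf("OptimizationResult [%s | %s | RFS %s]\n", object@pathology,
                object@subgroup, object@rfs))
    cat(sprintf("  target sensitivity %.1f%% (criterion %s)\n",
                object@target_sensitivity,
                if (object@criterion_triggered) "triggered" else "not triggered"))
    cat(sprintf("  OT %.4f, alert rate at OT %.1f%%, AIDT %s\n", object@ot,
                object@alert_at_ot,
                if (is.na(object@aidt)) "-" else sprintf("%.4f", object@aidt)))
})

setMethod("show", "ConfusionTable", function(object) {
    m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2L, 2L,
                dimnames = list(call = c("positive", "negative"),
                                reference = c("positive", "negative")))
    cat("ConfusionTable (n =", sum(m), ")\n")
    print(m)
    if (length(object@note) && nzchar(object@note[1L]))
        cat("note:", object@note, "\n")
})

#' @describeIn RocCurve-class operating points as a data.frame.
#' @export
setMethod("rocPoints", "RocCurve", function(x) x@points)

#' @describeIn RocCurve-class area under the curve.
#' @export
setMethod("rocAuc", "RocCurve", function(x) x@auc)

#' @describeIn LinkageCurve-class the target-sensitivity grid (percent).
#' @export
setMethod("sensGrid", "LinkageCurve", function(x) x@sens_grid)

#' @describeIn LinkageCurve-class mean alert rate (percent) per grid point.
#' @export
setMethod("meanAlert", "LinkageCurve", function(x) x@mean_alert)

#' @describeIn OptimizationResult-class target sensitivity in percent.
#' @export
setMethod("targetSensitivity", "OptimizationResult",
    function(x) x@target_sensitivity)

#' @describeIn OptimizationResult-class whether the slope criterion fired.
#' @export
setMethod("criterionTriggered", "OptimizationResult",
    function(x) x@criterion_triggered)

#' @describeIn OptimizationResult-class the aggregate optimized threshold.
#' @export
setMethod("optimizedThreshold", "OptimizationResult", function(x) x@ot)

#' Construct a ConfusionTable
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param note optional character annotation (used by [reconstructTable()]
#'   to flag ambiguous cells).
#' @return a \linkS4class{ConfusionTable}.
#' @export
confusionTable <- function(tp, fp, fn, tn, note = character()) {
    new("ConfusionTable", tp = as.integer(tp), fp = as.integer(fp),
        fn = as.integer(fn), tn = as.integer(tn), note = note)
}

#' @describeIn ConfusionTable-class counts as a named integer vector
#'   (tp, fp, fn, tn).
#' @export
setMethod("counts2x2", "ConfusionTable", function(x)
    c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))
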