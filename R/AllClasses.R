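#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importClassesFrom S4Vectors Annotated DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.PATHOLOGIES <- c("pleural_effusion", "consolidation", "pneumothorax", "nodule")
.SUBGROUPS   <- c("inpatient", "outpatient", "other")
.RFS_LEVELS  <- c(I = 4L, II = 3L, III = 2L, IV = 1L)

#' EnrichedCohort: pathology-enriched validation cohort
#'
#' Container for a pathology-enriched validation cohort: one row per
#' (case, pathology) pair, one column per reference reader. The single
#' \code{"likert"} assay holds the readers' 0--4 suspicion ratings
#' (0 no suspicion, 1 unlikely, 2 possible, 3 likely, 4 certain) and
#' \code{rowData} carries the AI confidence score in [0, 1] for each
#' (case, pathology) pair.
#'
#' @slot ... inherits all slots from \linkS4class{SummarizedExperiment};
#'   \code{rowData} must contain \code{case_id}, \code{pathology} and
#'   \code{ai_score} columns.
#'
#' @seealso [enrichedCohort()] (constructor), [genEnrichedCohort()]
#' @export
setClass("EnrichedCohort", contains = "SummarizedExperiment")

setValidity("EnrichedCohort", function(object) {
    msg <- character()
    rd <- rowData(object)
    need <- c("case_id", "pathology", "ai_score")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain columns:", paste(need, collapse = ", ")))
    if (!"likert" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'likert' is required")
    if (ncol(object) < 1L)
        msg <- c(msg, "at least one reader is required")
    key <- paste(rd$case_id, rd$pathology)
    if (anyDuplicated(key))
        msg <- c(msg, "duplicated (case_id, pathology) rows")
    sc <- rd$ai_score
    if (anyNA(sc) || any(sc < 0 | sc > 1))
        msg <- c(msg, "ai_score must lie in [0, 1] with no missing values")
    lk <- assay(object, "likert")
    if (anyNA(lk) || !all(lk %in% 0:4))
        msg <- c(msg, "likert ratings must be integers in 0..4 with no missing cells")
    if (length(msg)) msg else TRUE
})

#' ClinicalCohort: consecutive clinical-routine cohort
#'
#' Scored clinical-routine cases with a subgroup label per case
#' (inpatient / outpatient / other) and an optional expert sample
#' reading: a binary reference label for a random subset of
#' (case, pathology) pairs, mirroring a small targeted expert read of a
#' large routine cohort.
#'
#' @slot scores DataFrame with columns \code{case_id}, \code{subgroup},
#'   \code{pathology}, \code{ai_score}.
#' @slot sampleReading DataFrame with columns \code{case_id},
#'   \code{pathology}, \code{reference_positive} (0/1); may have zero rows.
#'
#' @seealso [clinicalCohort()] (constructor), [genClinicalCohort()]
#' @export
setClass("ClinicalCohort",
    representation(scores = "DataFrame", sampleReading = "DataFrame"),
    contains = "Annotated")

setValidity("ClinicalCohort", function(object) {
    msg <- character()
    sc <- object@scores
    need <- c("case_id", "subgroup", "pathology", "ai_score")
    if (!all(need %in% colnames(sc)))
        return(paste("scores must contain columns:", paste(need, collapse = ", ")))
    if (!all(sc$subgroup %in% .SUBGROUPS))
        msg <- c(msg, paste("subgroup must be one of:", paste(.SUBGROUPS, collapse = ", ")))
    if (anyDuplicated(paste(sc$case_id, sc$pathology)))
        msg <- c(msg, "duplicated (case_id, pathology) score rows")
    if (anyNA(sc$ai_score) || any(sc$ai_score < 0 | sc$ai_score > 1))
        msg <- c(msg, "ai_score must lie in [0, 1]")
    sr <- object@sampleReading
    if (nrow(sr)) {
        needr <- c("case_id", "pathology", "reference_positive")
        if (!all(needr %in% colnames(sr)))
            return(paste("sampleReading must contain columns:",
                         paste(needr, collapse = ", ")))
        if (!all(sr$case_id %in% sc$case_id))
            msg <- c(msg, "sampleReading case_ids must be cohort case_ids")
        if (!all(sr$reference_positive %in% c(0L, 1L)))
            msg <- c(msg, "reference_positive must be 0/1")
    }
    if (length(msg)) msg else TRUE
})

#' RocCurve: empirical ROC curve for one reader reference standard
#'
#' Operating points of the AI score against one reader's pooled binary
#' reference standard. Points are ordered by decreasing threshold
#' (increasing sensitivity); a case is called positive when its score is
#' greater than or equal to the threshold. The first point sits at a
#' sentinel threshold above the maximum observed score (sensitivity 0,
#' specificity 1); tied scores collapse to a single operating point.
#'
#' @slot reader_id,pathology,rfs character identifiers.
#' @slot points data.frame with columns \code{threshold},
#'   \code{sensitivity}, \code{specificity}, \code{youden_j}.
#' @slot auc numeric; trapezoidal area under the curve (equals the
#'   Mann-Whitney statistic with ties counted 1/2).
#' @slot n_pos,n_neg integer class counts.
#'
#' @seealso [rocCurve()], [youdenThreshold()], [thresholdForSensitivity()]
#' @export
setClass("RocCurve",
    representation(reader_id = "character", pathology = "character",
                   rfs = "character", points = "data.frame",
                   auc = "numeric", n_pos = "integer", n_neg = "integer"))

setValidity("RocCurve", function(object) {
    p <- object@points
    msg <- character()
    if (!all(c("threshold", "sensitivity", "specificity", "youden_j") %in% names(p)))
        return("points must have threshold, sensitivity, specificity, youden_j")
    if (is.unsorted(rev(p$threshold), strictly = TRUE))
        msg <- c(msg, "thresholds must strictly decrease")
    if (is.unsorted(p$sensitivity))
        msg <- c(msg, "sensitivity must be non-decreasing")
    if (is.unsorted(rev(p$specificity)))
        msg <- c(msg, "specificity must be non-increasing")
    if (nrow(p)) {
        if (p$sensitivity[1L] != 0 || p$specificity[1L] != 1)
            msg <- c(msg, "first point must have sensitivity 0, specificity 1")
        if (p$sensitivity[nrow(p)] != 1 || p$specificity[nrow(p)] != 0)
            msg <- c(msg, "last point must have sensitivity 1, specificity 0")
    }
    if (any(p$youden_j < -1 | p$youden_j > 1))
        msg <- c(msg, "Youden J out of [-1, 1]")
    if (object@n_pos < 1L || object@n_neg < 1L)
        msg <- c(msg, "both classes must be represented")
    if (length(msg)) msg else TRUE
})

#' LinkageCurve: sensitivity-to-alert-rate linkage in a clinical subgroup
#'
#' For an ascending grid of target sensitivities (percent), the
#' per-reader thresholds that achieve them on the enriched cohort, the
#' sensitivities actually realized on the step-function ROC, and the
#' resulting alert rates (percent of subgroup cases at or above the
#' threshold) in a clinical subgroup, together with the across-reader
#' mean alert curve that drives threshold optimization.
#'
#' @slot pathology,subgroup,rfs character identifiers.
#' @slot sens_grid ascending numeric grid of target sensitivities (percent).
#' @slot per_reader_alert,per_reader_threshold,per_reader_sens numeric
#'   matrices, one row per grid point, one column per reader.
#' @slot mean_alert numeric; pointwise arithmetic mean of per-reader alert
#'   rates (percent).
#'
#' @seealso [linkageCurve()], [findTargetSensitivity()]
#' @export
setClass("LinkageCurve",
    representation(pathology = "character", subgroup = "character",
                   rfs = "character", sens_grid = "numeric",
                   per_reader_alert = "matrix", per_reader_threshold = "matrix",
                   per_reader_sens = "matrix", mean_alert = "numeric"))

setValidity("LinkageCurve", function(object) {
    msg <- character()
    g <- object@sens_grid
    if (length(g) < 2L || is.unsorted(g, strictly = TRUE))
        msg <- c(msg, "sens_grid must be strictly ascending with >= 2 points")
    if (any(g < 0 | g > 100))
        msg <- c(msg, "sens_grid must lie in [0, 100]")
    A <- object@per_reader_alert
    if (nrow(A) != length(g))
        msg <- c(msg, "per_reader_alert rows must match sens_grid")
    if (ncol(A) >= 1L && any(apply(A, 2L, is.unsorted)))
        msg <- c(msg, "per-reader alert rates must be non-decreasing in sensitivity")
    if (max(abs(object@mean_alert - rowMeans(A))) > 1e-8)
        msg <- c(msg, "mean_alert must be the mean of per-reader alert rates")
    if (length(msg)) msg else TRUE
})

#' OptimizationResult: slope-criterion threshold for one subgroup
#'
#' The outcome of applying the slope criterion to a linkage curve: the
#' target sensitivity at which one more percentage point of sensitivity
#' first costs more than one percentage point of alert rate, the
#' per-reader thresholds achieving it, their aggregate (the optimized
#' threshold, OT), the alert rate at the OT, and the vendor-default
#' (AIDT) and per-reader Youden thresholds for comparison. When the
#' criterion never triggers, the maximum grid sensitivity is returned
#' with \code{criterion_triggered = FALSE}.
#'
#' @slot pathology,subgroup,rfs character identifiers.
#' @slot target_sensitivity percent in [0, 100].
#' @slot criterion_triggered logical.
#' @slot per_reader_ot named numeric thresholds.
#' @slot ot aggregate optimized threshold in [0, 1].
#' @slot alert_at_ot alert rate (percent) at the aggregate OT.
#' @slot aidt vendor default threshold (NA when not configured).
#' @slot youden_by_reader named numeric Youden thresholds.
#' @slot linkage the \linkS4class{LinkageCurve} the result was derived from.
#' @slot slope_method slope estimator used (\code{"gcm"} or
#'   \code{"forward"}), see [findTargetSensitivity()].
#'
#' @seealso [optimizeThreshold()], [deriveOt()]
#' @export
setClass("OptimizationResult",
    representation(pathology = "character", subgroup = "character",
                   rfs = "character", target_sensitivity = "numeric",
                   criterion_triggered = "logical", per_reader_ot = "numeric",
                   ot = "numeric", alert_at_ot = "numeric", aidt = "numeric",
                   youden_by_reader = "numeric", linkage = "LinkageCurve",
                   slope_method = "character"))

setValidity("OptimizationResult", function(object) {
    msg <- character()
    if (object@target_sensitivity < 0 || object@target_sensitivity > 100)
        msg <- c(msg, "target_sensitivity must lie in [0, 100]")
    if (object@ot < 0 || object@ot > 1 + 1e-9)
        msg <- c(msg, "ot must lie in [0, 1] (sentinel excepted)")
    lk <- object@linkage
    k <- match(object@target_sensitivity, lk@sens_grid)
    if (object@criterion_triggered && !is.na(k) && k > 1L) {
        sl <- if (identical(object@slope_method, "forward"))
            diff(lk@mean_alert) / diff(lk@sens_grid)
        else .gcmSlopes(lk@sens_grid, lk@mean_alert)
        if (any(sl[seq_len(k - 1L)] > 1 + 1e-9))
            msg <- c(msg, "slopes below the target must be <= 1")
    }
    if (length(msg)) msg else TRUE
})

#' ConfusionTable: integer 2x2 diagnostic contingency table
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @slot note character; reconstruction notes such as ambiguity flags.
#'
#' @seealso [confusionTable()], [diagnosticMetrics()], [reconstructTable()]
#' @export
setClass("ConfusionTable",
    representation(tp = "integer", fp = "integer", fn = "integer",
                   tn = "integer", note = "character"))

setValidity("ConfusionTable", function(object) {
    counts <- c(object@tp, object@fp, object@fn, object@tn)
    if (any(is.na(counts)) || any(counts < 0L))
        "counts must be non-negative integers" else TRUE
})
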