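#' @rdname EnrichedCohort-class
#' @param x an object.
#' @export
setGeneric("readers", function(x) standardGeneric("readers"))

#' @rdname EnrichedCohort-class
#' @export
setGeneric("pathologies", function(x) standardGeneric("pathologies"))

#' @rdname EnrichedCohort-class
#' @param pathology optional pathology to restrict to.
#' @export
setGeneric("aiScores", function(x, pathology = NULL) standardGeneric("aiScores"))

#' @rdname ClinicalCohort-class
#' @param x an object.
#' @export
setGeneric("subgroups", function(x) standardGeneric("subgroups"))

#' @rdname ClinicalCohort-class
#' @export
setGeneric("sampleReading", function(x) standardGeneric("sampleReading"))

#' @rdname RocCurve-class
#' @param x an object.
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname RocCurve-class
#' @export
setGeneric("rocAuc", function(x) standardGeneric("rocAuc"))

#' @rdname LinkageCurve-class
#' @param x an object.
#' @export
setGeneric("sensGrid", function(x) standardGeneric("sensGrid"))

#' @rdname LinkageCurve-class
#' @export
setGeneric("meanAlert", function(x) standardGeneric("meanAlert"))

#' @rdname OptimizationResult-class
#' @param x an object.
#' @export
setGeneric("targetSensitivity", function(x) standardGeneric("targetSensitivity"))

#' @rdname OptimizationResult-class
#' @export
setGeneric("criterionTriggered", function(x) standardGeneric("criterionTriggered"))

#' @rdname OptimizationResult-class
#' @export
setGeneric("optimizedThreshold", function(x) standardGeneric("optimizedThreshold"))

#' @rdname ConfusionTable-class
#' @param x an object.
#' @export
setGeneric("counts2x2", function(x) standardGeneric("counts2x2"))
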