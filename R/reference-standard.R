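#' Reference-standard levels for pooled Likert ratings
#'
#' The four nested binary reference standards (RFS I--IV) pool a 0--4
#' Likert suspicion rating into a binary label. RFS I is the most
#' specific (only "certain", rating 4, counts as positive); RFS IV is
#' the most sensitive ("unlikely" and above, ratings 1--4, count as
#' positive); RFS II and III sit in between at ratings >= 3 and >= 2,
#' the only monotone completion of those endpoints.
#'
#' @param rfs one of \code{"I"}, \code{"II"}, \code{"III"}, \code{"IV"}.
#' @return the minimum Likert rating counted as positive (4, 3, 2, 1).
#' @examples
#' rfsMinPositive("I")   # 4
#' rfsMinPositive("IV")  # 1
#' @export
rfsMinPositive <- function(rfs) {
    rfs <- match.arg(as.character(rfs), names(.RFS_LEVELS))
    .RFS_LEVELS[[rfs]]
}

#' Pool a Likert rating into a binary label
#'
#' @param likert integer rating(s) in 0..4.
#' @param rfs reference-standard level, see [rfsMinPositive()].
#' @param case_id optional identifier(s) used in error messages.
#' @return logical vector: \code{TRUE} iff \code{likert >=
#'   rfsMinPositive(rfs)}.
#' @examples
#' poolLikert(4, "I")            # TRUE: only certain findings
#' poolLikert(0:4, "IV")         # FALSE TRUE TRUE TRUE TRUE
#' @export
poolLikert <- function(likert, rfs, case_id = NULL) {
    bad <- is.na(likert) | !likert %in% 0:4
    if (any(bad)) {
        lab <- if (!is.null(case_id)) paste(unique(case_id[bad]), collapse = ", ")
               else paste(which(bad), collapse = ", ")
        stop("likert rating out of range 0..4 for: ", lab)
    }
    likert >= rfsMinPositive(rfs)
}

#' Build one reader's binary reference standard
#'
#' Pools one reader's Likert ratings for one pathology into a binary
#' label per case, under the requested reference-standard level. The
#' resulting prevalence is attached as an attribute.
#'
#' @param cohort an \linkS4class{EnrichedCohort}.
#' @param reader_id one of \code{readers(cohort)}.
#' @param pathology one of \code{pathologies(cohort)}.
#' @param rfs reference-standard level, default the most sensitive
#'   (\code{"IV"}).
#' @return named logical vector (one element per case, names are
#'   case_ids) with attribute \code{prevalence} (fraction positive).
#' @export
buildReferenceStandard <- function(cohort, reader_id, pathology, rfs = "IV") {
    stopifnot(is(cohort, "EnrichedCohort"))
    if (!reader_id %in% readers(cohort))
        stop("unknown reader: ", reader_id)
    if (!pathology %in% pathologies(cohort))
        stop("unknown pathology: ", pathology)
    rd <- rowData(cohort)
    keep <- rd$pathology == pathology
    lk <- assay(cohort, "likert")[keep, reader_id]
    lab <- poolLikert(lk, rfs, case_id = rd$case_id[keep])
    names(lab) <- rd$case_id[keep]
    attr(lab, "prevalence") <- mean(lab)
    lab
}

#' Declare per-pathology analysis configuration
#'
#' @param pathology character vector of pathology names.
#' @param aidt vendor default thresholds in [0, 1], recycled to length.
#' @param rfs reference-standard level(s), recycled.
#' @return data.frame with columns \code{pathology}, \code{aidt},
#'   \code{rfs}, one row per pathology.
#' @examples
#' pathologyConfig(c("pleural_effusion", "nodule"), aidt = c(0.145, 0.089))
#' @export
pathologyConfig <- function(pathology, aidt = NA_real_, rfs = "IV") {
    if (any(!is.na(aidt) & (aidt < 0 | aidt > 1)))
        stop("aidt thresholds must lie in [0, 1]")
    rfs <- vapply(rep_len(as.character(rfs), length(pathology)),
                  function(r) match.arg(r, names(.RFS_LEVELS)), character(1))
    data.frame(pathology = as.character(pathology),
               aidt = rep_len(as.numeric(aidt), length(pathology)),
               rfs = unname(rfs))
}

#' Validate cohorts against the pipeline's schema invariants
#'
#' Collects (rather than throws) findings: duplicate keys, out-of-range
#' scores or ratings, subgroup labels outside the known set, missing
#' rating cells, and configured pathologies absent from the data. An
#' empty report means every invariant holds.
#'
#' @param enriched an \linkS4class{EnrichedCohort} or a list with raw
#'   \code{scores} / \code{readings} data.frames (checked pre-construction).
#' @param clinical a \linkS4class{ClinicalCohort} or a raw \code{scores}
#'   data.frame.
#' @param configs optional data.frame from [pathologyConfig()].
#' @return data.frame with columns \code{scope}, \code{finding},
#'   \code{detail}; zero rows iff the inputs are well formed.
#' @export
validateCohorts <- function(enriched = NULL, clinical = NULL, configs = NULL) {
    rep <- list()
    add <- function(scope, finding, detail)
        rep[[length(rep) + 1L]] <<- data.frame(scope = scope, finding = finding,
                                               detail = detail)
    if (!is.null(enriched)) {
        if (is(enriched, "EnrichedCohort")) {
            sc <- as.data.frame(rowData(enriched))
        } else {
            sc <- as.data.frame(enriched$scores)
            rd <- as.data.frame(enriched$readings)
            bad <- !rd$likert %in% 0:4
            if (any(bad))
                add("enriched", "likert_out_of_range",
                    paste(unique(rd$case_id[bad]), collapse = ", "))
            cell <- paste(rd$case_id, rd$reader_id, rd$pathology)
            if (anyDuplicated(cell))
                add("enriched", "duplicate_rating",
                    paste(unique(cell[duplicated(cell)]), collapse = ", "))
            want <- expand.grid(key = unique(paste(sc$case_id, sc$pathology)),
                                reader = unique(rd$reader_id))
            have <- paste(rd$case_id, rd$pathology)
            miss <- !paste(want$key) %in% have
            if (length(unique(rd$reader_id)) &&
                !all(paste(want$key, want$reader) %in%
                     paste(have, rd$reader_id)))
                add("enriched", "missing_rating_cell",
                    "not every (case, reader, pathology) cell is rated")
            if (any(miss))
                add("enriched", "unrated_case",
                    paste(unique(want$key[miss]), collapse = ", "))
        }
        key <- paste(sc$case_id, sc$pathology)
        if (anyDuplicated(key))
            add("enriched", "duplicate_score_key",
                paste(unique(key[duplicated(key)]), collapse = ", "))
        oob <- is.na(sc$ai_score) | sc$ai_score < 0 | sc$ai_score > 1
        if (any(oob))
            add("enriched", "score_out_of_range",
                paste(unique(sc$case_id[oob]), collapse = ", "))
    }
    if (!is.null(clinical)) {
        sc <- if (is(clinical, "ClinicalCohort")) as.data.frame(clinical@scores)
              else as.data.frame(clinical)
        key <- paste(sc$case_id, sc$pathology)
        if (anyDuplicated(key))
            add("clinical", "duplicate_score_key",
                paste(unique(key[duplicated(key)]), collapse = ", "))
        oob <- is.na(sc$ai_score) | sc$ai_score < 0 | sc$ai_score > 1
        if (any(oob))
            add("clinical", "score_out_of_range",
                paste(unique(sc$case_id[oob]), collapse = ", "))
        if (!is.null(sc$subgroup)) {
            badg <- !sc$subgroup %in% .SUBGROUPS
            if (any(badg))
                add("clinical", "unknown_subgroup",
                    paste(unique(sc$subgroup[badg]), collapse = ", "))
        } else add("clinical", "missing_column", "subgroup")
        if (is(clinical, "ClinicalCohort")) {
            sr <- clinical@sampleReading
            if (nrow(sr) && !all(sr$case_id %in% sc$case_id))
                add("clinical", "sample_reading_orphan",
                    "sample_reading case_ids outside cohort")
        }
    }
    if (!is.null(configs)) {
        bad <- !is.na(configs$aidt) & (configs$aidt < 0 | configs$aidt > 1)
        if (any(bad))
            add("config", "aidt_out_of_range",
                paste(configs$pathology[bad], collapse = ", "))
        for (obj in list(enriched, clinical)) {
            if (is(obj, "EnrichedCohort") || is(obj, "ClinicalCohort")) {
                miss <- setdiff(configs$pathology, pathologies(obj))
                if (length(miss))
                    add("config", "pathology_not_in_cohort",
                        paste(miss, collapse = ", "))
            }
        }
    }
    if (length(rep)) do.call(rbind, rep)
    else data.frame(scope = character(), finding = character(),
                    detail = character())
}
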