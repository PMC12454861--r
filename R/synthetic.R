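#' Simulation parameters for synthetic dual-cohort generation
#'
#' Bundles everything the synthetic generator needs: per-pathology
#' prevalences for the enriched cohort and for each clinical subgroup,
#' Beta score models for diseased and healthy cases, a latent-severity
#' reader model, and cohort sizes. Defaults reproduce the structure of
#' the motivating study: a 563-case enriched cohort with 8--26%
#' per-pathology prevalences read by six radiologists (three
#' board-certified, three residents), and a clinical-routine cohort of
#' 3,619 outpatient plus 11,900 inpatient examinations with
#' subgroup-specific prevalences.
#'
#' Scores follow a two-component Beta mixture per pathology: diseased
#' cases draw from \code{Beta(a1, b1)}, healthy from \code{Beta(a0, b0)}
#' with a higher diseased mean; bounded support matches the [0, 1]
#' score scale without clipping. Each diseased case carries a latent
#' severity \code{s ~ Uniform(0, 1)} (0 for healthy) that drives both
#' its AI score (quantile coupling: \code{score = qbeta(s, a1, b1)}) and
#' every reader's perception \code{s + Normal(0, sigma_r)}, which
#' strictly increasing cutpoints map to the 0--4 Likert scale. This
#' induces a realistic reader-AI correlation; \code{coupling} < 1 mixes
#' in independent score draws while preserving the Beta marginals.
#'
#' @param pathologies character vector of pathology names.
#' @param prev_enriched named (or positionally matched) per-pathology
#'   prevalence fractions in the enriched cohort.
#' @param prev_subgroup numeric matrix, pathologies x subgroups, of
#'   clinical prevalence fractions.
#' @param score_diseased,score_healthy length-2 Beta shape vectors
#'   (shared across pathologies) or pathology-named lists of such vectors.
#' @param n_enriched enriched cohort size.
#' @param n_subgroup named integer vector of clinical subgroup sizes.
#' @param n_readers number of reference readers (named BCR1..3, RR1..
#'   by default).
#' @param sigma_r standard deviation of reader perception noise on the
#'   latent severity scale; 0 makes all readers reproduce the truth.
#' @param cutpoints strictly increasing Likert cutpoints on the
#'   perception scale (4 values mapping to ratings 1..4); a rating is
#'   awarded when perception strictly exceeds the cutpoint, so with
#'   \code{sigma_r = 0} and a first cutpoint of 0 every reader
#'   reproduces the ground truth exactly (the analytic oracle's
#'   regime).
#' @param coupling probability in [0, 1] that a diseased score is
#'   quantile-coupled to severity (1 = fully coupled).
#' @param sample_n expert sample-reading size per clinical subgroup.
#' @return a \code{GenParams} list.
#' @examples
#' p <- genParams()
#' p$prev_subgroup
#' @export
genParams <- function(pathologies = c("pleural_effusion", "consolidation",
                                      "pneumothorax", "nodule"),
                      prev_enriched = c(0.249, 0.259, 0.103, 0.084),
                      prev_subgroup = cbind(
                          outpatient = c(0.235, 0.235, 0.025, 0.080),
                          inpatient  = c(0.465, 0.290, 0.125, 0.055)),
                      score_diseased = c(2.2, 2.8),
                      score_healthy = c(1.2, 14),
                      n_enriched = 563L,
                      n_subgroup = c(outpatient = 3619L, inpatient = 11900L),
                      n_readers = 6L, sigma_r = 0.03,
                      cutpoints = c(0.05, 0.35, 0.65, 0.9),
                      coupling = 1, sample_n = 200L) {
    np <- length(pathologies)
    canonical <- c("pleural_effusion", "consolidation", "pneumothorax",
                   "nodule")
    if (missing(prev_enriched) && np != 4L) {
        prev_enriched <- stats::setNames(rep_len(0.15, np), pathologies)
        known <- intersect(pathologies, canonical)
        prev_enriched[known] <-
            stats::setNames(c(0.249, 0.259, 0.103, 0.084),
                            canonical)[known]
    }
    prev_enriched <- rep_len(prev_enriched, np)
    names(prev_enriched) <- pathologies
    if (missing(prev_subgroup) && np != 4L) {
        full <- cbind(outpatient = c(0.235, 0.235, 0.025, 0.080),
                      inpatient  = c(0.465, 0.290, 0.125, 0.055))
        rownames(full) <- canonical
        prev_subgroup <- rbind(
            matrix(rep(c(0.1, 0.2), each = np), np,
                   dimnames = list(pathologies,
                                   c("outpatient", "inpatient"))))
        known <- intersect(pathologies, canonical)
        prev_subgroup[known, ] <- full[known, ]
    }
    prev_subgroup <- as.matrix(prev_subgroup)
    if (nrow(prev_subgroup) != np)
        stop("prev_subgroup must have one row per pathology")
    rownames(prev_subgroup) <- pathologies
    if (is.null(colnames(prev_subgroup)))
        stop("prev_subgroup columns must be named by subgroup")
    expand <- function(sh) {
        if (is.list(sh)) {
            if (!all(pathologies %in% names(sh)))
                stop("per-pathology score shapes must name every pathology")
            sh[pathologies]
        } else rep(list(as.numeric(sh)), np) |> stats::setNames(pathologies)
    }
    p <- list(pathologies = pathologies, prev_enriched = prev_enriched,
              prev_subgroup = prev_subgroup,
              score_diseased = expand(score_diseased),
              score_healthy = expand(score_healthy),
              n_enriched = as.integer(n_enriched),
              n_subgroup = vapply(n_subgroup, as.integer, integer(1)),
              n_readers = as.integer(n_readers), sigma_r = sigma_r,
              cutpoints = as.numeric(cutpoints), coupling = coupling,
              sample_n = as.integer(sample_n))
    .validateGenParams(p)
    class(p) <- "GenParams"
    p
}

.validateGenParams <- function(p) {
    if (any(p$prev_enriched < 0 | p$prev_enriched > 1) ||
        any(p$prev_subgroup < 0 | p$prev_subgroup > 1))
        stop("prevalence fractions must lie in [0, 1]")
    if (length(p$cutpoints) != 4L || is.unsorted(p$cutpoints, strictly = TRUE) ||
        any(p$cutpoints < 0))
        stop("cutpoints must be 4 strictly increasing non-negative values")
    if (p$n_enriched < 1L || any(p$n_subgroup < 1L) || p$n_readers < 1L)
        stop("cohort sizes and reader count must be positive")
    if (p$sigma_r < 0) stop("sigma_r must be non-negative")
    if (p$coupling < 0 || p$coupling > 1) stop("coupling must lie in [0, 1]")
    for (pt in p$pathologies) {
        d <- p$score_diseased[[pt]]; h <- p$score_healthy[[pt]]
        if (any(c(d, h) <= 0)) stop("Beta shapes must be positive")
        if (d[1] / sum(d) <= h[1] / sum(h))
            stop("diseased score mean must exceed healthy mean (", pt, ")")
    }
    if (any(p$sample_n > p$n_subgroup))
        stop("sample_n exceeds a subgroup size")
    invisible(TRUE)
}

#' @export
print.GenParams <- function(x, ...) {
    cat("GenParams:", length(x$pathologies), "pathologies,",
        x$n_enriched, "enriched cases,",
        paste(sprintf("%s=%d", names(x$n_subgroup), x$n_subgroup),
              collapse = " + "), "clinical cases,",
        x$n_readers, "readers (sigma_r =", x$sigma_r, ")\n")
    invisible(x)
}

# Stable 31-polynomial string hash mod 2^31-1, combined with the global
# seed: every generation stream gets its own reproducible substream that
# does not depend on platform or session state.
deriveSeed <- function(seed, ...) {
    s <- paste(c(...), collapse = "/")
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    as.integer((abs(as.double(seed)) + h) %% 2147483647)
}

.readerIds <- function(n) {
    base <- c("BCR1", "BCR2", "BCR3", "RR1", "RR2", "RR3")
    if (n <= 6L) base[seq_len(n)] else c(base, paste0("R", seq_len(n - 6L) + 6L))
}

# One pathology channel: disease status, latent severity, coupled score.
.drawChannel <- function(n, prev, shapes_d, shapes_h, coupling) {
    diseased <- stats::rbinom(n, 1L, prev) == 1L
    s <- numeric(n)
    s[diseased] <- stats::runif(sum(diseased))
    u <- stats::runif(n)                       # independent score quantiles
    couple <- stats::runif(n) < coupling
    q <- ifelse(diseased & couple, s, u)
    score <- ifelse(diseased,
                    stats::qbeta(q, shapes_d[1], shapes_d[2]),
                    stats::qbeta(u, shapes_h[1], shapes_h[2]))
    list(diseased = diseased, severity = s, score = score)
}

#' Generate a synthetic pathology-enriched cohort
#'
#' Draws disease status, latent severity, AI scores and six readers'
#' Likert ratings per case and pathology under [genParams()].
#' Deterministic for a fixed seed; each (pathology, purpose) stream is
#' seeded independently so adding pathologies does not perturb others.
#'
#' @param params a [genParams()] object.
#' @param seed integer seed.
#' @return an \linkS4class{EnrichedCohort}; the per-(case, pathology)
#'   ground truth is kept in \code{metadata(x)$truth}.
#' @export
genEnrichedCohort <- function(params, seed = 1L) {
    stopifnot(inherits(params, "GenParams"))
    n <- params$n_enriched
    ids <- sprintf("E%04d", seq_len(n))
    rdr <- .readerIds(params$n_readers)
    rows <- list(); ratings <- list(); truth <- list()
    for (pt in params$pathologies) {
        set.seed(deriveSeed(seed, "enriched", pt))
        ch <- .drawChannel(n, params$prev_enriched[[pt]],
                           params$score_diseased[[pt]],
                           params$score_healthy[[pt]], params$coupling)
        rows[[pt]] <- data.frame(case_id = ids, pathology = pt,
                                 ai_score = ch$score)
        truth[[pt]] <- data.frame(case_id = ids, pathology = pt,
                                  diseased = ch$diseased)
        set.seed(deriveSeed(seed, "readers", pt))
        for (r in rdr) {
            perception <- ch$severity +
                if (params$sigma_r > 0) stats::rnorm(n, 0, params$sigma_r)
                else 0
            # strict comparison: a perception exactly at a cutpoint stays
            # below it, so noise-free readers with a zero first cutpoint
            # rate healthy cases 0 and any diseased case >= 1 (labels
            # equal the ground truth, the analytic oracle's regime)
            ratings[[paste(pt, r)]] <- data.frame(
                case_id = ids, reader_id = r, pathology = pt,
                likert = findInterval(perception, params$cutpoints,
                                      left.open = TRUE))
        }
    }
    x <- enrichedCohort(do.call(rbind, rows), do.call(rbind, ratings))
    metadata(x)$truth <- do.call(rbind, c(truth, make.row.names = FALSE))
    metadata(x)$seed <- seed
    x
}

#' Generate a synthetic clinical-routine cohort
#'
#' Draws AI scores for each clinical subgroup at its configured size and
#' per-pathology prevalence, and selects a random expert sample reading
#' of \code{params$sample_n} cases per subgroup whose reference labels
#' are the simulated ground truth (a noise-free expert read).
#'
#' @param params a [genParams()] object.
#' @param seed integer seed.
#' @param sample_reading generate the expert-read subset (default TRUE).
#' @return a \linkS4class{ClinicalCohort}; per-(case, pathology) truth in
#'   \code{metadata(x)$truth}.
#' @export
genClinicalCohort <- function(params, seed = 1L, sample_reading = TRUE) {
    stopifnot(inherits(params, "GenParams"))
    sgs <- colnames(params$prev_subgroup)
    offset <- 0L
    rows <- list(); truth <- list(); sampled <- list()
    for (sg in sgs) {
        n <- params$n_subgroup[[sg]]
        ids <- sprintf("C%05d", offset + seq_len(n))
        offset <- offset + n
        for (pt in params$pathologies) {
            set.seed(deriveSeed(seed, "clinical", sg, pt))
            ch <- .drawChannel(n, params$prev_subgroup[pt, sg],
                               params$score_diseased[[pt]],
                               params$score_healthy[[pt]], params$coupling)
            rows[[paste(sg, pt)]] <- data.frame(
                case_id = ids, subgroup = sg, pathology = pt,
                ai_score = ch$score)
            truth[[paste(sg, pt)]] <- data.frame(
                case_id = ids, pathology = pt, diseased = ch$diseased)
        }
        if (sample_reading) {
            if (params$sample_n > n)
                stop("sample_n exceeds subgroup size for ", sg)
            set.seed(deriveSeed(seed, "sample", sg))
            sampled[[sg]] <- sample(ids, params$sample_n)
        }
    }
    scores <- do.call(rbind, c(rows, make.row.names = FALSE))
    tr <- do.call(rbind, c(truth, make.row.names = FALSE))
    sr <- NULL
    if (sample_reading) {
        pick <- unlist(sampled, use.names = FALSE)
        sr <- tr[tr$case_id %in% pick, ]
        sr <- data.frame(case_id = sr$case_id, pathology = sr$pathology,
                         reference_positive = as.integer(sr$diseased))
    }
    x <- clinicalCohort(scores, sr)
    metadata(x)$truth <- tr
    metadata(x)$seed <- seed
    x
}

#' Round-trip simulation parameters through YAML
#'
#' @param params a [genParams()] object.
#' @param file YAML path to write; for [readGenParams()], to read.
#' @return [writeGenParams()] the path invisibly; [readGenParams()] a
#'   reconstructed \code{GenParams}.
#' @export
writeGenParams <- function(params, file) {
    stopifnot(inherits(params, "GenParams"))
    y <- unclass(params)
    # named vectors must become maps or YAML drops the names
    y$prev_enriched <- as.list(params$prev_enriched)
    y$n_subgroup <- as.list(params$n_subgroup)
    y$prev_subgroup <- c(list(.subgroups = colnames(params$prev_subgroup)),
                         as.list(as.data.frame(t(params$prev_subgroup))))
    yaml::write_yaml(y, file)
    invisible(file)
}

#' @rdname writeGenParams
#' @export
readGenParams <- function(file) {
    y <- yaml::read_yaml(file)
    ps <- y$prev_subgroup
    sgs <- ps$.subgroups
    ps$.subgroups <- NULL
    m <- t(vapply(ps, unlist, numeric(length(sgs))))
    colnames(m) <- sgs
    genParams(pathologies = y$pathologies,
              prev_enriched = unlist(y$prev_enriched),
              prev_subgroup = m,
              score_diseased = lapply(y$score_diseased, unlist),
              score_healthy = lapply(y$score_healthy, unlist),
              n_enriched = y$n_enriched,
              n_subgroup = unlist(y$n_subgroup),
              n_readers = y$n_readers, sigma_r = y$sigma_r,
              cutpoints = unlist(y$cutpoints), coupling = y$coupling,
              sample_n = y$sample_n)
}
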