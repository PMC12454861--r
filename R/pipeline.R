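#' Run configuration for the full optimization pipeline
#'
#' A validated bundle of everything one pipeline run needs. Input
#' cohorts come either from the four CSV schemas (see [readEnrichedCohort()])
#' or, when \code{simulate = TRUE}, from the synthetic generator.
#'
#' @param enriched_scores,readings,clinical_scores,sample_reading CSV
#'   paths (ignored when \code{simulate = TRUE}).
#' @param simulate generate cohorts with [genParams()] defaults instead
#'   of reading CSVs.
#' @param pathologies pathology names to analyze.
#' @param aidt named numeric vendor thresholds per pathology (NA allowed).
#' @param rfs reference-standard level, default \code{"IV"}.
#' @param subgroups clinical subgroups to optimize for.
#' @param grid_step sensitivity grid step in percent, in (0, 5].
#' @param aggregate \code{"mean"} or \code{"median"} threshold
#'   aggregation.
#' @param seed integer seed (simulation and any sampling).
#' @param outdir output directory.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(enriched_scores = NULL, readings = NULL,
                      clinical_scores = NULL, sample_reading = NULL,
                      simulate = is.null(enriched_scores),
                      pathologies = c("pleural_effusion", "consolidation",
                                      "pneumothorax", "nodule"),
                      aidt = NULL, rfs = "IV",
                      subgroups = c("outpatient", "inpatient"),
                      grid_step = 1, aggregate = "mean", seed = 1L,
                      outdir = "threshlink_out") {
    if (grid_step <= 0 || grid_step > 5)
        stop("grid_step must lie in (0, 5] percent")
    rfs <- match.arg(rfs, names(.RFS_LEVELS))
    aggregate <- match.arg(aggregate, c("mean", "median"))
    if (!simulate) {
        for (f in c(enriched_scores, readings, clinical_scores, sample_reading))
            if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
    }
    if (!is.null(aidt)) {
        if (is.null(names(aidt)) || !all(names(aidt) %in% pathologies))
            stop("aidt must be named by configured pathologies")
        if (any(!is.na(aidt) & (aidt < 0 | aidt > 1)))
            stop("aidt thresholds must lie in [0, 1]")
    }
    structure(list(enriched_scores = enriched_scores, readings = readings,
                   clinical_scores = clinical_scores,
                   sample_reading = sample_reading, simulate = simulate,
                   pathologies = pathologies, aidt = aidt, rfs = rfs,
                   subgroups = subgroups, grid_step = grid_step,
                   aggregate = aggregate, seed = as.integer(seed),
                   outdir = outdir),
              class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param file YAML file whose keys mirror the [runConfig()] arguments.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(file) {
    y <- yaml::read_yaml(file)
    args <- y[intersect(names(y), names(formals(runConfig)))]
    if (!is.null(args$aidt)) args$aidt <- unlist(args$aidt)
    if (!is.null(args$pathologies)) args$pathologies <- unlist(args$pathologies)
    if (!is.null(args$subgroups)) args$subgroups <- unlist(args$subgroups)
    do.call(runConfig, args)
}

#' Execute the full threshold-optimization pipeline
#'
#' For every configured pathology and clinical subgroup: per-reader ROC
#' curves (CSV), the sensitivity-to-alert-rate linkage curve (CSV), the
#' slope-criterion optimization result (JSON), diagnostic metrics of
#' the OT / AIDT / Youden thresholds against the expert sample reading
#' when one is available (JSON), and a four-panel figure (ROC, clinical
#' score histogram with threshold markers, per-reader alert bars,
#' linkage curve with the target annotated). A per-pathology
#' threshold-comparison histogram and a run log (configuration, seed,
#' row counts per stage) complete the bundle.
#'
#' @param config a [runConfig()] (or path to its YAML).
#' @param figures render figures (default TRUE; numeric outputs are the
#'   contract, figures are best-effort).
#' @return invisibly, a nested list of \linkS4class{OptimizationResult}
#'   objects indexed \code{[[pathology]][[subgroup]]}, with the cohorts
#'   attached as attributes.
#' @export
runPipeline <- function(config, figures = TRUE) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(config$outdir, "run.log")
    logline <- function(...) cat(..., "\n", sep = "", file = log, append = TRUE)
    cat("", file = log)
    logline("ThreshLink pipeline run, seed ", config$seed)
    logline("config: ", paste(utils::capture.output(utils::str(unclass(config))),
                              collapse = " "))

    if (config$simulate) {
        params <- genParams(pathologies = config$pathologies)
        enriched <- genEnrichedCohort(params, config$seed)
        clinical <- genClinicalCohort(params, config$seed)
        logline("simulated cohorts under default generator parameters")
    } else {
        enriched <- readEnrichedCohort(config$enriched_scores, config$readings)
        clinical <- readClinicalCohort(config$clinical_scores,
                                       config$sample_reading)
    }
    logline("enriched rows: ", nrow(enriched), "; clinical rows: ",
            nrow(clinical@scores), "; sample-reading rows: ",
            nrow(clinical@sampleReading))

    cfg <- pathologyConfig(config$pathologies,
                           aidt = if (is.null(config$aidt)) NA_real_
                                  else unname(config$aidt[config$pathologies]),
                           rfs = config$rfs)
    vr <- validateCohorts(enriched, clinical, cfg)
    if (nrow(vr)) {
        utils::write.csv(vr, file.path(config$outdir, "validation.csv"),
                         row.names = FALSE)
        stop("validation failed with ", nrow(vr), " finding(s); see ",
             file.path(config$outdir, "validation.csv"))
    }
    logline("validation: clean")

    grid <- seq(0, 100, by = config$grid_step)
    results <- list()
    for (pt in config$pathologies) {
        rocs <- readerRocCurves(enriched, pt, config$rfs)
        exportRoc(rocs, file.path(config$outdir, paste0("roc_", pt, ".csv")))
        results[[pt]] <- list()
        for (sg in config$subgroups) {
            res <- optimizeThreshold(enriched, clinical, sg, pt,
                                     rfs = config$rfs,
                                     aidt = if (is.null(config$aidt))
                                         NA_real_ else config$aidt[[pt]],
                                     sens_grid = grid,
                                     aggregate = config$aggregate)
            stemsg <- paste0(pt, "_", sg)
            exportLinkage(res@linkage,
                          file.path(config$outdir,
                                    paste0("linkage_", stemsg, ".csv")))
            optimizationAsList(res, file.path(config$outdir,
                                              paste0("ot_", stemsg, ".json")))
            if (nrow(clinical@sampleReading))
                .writeMetricsJson(clinical, res, config$outdir, stemsg)
            if (figures)
                .renderFourPanel(rocs, clinical, res,
                                 file.path(config$outdir,
                                           paste0("panel_", stemsg, ".pdf")))
            results[[pt]][[sg]] <- res
            logline("optimized ", stemsg, ": target ",
                    res@target_sensitivity, "% -> OT ",
                    signif(res@ot, 4), " (alert ",
                    round(res@alert_at_ot, 1), "%)")
        }
        if (figures)
            plotThresholdComparison(
                clinical, pt, results[[pt]],
                file = file.path(config$outdir,
                                 paste0("comparison_", pt, ".pdf")))
    }
    attr(results, "enriched") <- enriched
    attr(results, "clinical") <- clinical
    logline("pipeline complete")
    invisible(results)
}

.writeMetricsJson <- function(clinical, res, outdir, stem) {
    thr <- c(ot = res@ot, aidt = res@aidt,
             youden = unname(mean(res@youden_by_reader)))
    out <- list()
    for (nm in names(thr)) {
        if (is.na(thr[[nm]])) next
        tab <- confusionFromReading(clinical, res@pathology, thr[[nm]],
                                    subgroup = res@subgroup)
        rep <- diagnosticMetrics(tab)
        out[[nm]] <- list(threshold = thr[[nm]],
                          counts = as.list(counts2x2(tab)),
                          n = metadata(rep)$n,
                          prevalence_pct = metadata(rep)$prevalence,
                          metrics = lapply(seq_len(nrow(rep)), function(i)
                              list(metric = rep$metric[i],
                                   estimate_pct = rep$estimate[i],
                                   ci = c(rep$lower[i], rep$upper[i]))))
    }
    jsonlite::write_json(out, file.path(outdir,
                                        paste0("metrics_", stem, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
}
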