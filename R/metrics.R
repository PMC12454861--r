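#' Wald confidence interval for a binomial proportion
#'
#' Normal-approximation interval \eqn{\hat p \pm z \sqrt{\hat p (1 -
#' \hat p) / n}}, reported in percent and clipped to [0, 100]. The Wald
#' form (rather than Wilson or Clopper-Pearson) is the one that
#' reproduces the bracketed intervals of published diagnostic-accuracy
#' tables this package reconstructs; Wilson is available via
#' \code{method = "wilson"}.
#'
#' @param successes number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95, z = 1.959964).
#' @param method \code{"wald"} (default) or \code{"wilson"}.
#' @return named numeric: \code{lower}, \code{upper} (percent),
#'   \code{level}.
#' @examples
#' waldCi(47, 200)   # 17.6 .. 29.4
#' waldCi(41, 47)    # 77.7 .. 96.8
#' @export
waldCi <- function(successes, n, level = 0.95, method = c("wald", "wilson")) {
    method <- match.arg(method)
    if (n <= 0) stop("n must be positive")
    if (successes < 0 || successes > n)
        stop("successes must lie in 0..n")
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- successes / n
    if (method == "wald") {
        half <- z * sqrt(p * (1 - p) / n)
        lo <- p - half; hi <- p + half
    } else {
        den <- 1 + z^2 / n
        ctr <- (p + z^2 / (2 * n)) / den
        half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
        lo <- ctr - half; hi <- ctr + half
    }
    c(lower = max(0, 100 * lo), upper = min(100, 100 * hi), level = level)
}

#' 2x2 table of AI calls against the expert sample reading
#'
#' Crosses the AI decision (score >= threshold) with the binary expert
#' reference over the sample-read subset of a clinical cohort.
#'
#' @param clinical a \linkS4class{ClinicalCohort} with a non-empty
#'   sample reading for the pathology.
#' @param pathology pathology name.
#' @param threshold decision threshold.
#' @param subgroup optional subgroup restriction (default all sampled
#'   cases).
#' @return a \linkS4class{ConfusionTable}.
#' @export
confusionFromReading <- function(clinical, pathology, threshold,
                                 subgroup = NULL) {
    stopifnot(is(clinical, "ClinicalCohort"))
    sr <- as.data.frame(clinical@sampleReading)
    sr <- sr[sr$pathology == pathology, ]
    if (!is.null(subgroup)) {
        sg <- subgroups(clinical)
        sr <- sr[sg[sr$case_id] == subgroup, ]
    }
    if (!nrow(sr)) stop("no sample-reading cases for pathology ", pathology)
    sc <- aiScores(clinical, pathology)
    call <- sc[sr$case_id] >= threshold
    ref <- sr$reference_positive == 1L
    confusionTable(tp = sum(call & ref), fp = sum(call & !ref),
                   fn = sum(!call & ref), tn = sum(!call & !ref))
}

#' Diagnostic metrics with Wald confidence intervals
#'
#' Sensitivity, specificity, accuracy, predictive values and error
#' rates from a 2x2 table, each in percent with its 95% Wald interval.
#' A metric whose denominator is zero is reported as undefined (NA
#' estimate, flagged) rather than propagating NaN.
#'
#' @param table a \linkS4class{ConfusionTable}.
#' @param level confidence level.
#' @return a \linkS4class{DataFrame} with one row per metric and columns
#'   \code{metric}, \code{estimate}, \code{lower}, \code{upper},
#'   \code{undefined}; \code{metadata()} carries \code{n} and
#'   \code{prevalence} (percent).
#' @examples
#' diagnosticMetrics(confusionTable(tp = 22, fp = 3, fn = 25, tn = 150))
#' @export
diagnosticMetrics <- function(table, level = 0.95) {
    stopifnot(is(table, "ConfusionTable"))
    tp <- table@tp; fp <- table@fp; fn <- table@fn; tn <- table@tn
    n <- tp + fp + fn + tn
    if (n == 0L) stop("empty table")
    num <- c(sensitivity = tp, specificity = tn, accuracy = tp + tn,
             ppv = tp, npv = tn, fnr = fn, fpr = fp)
    den <- c(sensitivity = tp + fn, specificity = fp + tn, accuracy = n,
             ppv = tp + fp, npv = tn + fn, fnr = tp + fn, fpr = fp + tn)
    rows <- lapply(names(num), function(m) {
        if (den[[m]] == 0L)
            return(DataFrame(metric = m, estimate = NA_real_,
                             lower = NA_real_, upper = NA_real_,
                             undefined = TRUE))
        ci <- waldCi(num[[m]], den[[m]], level)
        DataFrame(metric = m, estimate = 100 * num[[m]] / den[[m]],
                  lower = ci[["lower"]], upper = ci[["upper"]],
                  undefined = FALSE)
    })
    out <- do.call(rbind, rows)
    metadata(out) <- list(n = n, prevalence = 100 * (tp + fn) / n,
                          level = level)
    out
}

.metric <- function(report, name, what = "estimate")
    report[[what]][match(name, report$metric)]

#' Compare two proportions (threshold A vs threshold B)
#'
#' Two-sample test of equal proportions: continuity-corrected
#' chi-square ([stats::prop.test]), falling back to Fisher's exact test
#' when any expected cell count is below 5.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return the p-value, with attribute \code{method}.
#' @export
compareProportions <- function(k1, n1, k2, n2) {
    if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
    pbar <- (k1 + k2) / (n1 + n2)
    expected <- c(n1 * pbar, n1 * (1 - pbar), n2 * pbar, n2 * (1 - pbar))
    if (any(expected < 5)) {
        p <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2L,
                                       byrow = TRUE))$p.value
        attr(p, "method") <- "fisher"
    } else {
        p <- stats::prop.test(c(k1, k2), c(n1, n2))$p.value
        attr(p, "method") <- "chisq_cc"
    }
    p
}

#' Reconstruct an integer 2x2 table from published summary percentages
#'
#' Inverts rounded summary statistics: given a table's printed
#' sensitivity, specificity, prevalence (all percent, one decimal) and
#' total n, finds the integer counts that re-render to them. The
#' positive count is \code{round(prev * n / 100)}; tp is the integer
#' minimizing the distance of \code{100 * tp / P} to the printed
#' sensitivity (ties broken toward the larger count and flagged
#' ambiguous), tn likewise from specificity over the negatives. An
#' inconsistency error is raised when no integer count lands within
#' \code{tol} percentage points of a printed value.
#'
#' @param sens_pct,spec_pct,prev_pct printed percentages in [0, 100].
#' @param n total sample size.
#' @param tol maximum allowed distance between a printed percent and the
#'   re-rendered one (default 0.05, half of one printed decimal).
#' @return a \linkS4class{ConfusionTable}; ambiguity flags, if any, in
#'   its \code{note}.
#' @examples
#' reconstructTable(46.8, 98.0, 23.5, 200)  # tp 22, fn 25, fp 3, tn 150
#' @export
reconstructTable <- function(sens_pct, spec_pct, prev_pct, n, tol = 0.05) {
    stopifnot(n > 0)
    for (v in c(sens_pct, spec_pct, prev_pct))
        if (v < 0 || v > 100) stop("percent values must lie in [0, 100]")
    P <- as.integer(round(prev_pct * n / 100))
    N <- as.integer(n) - P
    if (P <= 0L || N < 0L)
        stop("inconsistent prevalence: no positive cases implied")
    note <- character()
    pick <- function(target, den, what) {
        if (den == 0L) return(0L)
        k <- 0:den
        d <- abs(100 * k / den - target)
        if (min(d) > tol)
            stop("inconsistent summary: no integer ", what, " count renders ",
                 target, "% over ", den, " cases (closest off by ",
                 round(min(d), 3), " points)")
        best <- which(d == min(d))
        if (length(best) > 1L)
            note <<- c(note, paste0("ambiguous:", what))
        k[max(best)]
    }
    tp <- pick(sens_pct, P, "tp")
    tn <- pick(spec_pct, N, "tn")
    confusionTable(tp = tp, fp = N - tn, fn = P - tp, tn = tn, note = note)
}

#' Expected pathology count in a clinical subgroup
#'
#' Projects a sample-reading prevalence onto a full subgroup:
#' \code{ceiling(prev_pct / 100 * subgroup_size)}, the rounding rule
#' consistent with published projected-count tables.
#'
#' @param prev_pct prevalence in percent.
#' @param subgroup_size subgroup size.
#' @return expected integer count.
#' @examples
#' estimateClinicalCounts(46.5, 11900)  # 5534
#' @export
estimateClinicalCounts <- function(prev_pct, subgroup_size) {
    stopifnot(prev_pct >= 0, subgroup_size > 0)
    as.integer(ceiling(prev_pct / 100 * subgroup_size))
}
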