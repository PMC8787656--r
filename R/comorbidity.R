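## Probable-case screening, risk ratios and reliability.

CESD_CUTOFF <- 16L   # probable depression: CES-D total >= 16
STAI_CUTOFF <- 40L   # probable anxiety: STAI state total >= 40

#' Probable-case screening for depression and anxiety
#'
#' Dichotomises a scale total at the standard screening cutoff: CES-D
#' depression total >= 16, STAI state anxiety total >= 40 (both
#' inclusive).
#'
#' @param score Integer scale totals (CES-D 0-60; STAI 20-80).
#' @param instrument `"depression"` or `"anxiety"`.
#' @return Logical vector, `TRUE` = probable case.
#' @examples
#' probable_case(c(0, 15, 16, 40), "depression")
#' @export
probable_case <- function(score, instrument = c("depression", "anxiety")) {
  instrument <- match.arg(instrument)
  rng <- if (instrument == "depression") c(0, 60) else c(20, 80)
  cut <- if (instrument == "depression") CESD_CUTOFF else STAI_CUTOFF
  bad <- which(is.na(score) | score < rng[1] | score > rng[2])
  if (length(bad))
    stop(sprintf("%s score out of range [%d, %d] at position %d",
                 instrument, rng[1], rng[2], bad[1]), call. = FALSE)
  score >= cut
}

rr_from_counts <- function(a, n1, b, n0) {
  computable <- n1 > 0 && n0 > 0 && b > 0
  rr <- if (computable) (a / n1) / (b / n0) else NA_real_
  structure(list(exposed_events = a, exposed_n = n1,
                 unexposed_events = b, unexposed_n = n0,
                 rr = rr, computable = computable),
            class = "risk_ratio")
}

#' Risk ratio of an outcome given a binary exposure
#'
#' `RR = (exposed events / exposed n) / (unexposed events /
#' unexposed n)`. When a stratum is empty or the reference
#' (unexposed) risk is zero, the ratio is flagged not computable
#' (`NA`), mirroring how such cells are reported as N/A rather than
#' erroring.
#'
#' @param exposure,outcome Equal-length logical (or 0/1) vectors.
#' @param conf.int Also attach an approximate log-normal 95%
#'   confidence interval? Default `FALSE`.
#' @return An object of class `"risk_ratio"` with the 2x2 counts and
#'   the ratio.
#' @examples
#' risk_ratio(rep(c(TRUE, FALSE), each = 20),
#'            c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 15)))
#' @export
risk_ratio <- function(exposure, outcome, conf.int = FALSE) {
  e <- as.logical(exposure); o <- as.logical(outcome)
  if (length(e) != length(o))
    stop("exposure and outcome differ in length", call. = FALSE)
  if (anyNA(e) || anyNA(o))
    stop("exposure and outcome must be binary with no missing values",
         call. = FALSE)
  out <- rr_from_counts(sum(e & o), sum(e), sum(!e & o), sum(!e))
  if (conf.int && out$computable && out$exposed_events > 0) {
    se <- sqrt(1 / out$exposed_events - 1 / out$exposed_n +
               1 / out$unexposed_events - 1 / out$unexposed_n)
    out$conf.int <- exp(log(out$rr) + c(-1, 1) * qnorm(0.975) * se)
  }
  out
}

#' @export
print.risk_ratio <- function(x, ...) {
  cat(sprintf("Risk ratio: %s  (exposed %d/%d vs unexposed %d/%d)\n",
              if (x$computable) sprintf("%.2f", x$rr) else "not computable",
              x$exposed_events, x$exposed_n,
              x$unexposed_events, x$unexposed_n))
  if (!is.null(x$conf.int))
    cat(sprintf("  95%% CI %.2f-%.2f (log-normal)\n",
                x$conf.int[1], x$conf.int[2]))
  invisible(x)
}

#' Single-criterion risk ratios
#'
#' Dummy-codes each of the six items at the given cutoff and computes
#' the risk ratio of the outcome for each item-level exposure.
#'
#' @param ratings Cohort data frame or rating matrix.
#' @param item_cutoff 3 or 4.
#' @param outcome Logical outcome vector (e.g. probable depression).
#' @return Named list of six [risk_ratio()] results, in item order.
#' @export
item_level_rr <- function(ratings, item_cutoff, outcome) {
  crit <- dichotomize(ratings, item_cutoff)
  out <- lapply(seq_len(6), function(j) risk_ratio(crit[, j], outcome))
  stats::setNames(out, BSMAS_ITEMS)
}

#' Group descriptives with a one-tailed t test
#'
#' Means and SDs (n - 1 denominator) of a score in the high-risk and
#' low-to-at-risk groups, with a Welch independent-samples t test,
#' one-tailed in the direction "high-risk mean greater". Groups with
#' fewer than 2 members make the test not computable.
#'
#' @param scores Numeric vector.
#' @param highrisk Logical vector: `TRUE` = high-risk group.
#' @return An object of class `"group_comparison"`: list with per-group
#'   `n`, `mean`, `sd`, plus `t`, `df` and the one-tailed `p`.
#' @export
group_comparison <- function(scores, highrisk) {
  h <- as.logical(highrisk)
  stopifnot(length(scores) == length(h))
  a <- scores[h]; b <- scores[!h]
  res <- list(n_high = length(a), mean_high = mean(a), sd_high = sd(a),
              n_rest = length(b), mean_rest = mean(b), sd_rest = sd(b))
  if (length(a) >= 2 && length(b) >= 2 && (sd(a) > 0 || sd(b) > 0)) {
    tt <- stats::t.test(a, b, alternative = "greater")
    res$t <- unname(tt$statistic); res$df <- unname(tt$parameter)
    res$p <- tt$p.value; res$computable <- TRUE
  } else {
    res$t <- res$df <- res$p <- NA_real_; res$computable <- FALSE
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("high-risk %.2f (%.2f), n=%d  vs  rest %.2f (%.2f), n=%d\n",
              x$mean_high, x$sd_high, x$n_high,
              x$mean_rest, x$sd_rest, x$n_rest))
  cat(if (x$computable)
        sprintf("Welch t = %.2f, df = %.1f, one-tailed p = %.4g\n",
                x$t, x$df, x$p)
      else "test not computable\n")
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / total-score variance)`
#' with sample (n - 1) variances.
#'
#' @param item_matrix Numeric matrix or data frame, respondents by
#'   items (>= 2 of each).
#' @return A number, or `NA` when the total-score variance is zero.
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  k <- ncol(x)
  if (k < 2 || nrow(x) < 2)
    stop("need at least 2 items and 2 respondents", call. = FALSE)
  vt <- var(rowSums(x))
  if (vt == 0) return(NA_real_)
  (k / (k - 1)) * (1 - sum(apply(x, 2, var)) / vt)
}

#' Demographic risk ratios for a classification
#'
#' Risk of being classified positive by exposure stratum, against a
#' reference stratum (female for sex; ages 50-65 for age band),
#' mirroring the prevalence-table layout of the survey report.
#'
#' @param labels Logical classification vector.
#' @param factor_values Factor of demographic strata.
#' @param reference Reference level (risk denominator).
#' @return Named list of [risk_ratio()]-style results, one per
#'   non-reference level.
#' @export
demographic_rr <- function(labels, factor_values, reference) {
  labels <- as.logical(labels)
  f <- as.factor(factor_values)
  stopifnot(reference %in% levels(f))
  ref <- f == reference
  other <- setdiff(levels(f), reference)
  out <- lapply(other, function(lv) {
    idx <- f == lv | ref
    risk_ratio(f[idx] == lv, labels[idx])
  })
  stats::setNames(out, other)
}
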