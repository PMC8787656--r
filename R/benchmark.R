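## Concordance of scheme classifications with the latent benchmark.

#' Cross-tabulate a scheme against the latent benchmark
#'
#' Builds the 2x2 table of scheme-positive vs benchmark-positive
#' counts. Benchmark positivity is the latent high-risk group; the
#' low- and at-risk groups are coded 0.
#'
#' @param scheme_labels,benchmark_labels Equal-length logical (or
#'   0/1) vectors.
#' @return An object of class `"confusion_table"` with integer fields
#'   `TP`, `FP`, `FN`, `TN` and `n`.
#' @examples
#' cross_tabulate(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
cross_tabulate <- function(scheme_labels, benchmark_labels) {
  s <- as.logical(scheme_labels); b <- as.logical(benchmark_labels)
  if (length(s) != length(b))
    stop("scheme and benchmark labels differ in length", call. = FALSE)
  if (anyNA(s) || anyNA(b))
    stop("labels must be binary with no missing values", call. = FALSE)
  structure(list(TP = sum(s & b), FP = sum(s & !b),
                 FN = sum(!s & b), TN = sum(!s & !b), n = length(s)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(c("scheme +", "scheme -"),
                              c("benchmark +", "benchmark -")))
  print(m)
  invisible(x)
}

#' Diagnostic concordance indices from a 2x2 table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive
#' predictive value `TP/(TP+FP)`, negative predictive value
#' `TN/(TN+FN)` and overall consistency `(TP+TN)/n`. Any index with a
#' zero denominator is returned as `NA` and flagged not computable.
#'
#' @param ct A [cross_tabulate()] result, or a list with fields
#'   `TP`, `FP`, `FN`, `TN`.
#' @return An object of class `"diagnostic_indices"`: named numeric
#'   vector of the five proportions with a `"computable"` attribute.
#' @examples
#' diagnostic_indices(list(TP = 10, FN = 2, FP = 3, TN = 85))
#' @export
diagnostic_indices <- function(ct) {
  cells <- c(TP = ct$TP, FP = ct$FP, FN = ct$FN, TN = ct$TN)
  if (any(cells < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  n <- sum(cells)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- c(sensitivity = ratio(ct$TP, ct$TP + ct$FN),
           specificity = ratio(ct$TN, ct$TN + ct$FP),
           ppv = ratio(ct$TP, ct$TP + ct$FP),
           npv = ratio(ct$TN, ct$TN + ct$FN),
           overall_consistency = ratio(ct$TP + ct$TN, n))
  structure(out, computable = !is.na(out), class = "diagnostic_indices")
}

#' @export
print.diagnostic_indices <- function(x, ...) {
  v <- unclass(x)
  lab <- ifelse(is.na(v), "not computable", sprintf("%d%%", round(100 * v)))
  cat(paste(sprintf("%-20s %s", names(v), lab), collapse = "\n"), "\n")
  invisible(x)
}

#' Concordance report of all schemes against the latent benchmark
#'
#' One row per scheme with the five concordance indices, as
#' proportions (full precision) plus the raw 2x2 counts; the print
#' method shows integer percentages.
#'
#' @param data Cohort data frame (or rating matrix).
#' @param schemes List of [scheme_spec()] objects (default all four).
#' @param benchmark Logical benchmark vector, e.g. the `highrisk`
#'   column of [assign_risk()].
#' @return A data frame of class `"scheme_benchmark_report"`.
#' @export
scheme_benchmark_report <- function(data, schemes = sma_schemes(),
                                    benchmark) {
  benchmark <- as.logical(benchmark)
  rows <- lapply(schemes, function(sc) {
    ct <- cross_tabulate(apply_scheme(data, sc), benchmark)
    di <- diagnostic_indices(ct)
    cbind(data.frame(scheme = sc$name),
          as.data.frame(as.list(unclass(di))),
          data.frame(TP = ct$TP, FP = ct$FP, FN = ct$FN, TN = ct$TN))
  })
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("scheme_benchmark_report", "data.frame"))
}

#' @export
print.scheme_benchmark_report <- function(x, ...) {
  df <- as.data.frame(x)
  idx <- c("sensitivity", "specificity", "ppv", "npv", "overall_consistency")
  for (cn in idx)
    df[[cn]] <- ifelse(is.na(df[[cn]]), "N/A",
                       sprintf("%d", round(100 * df[[cn]])))
  cat("Concordance with latent benchmark (%)\n")
  print(df[c("scheme", idx)], row.names = FALSE)
  invisible(x)
}
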