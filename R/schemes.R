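#' Criterion-counting classification schemes
#'
#' The four common schemes for turning six 1-5 symptom ratings into a
#' binary addiction classification combine an item cutoff with a
#' counting rule: the *monothetic* rules require every criterion to be
#' met, the *polythetic* rules require more than half (at least 4 of
#' 6); the plain schemes score a criterion as met at the scale midpoint
#' (rating >= 3), the *strict* schemes at rating >= 4.
#'
#' @param name One of `"strict monothetic"`, `"strict polythetic"`,
#'   `"monothetic"`, `"polythetic"`.
#' @return `scheme_spec()` returns an object of class `"scheme_spec"`
#'   with fields `name`, `item_cutoff` (3 or 4) and `rule`
#'   (`"all-criteria"` or `"more-than-half"`). `sma_schemes()` returns
#'   the named list of all four, in increasing order of liberality of
#'   the classification.
#' @examples
#' sma_schemes()
#' @export
scheme_spec <- function(name = c("strict monothetic", "strict polythetic",
                                 "monothetic", "polythetic")) {
  name <- match.arg(name)
  cutoff <- if (grepl("^strict", name)) 4L else 3L
  rule <- if (grepl("monothetic", name)) "all-criteria" else "more-than-half"
  structure(list(name = name, item_cutoff = cutoff, rule = rule),
            class = "scheme_spec")
}

#' @rdname scheme_spec
#' @export
sma_schemes <- function() {
  nm <- c("strict monothetic", "strict polythetic", "monothetic", "polythetic")
  stats::setNames(lapply(nm, scheme_spec), nm)
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat(sprintf("Scheme '%s': criterion met at rating >= %d, positive under %s rule\n",
              x$name, x$item_cutoff, x$rule))
  invisible(x)
}

## Pull the 6 rating columns out of a cohort data frame or matrix.
ratings_matrix <- function(x) {
  if (is.data.frame(x)) {
    miss <- setdiff(BSMAS_COLS, names(x))
    if (length(miss))
      stop("missing rating columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- as.matrix(x[BSMAS_COLS])
  }
  x <- as.matrix(x)
  if (ncol(x) != 6L) stop("ratings must have 6 columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

check_ratings <- function(r) {
  bad <- which(is.na(r) | r < 1 | r > 5 | r != round(r), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid rating at row %d, item %d (value %s)",
                 bad[1, 1], bad[1, 2], format(r[bad[1, , drop = FALSE]])),
         call. = FALSE)
  invisible(r)
}

#' Dichotomise ratings into met/not-met criteria
#'
#' A criterion is met when its rating is at or above the cutoff.
#'
#' @param ratings Cohort data frame or n x 6 integer matrix of ratings
#'   in 1-5.
#' @param cutoff Item cutoff, 3 (scale midpoint) or 4 (strict).
#' @return Logical n x 6 matrix.
#' @examples
#' dichotomize(rbind(c(4, 3, 5, 2, 1, 3)), cutoff = 4)
#' @export
dichotomize <- function(ratings, cutoff) {
  if (!cutoff %in% c(3, 4)) stop("cutoff must be 3 or 4", call. = FALSE)
  r <- check_ratings(ratings_matrix(ratings))
  r >= cutoff
}

#' Classify respondents from a criterion matrix
#'
#' Applies a counting rule to met/not-met criteria: `"all-criteria"`
#' is positive only when all 6 are met; `"more-than-half"` is positive
#' when at least 4 of 6 are met (strictly more than half).
#'
#' @param criteria Logical n x 6 matrix, e.g. from [dichotomize()].
#' @param rule `"all-criteria"` or `"more-than-half"`.
#' @return Logical vector, `TRUE` = classified as high-risk/addicted.
#' @export
classify <- function(criteria, rule = c("all-criteria", "more-than-half")) {
  rule <- match.arg(rule)
  criteria <- as.matrix(criteria)
  if (ncol(criteria) != 6L) stop("criteria must have 6 columns", call. = FALSE)
  cnt <- rowSums(criteria)
  if (rule == "all-criteria") cnt == 6L else cnt >= 4L
}

#' Apply a classification scheme to a cohort
#'
#' Convenience wrapper combining [dichotomize()] and [classify()].
#'
#' @param x Cohort data frame or rating matrix.
#' @param scheme A [scheme_spec()] or a scheme name.
#' @return Logical vector of classifications.
#' @export
apply_scheme <- function(x, scheme) {
  if (is.character(scheme)) scheme <- scheme_spec(scheme)
  stopifnot(inherits(scheme, "scheme_spec"))
  classify(dichotomize(x, scheme$item_cutoff), scheme$rule)
}

#' Composite symptom score
#'
#' Row sum of the six ratings (range 6-30). Exposed for descriptive
#' use; no composite-score cutoff scheme is implemented, since the
#' schemes classify by criterion counting only.
#'
#' @param x Cohort data frame or rating matrix.
#' @return Integer vector of totals.
#' @export
bsmas_total <- function(x) as.integer(rowSums(ratings_matrix(x)))

#' Prevalence of a binary classification
#'
#' Counts and proportions of positives, overall or within strata of a
#' demographic factor. An empty stratum yields `NA` ("not computable")
#' rather than an error.
#'
#' @param labels Logical (or 0/1) vector of classifications.
#' @param by Optional factor of the same length defining strata.
#' @return Data frame with columns `stratum`, `n`, `positive`,
#'   `proportion`, `percent`.
#' @examples
#' prevalence(c(rep(TRUE, 86), rep(FALSE, 487)))
#' @export
prevalence <- function(labels, by = NULL) {
  labels <- as.logical(labels)
  if (!length(labels)) stop("labels must be nonempty", call. = FALSE)
  one <- function(l, nm) {
    n <- length(l)
    pos <- sum(l)
    prop <- if (n > 0) pos / n else NA_real_
    data.frame(stratum = nm, n = n, positive = pos, proportion = prop,
               percent = 100 * prop, stringsAsFactors = FALSE)
  }
  if (is.null(by)) return(one(labels, "total"))
  by <- as.factor(by)
  stopifnot(length(by) == length(labels))
  do.call(rbind, lapply(levels(by), function(lv) one(labels[by == lv], lv)))
}
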