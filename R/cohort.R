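#' @useDynLib smaclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm dnorm var sd kmeans pchisq p.adjust pt qnorm
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Canonical item order of the six-symptom scale.
BSMAS_ITEMS <- c("salience", "tolerance", "mood_modification",
                 "loss_of_control", "withdrawal", "conflict")
BSMAS_COLS <- paste0("bsmas", 1:6)
AGE_BANDS <- c("18-34", "35-49", "50-65")
SEX_LEVELS <- c("male", "female")

#' Names of the six addiction criteria
#'
#' Returns the canonical item order used throughout the package:
#' salience, tolerance, mood modification, loss of control, withdrawal,
#' conflict. Rating columns in a cohort are named `bsmas1` ... `bsmas6`
#' in this order.
#'
#' @return Character vector of length 6.
#' @export
bsmas_items <- function() BSMAS_ITEMS

## Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Latent class profile for cohort simulation
#'
#' Describes one mixture component of a synthetic cohort: its risk-tier
#' label, mixture weight, latent item means and standard deviations on
#' the 1-5 rating scale, and class-conditional normal parameters for the
#' depression (CES-D, 0-60) and anxiety (STAI state, 20-80) totals.
#'
#' @param label Risk tier name, e.g. `"low-risk"`, `"at-risk"`,
#'   `"high-risk"`.
#' @param weight Mixture proportion in `[0, 1]`.
#' @param item_means Numeric vector of 6 latent means, each in `[1, 5]`.
#' @param item_sds Numeric vector of 6 positive latent standard
#'   deviations (recycled from length 1).
#' @param depression_mean,depression_sd CES-D total mean and SD.
#' @param anxiety_mean,anxiety_sd STAI state total mean and SD.
#' @param age_weights Optional length-3 probability vector over the age
#'   bands 18-34, 35-49, 50-65 for members of this class; `NULL` (the
#'   default) draws age from the cohort-level margins.
#'
#' @return An object of class `"class_profile"`.
#' @export
class_profile <- function(label, weight, item_means, item_sds,
                          depression_mean, depression_sd,
                          anxiety_mean, anxiety_sd,
                          age_weights = NULL) {
  if (length(item_sds) == 1L) item_sds <- rep(item_sds, 6L)
  stopifnot(length(item_means) == 6L, length(item_sds) == 6L)
  if (any(item_means < 1 | item_means > 5))
    stop("item_means must lie in [1, 5]", call. = FALSE)
  if (any(item_sds <= 0) || depression_sd <= 0 || anxiety_sd <= 0)
    stop("standard deviations must be positive", call. = FALSE)
  if (weight < 0 || weight > 1)
    stop("weight must lie in [0, 1]", call. = FALSE)
  if (!is.null(age_weights)) {
    stopifnot(length(age_weights) == 3L)
    if (abs(sum(age_weights) - 1) > 1e-12)
      stop("age_weights must sum to 1", call. = FALSE)
  }
  structure(list(label = label, weight = weight,
                 item_means = as.numeric(item_means),
                 item_sds = as.numeric(item_sds),
                 depression_mean = depression_mean,
                 depression_sd = depression_sd,
                 anxiety_mean = anxiety_mean,
                 anxiety_sd = anxiety_sd,
                 age_weights = age_weights),
            class = "class_profile")
}

#' Specification of a synthetic cohort
#'
#' Bundles everything `generate_cohort()` needs: sample size, the list
#' of latent class profiles, demographic margins and the seed. Weights
#' across profiles must sum to 1.
#'
#' @param n Number of respondents (>= 1).
#' @param profiles List of [class_profile()] objects.
#' @param sex_split Proportion male, in `[0, 1]`.
#' @param age_splits Length-3 probability vector for the age bands
#'   18-34, 35-49, 50-65.
#' @param seed Integer seed controlling the cohort draw.
#'
#' @return An object of class `"cohort_spec"`.
#' @seealso [uk_like_spec()], [us_like_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n, profiles, sex_split, age_splits, seed) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer", call. = FALSE)
  if (!length(profiles) || !all(vapply(profiles, inherits, TRUE, "class_profile")))
    stop("profiles must be a non-empty list of class_profile objects",
         call. = FALSE)
  w <- vapply(profiles, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-12)
    stop("profile weights must sum to 1 (got ", format(sum(w)), ")",
         call. = FALSE)
  if (sex_split < 0 || sex_split > 1)
    stop("sex_split must lie in [0, 1]", call. = FALSE)
  stopifnot(length(age_splits) == 3L)
  if (abs(sum(age_splits) - 1) > 1e-12)
    stop("age_splits must sum to 1", call. = FALSE)
  structure(list(n = as.integer(n), profiles = profiles,
                 sex_split = sex_split,
                 age_splits = as.numeric(age_splits),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  n =", x$n, " seed =", x$seed, "\n")
  for (p in x$profiles)
    cat(sprintf("  %-10s w=%.3f  item means: %s\n", p$label, p$weight,
                paste(format(p$item_means, nsmall = 1), collapse = " ")))
  cat("  sex split (male):", x$sex_split,
      " age splits:", paste(x$age_splits, collapse = "/"), "\n")
  invisible(x)
}

#' Default UK-like and US-like cohort specifications
#'
#' Three-class mixtures emulating the published UK (n = 573) and US
#' (n = 474) survey samples: class proportions 55/33.1/11.9% (UK) and
#' 62.2/28.7/9.1% (US); a low-risk class with all item means below
#' 1.34 (UK) / 1.45 (US); an at-risk class endorsing salience,
#' tolerance and mood modification near the scale midpoint but not the
#' remaining criteria; and a high-risk class with all item means above
#' 3.18 (UK) or with salience, tolerance, mood modification and
#' withdrawal above 3.34 but loss of control and conflict below the
#' midpoint (US). Class-conditional depression and anxiety parameters
#' reproduce the published high-risk vs low-to-at-risk contrast.
#'
#' @param n Cohort size; defaults match the survey samples.
#' @param seed Seed stored in the specification.
#'
#' @return A [cohort_spec()].
#' @export
uk_like_spec <- function(n = 573, seed = 20201L) {
  cohort_spec(
    n = n,
    profiles = list(
      class_profile("low-risk", 0.55, rep(1.2, 6), 0.7,
                    depression_mean = 14.8, depression_sd = 10.39,
                    anxiety_mean = 37.5, anxiety_sd = 12.56),
      class_profile("at-risk", 0.331, c(2.8, 2.8, 2.9, 1.8, 1.8, 1.8), 0.7,
                    depression_mean = 17.3, depression_sd = 10.39,
                    anxiety_mean = 41.1, anxiety_sd = 12.56),
      class_profile("high-risk", 0.119, c(3.6, 3.7, 3.8, 3.5, 3.6, 3.5), 0.7,
                    depression_mean = 26.59, depression_sd = 12.70,
                    anxiety_mean = 50.10, anxiety_sd = 14.01)),
    sex_split = 0.456,
    age_splits = c(0.335, 0.333, 0.332),
    seed = seed)
}

#' @rdname uk_like_spec
#' @export
us_like_spec <- function(n = 474, seed = 20202L) {
  cohort_spec(
    n = n,
    profiles = list(
      class_profile("low-risk", 0.622, rep(1.3, 6), 0.7,
                    depression_mean = 14.9, depression_sd = 10.65,
                    anxiety_mean = 36.9, anxiety_sd = 13.04),
      class_profile("at-risk", 0.287, c(2.9, 2.85, 3.0, 1.7, 1.7, 1.7), 0.7,
                    depression_mean = 17.2, depression_sd = 10.65,
                    anxiety_mean = 40.1, anxiety_sd = 13.04),
      class_profile("high-risk", 0.091, c(3.6, 3.5, 3.7, 2.7, 3.5, 2.8), 0.7,
                    depression_mean = 24.00, depression_sd = 11.02,
                    anxiety_mean = 45.98, anxiety_sd = 13.07)),
    sex_split = 0.474,
    age_splits = c(0.356, 0.321, 0.323),
    seed = seed)
}

round_clip <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

#' Generate a synthetic respondent cohort
#'
#' Draws a cohort from a mixture specification. Class membership is
#' multinomial in the profile weights; each item rating is a normal
#' deviate with the class's latent mean/SD, rounded to the nearest
#' integer and clipped to 1-5; depression and anxiety totals are
#' class-conditional normals rounded and clipped to their scale ranges
#' (0-60 and 20-80); sex and age are drawn from the cohort margins
#' independently of class (unless a profile carries `age_weights`).
#' The same specification (including its seed) always yields the
#' identical table.
#'
#' @param spec A [cohort_spec()].
#' @param keep_truth Keep the generating class in a `true_class`
#'   column? Analysis functions never read this column; it exists for
#'   parameter-recovery checks. Default `TRUE`.
#'
#' @return A data frame with columns `bsmas1`..`bsmas6`, `sex`,
#'   `age_group`, `cesd_total`, `stai_total` and optionally
#'   `true_class`.
#' @examples
#' head(generate_cohort(uk_like_spec(n = 100)))
#' @export
generate_cohort <- function(spec, keep_truth = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  K <- length(spec$profiles)
  w <- vapply(spec$profiles, `[[`, numeric(1), "weight")
  with_seed(spec$seed, {
    z <- sample.int(K, n, replace = TRUE, prob = w)
    ratings <- matrix(0L, n, 6L, dimnames = list(NULL, BSMAS_COLS))
    dep <- anx <- numeric(n)
    for (k in seq_len(K)) {
      idx <- which(z == k)
      if (!length(idx)) next
      p <- spec$profiles[[k]]
      for (j in 1:6)
        ratings[idx, j] <- as.integer(round_clip(
          rnorm(length(idx), p$item_means[j], p$item_sds[j]), 1, 5))
      dep[idx] <- round_clip(rnorm(length(idx), p$depression_mean,
                                   p$depression_sd), 0, 60)
      anx[idx] <- round_clip(rnorm(length(idx), p$anxiety_mean,
                                   p$anxiety_sd), 20, 80)
    }
    sex <- sample(SEX_LEVELS, n, replace = TRUE,
                  prob = c(spec$sex_split, 1 - spec$sex_split))
    age <- sample(AGE_BANDS, n, replace = TRUE, prob = spec$age_splits)
    for (k in seq_len(K)) {
      aw <- spec$profiles[[k]]$age_weights
      if (!is.null(aw)) {
        idx <- which(z == k)
        if (length(idx))
          age[idx] <- sample(AGE_BANDS, length(idx), replace = TRUE, prob = aw)
      }
    }
    out <- data.frame(ratings, sex = factor(sex, SEX_LEVELS),
                      age_group = factor(age, AGE_BANDS),
                      cesd_total = as.integer(dep),
                      stai_total = as.integer(anx))
    if (keep_truth) out$true_class <- z
    out
  })
}

#' Read and write respondent cohorts as CSV
#'
#' The on-disk format is a plain CSV with the fixed header
#' `bsmas1,...,bsmas6,sex,age_group,cesd_total,stai_total[,true_class]`.
#'
#' @param x A cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns a validated cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(BSMAS_COLS, "sex", "age_group", "cesd_total", "stai_total"),
                  names(x))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$sex <- factor(x$sex, SEX_LEVELS)
  x$age_group <- factor(x$age_group, AGE_BANDS)
  x
}

spec_to_list <- function(spec) {
  list(n = spec$n, sex_split = spec$sex_split, age_splits = spec$age_splits,
       seed = spec$seed,
       profiles = lapply(spec$profiles, function(p)
         p[!vapply(p, is.null, TRUE)]))
}

list_to_spec <- function(l) {
  cohort_spec(n = l$n,
              profiles = lapply(l$profiles, function(p)
                class_profile(p$label, p$weight, unlist(p$item_means),
                              unlist(p$item_sds),
                              p$depression_mean, p$depression_sd,
                              p$anxiety_mean, p$anxiety_sd,
                              age_weights = if (!is.null(p$age_weights))
                                unlist(p$age_weights))),
              sex_split = l$sex_split, age_splits = unlist(l$age_splits),
              seed = l$seed)
}

#' Serialise a cohort specification
#'
#' Specifications round-trip through JSON (always available) or YAML
#' (if the yaml package is installed); the format is chosen from the
#' file extension.
#'
#' @param spec A [cohort_spec()].
#' @param path Destination ending in `.json`, `.yaml` or `.yml`.
#' @return `read_spec()` returns a [cohort_spec()].
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  l <- spec_to_list(spec)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML output", call. = FALSE)
    writeLines(yaml::as.yaml(l), path)
  } else {
    jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  l <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  list_to_spec(l)
}
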