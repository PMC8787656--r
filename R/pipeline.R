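## End-to-end orchestration: cohort -> schemes -> LPA benchmark ->
## concordance -> comorbidity -> report bundle.

child_seed <- function(master, stage) {
  ## documented derivation: offsets in units of 99991 (a prime), folded
  ## into the 32-bit integer range, so toggling one stage never
  ## perturbs another stage's stream
  as.integer((as.numeric(master) + 99991 * stage) %% .Machine$integer.max)
}

#' Configuration of a full pipeline run
#'
#' @param input Optional path to a cohort CSV (see [read_cohort()]).
#'   When `NULL`, a cohort is simulated from `spec`.
#' @param spec A [cohort_spec()] used when `input` is `NULL`; its seed
#'   is replaced by a child seed of `seed`.
#' @param k_range Candidate class counts for the latent benchmark
#'   (default 2:5).
#' @param schemes Character vector of scheme names (default all four).
#' @param n_starts EM starts per fit.
#' @param blrt Run the bootstrap LRT in the model comparison?
#' @param n_boot Bootstrap replicates (must be >= 1 when `blrt`).
#' @param tol EM convergence tolerance.
#' @param seed Master seed; every stochastic stage consumes a
#'   deterministic child seed derived from it.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input = NULL, spec = uk_like_spec(), k_range = 2:5,
                       schemes = names(sma_schemes()), n_starts = 50,
                       blrt = TRUE, n_boot = 99, tol = 1e-6, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range) || min(k_range) < 1)
    stop("k_range must be nonempty with minimum >= 1", call. = FALSE)
  if (blrt && n_boot < 1)
    stop("n_boot must be >= 1 when the bootstrap LRT is enabled",
         call. = FALSE)
  schemes <- match.arg(schemes, names(sma_schemes()), several.ok = TRUE)
  structure(list(input = input, spec = spec, k_range = k_range,
                 schemes = schemes, n_starts = n_starts, blrt = blrt,
                 n_boot = n_boot, tol = tol, seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a respondent table
#'
#' Enforces the row contracts: integer ratings in 1-5, depression
#' total in 0-60, anxiety total in 20-80, sex and age group in their
#' category domains. Invalid rows are rejected (never imputed) and
#' logged with row numbers and reasons; if every row is rejected the
#' call fails.
#'
#' @param table A cohort data frame.
#' @return List with `data` (clean rows) and `rejections` (data frame
#'   of `row`, `reason`).
#' @export
validate_cohort <- function(table) {
  need <- c(BSMAS_COLS, "sex", "age_group", "cesd_total", "stai_total")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(table)) stop("input table has no rows", call. = FALSE)
  reasons <- rep(NA_character_, nrow(table))
  note <- function(bad, why)
    reasons[is.na(reasons) & bad] <<- why
  r <- as.matrix(table[BSMAS_COLS])
  note(apply(is.na(r) | r < 1 | r > 5 | r != round(r), 1, any),
       "rating outside 1-5")
  note(is.na(table$cesd_total) | table$cesd_total < 0 |
         table$cesd_total > 60, "depression total outside 0-60")
  note(is.na(table$stai_total) | table$stai_total < 20 |
         table$stai_total > 80, "anxiety total outside 20-80")
  note(!(as.character(table$sex) %in% SEX_LEVELS), "unknown sex category")
  note(!(as.character(table$age_group) %in% AGE_BANDS),
       "unknown age band")
  bad <- which(!is.na(reasons))
  rejections <- data.frame(row = bad, reason = reasons[bad])
  clean <- table[setdiff(seq_len(nrow(table)), bad), , drop = FALSE]
  if (!nrow(clean))
    stop(sprintf("all %d rows rejected (first reason: %s)",
                 nrow(table), reasons[bad[1]]), call. = FALSE)
  clean$sex <- factor(as.character(clean$sex), SEX_LEVELS)
  clean$age_group <- factor(as.character(clean$age_group), AGE_BANDS)
  list(data = clean, rejections = rejections)
}

## Prevalence by scheme and stratum with demographic risk ratios
## (reference strata: female; ages 50-65).
prevalence_report <- function(data, labels_list) {
  strata <- list(total = rep(TRUE, nrow(data)))
  rows <- lapply(names(labels_list), function(nm) {
    lab <- labels_list[[nm]]
    tot <- prevalence(lab)
    sex <- prevalence(lab, data$sex)
    age <- prevalence(lab, data$age_group)
    df <- rbind(tot, sex, age)
    df <- cbind(scheme = nm, df)
    rr <- rep(NA_real_, nrow(df)); ref <- rep("", nrow(df))
    srr <- demographic_rr(lab, data$sex, "female")
    arr <- demographic_rr(lab, data$age_group, "50-65")
    for (lv in names(srr)) rr[df$stratum == lv] <- srr[[lv]]$rr
    for (lv in names(arr)) rr[df$stratum == lv] <- arr[[lv]]$rr
    ref[df$stratum %in% c("female", "50-65")] <- "Ref"
    df$rr <- rr; df$reference <- ref
    df
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## Table-5-like descriptives: per classification, depression and
## anxiety in high-risk vs low-to-at-risk groups with one-tailed tests.
descriptives_report <- function(data, labels_list) {
  rows <- list()
  for (nm in names(labels_list)) {
    lab <- labels_list[[nm]]
    for (sc in c(depression = "cesd_total", anxiety = "stai_total")) {
      g <- group_comparison(data[[sc]], lab)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = nm,
        outcome = if (sc == "cesd_total") "depression" else "anxiety",
        n_high = g$n_high, mean_high = g$mean_high, sd_high = g$sd_high,
        n_rest = g$n_rest, mean_rest = g$mean_rest, sd_rest = g$sd_rest,
        t = g$t, p_one_tailed = g$p, computable = g$computable)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## Table-6-like risk ratios: scale level per classification, then item
## level at cutoffs 4 and 3.
rr_report <- function(data, labels_list) {
  dep <- probable_case(data$cesd_total, "depression")
  anx <- probable_case(data$stai_total, "anxiety")
  scale_rows <- lapply(names(labels_list), function(nm) {
    data.frame(panel = "scale", exposure = nm,
               rr_depression = risk_ratio(labels_list[[nm]], dep)$rr,
               rr_anxiety = risk_ratio(labels_list[[nm]], anx)$rr)
  })
  item_rows <- lapply(c(4L, 3L), function(cut) {
    rd <- item_level_rr(data, cut, dep)
    ra <- item_level_rr(data, cut, anx)
    data.frame(panel = sprintf("item cutoff %d", cut),
               exposure = BSMAS_ITEMS,
               rr_depression = vapply(rd, `[[`, 0, "rr"),
               rr_anxiety = vapply(ra, `[[`, 0, "rr"))
  })
  do.call(rbind, c(scale_rows, item_rows, list(make.row.names = FALSE)))
}

#' Run the full classification-benchmarking pipeline
#'
#' Executes the complete workflow: obtain a cohort (from file or by
#' simulation), validate it, classify with the requested schemes, fit
#' and select the latent profile benchmark, evaluate concordance, and
#' compute comorbidity descriptives and risk ratios. All stochastic
#' stages consume deterministic child seeds of the master seed, so an
#' identical configuration yields a byte-identical report bundle.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, all reports are
#'   written there as CSV plus a JSON manifest (see [write_bundle()]).
#' @return An object of class `"sma_report_bundle"`: a list with the
#'   model-comparison, prevalence, concordance, descriptives and
#'   risk-ratio reports, the profile plot data, per-respondent
#'   assignments, and a run manifest. If a stage fails the bundle is
#'   returned with `manifest$partial = TRUE` and the error recorded.
#' @examples
#' \donttest{
#' cfg <- run_config(spec = uk_like_spec(n = 200), k_range = 2:3,
#'                   n_starts = 10, seed = 7)
#' bundle <- run_pipeline(cfg)
#' bundle$concordance
#' }
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(simulate = child_seed(config$seed, 1),
                lpa = child_seed(config$seed, 2))
  errors <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
  }

  raw <- if (!is.null(config$input)) read_cohort(config$input)
         else {
           spec <- config$spec
           spec$seed <- seeds$simulate
           generate_cohort(spec)
         }
  val <- validate_cohort(raw)
  data <- val$data
  adata <- data[setdiff(names(data), "true_class")]

  scheme_labels <- lapply(sma_schemes()[config$schemes],
                          function(sc) apply_scheme(adata, sc))
  names(scheme_labels) <- config$schemes

  scan <- stage("lpa", lpa_scan(adata, k_range = config$k_range,
                                blrt = config$blrt, n_boot = config$n_boot,
                                seed = seeds$lpa, n_starts = config$n_starts,
                                tol = config$tol))
  selection <- if (!is.null(scan))
    stage("select_model", select_model(scan)) else NULL
  model <- if (!is.null(selection)) scan$models[[paste0("K", selection$K)]]
  assignments <- if (!is.null(model)) assign_risk(model)

  all_labels <- scheme_labels
  if (!is.null(assignments))
    all_labels[["latent profile"]] <- assignments$highrisk

  bundle <- list(
    fit_report = if (!is.null(scan)) scan$report,
    prevalence = stage("prevalence", prevalence_report(adata, all_labels)),
    concordance = if (!is.null(assignments))
      stage("concordance",
            scheme_benchmark_report(adata, sma_schemes()[config$schemes],
                                    assignments$highrisk)),
    descriptives = stage("descriptives",
                         descriptives_report(adata, all_labels)),
    risk_ratios = stage("risk_ratios", rr_report(adata, all_labels)),
    profile_plot_data = if (!is.null(model)) profile_data(model),
    assignments = if (!is.null(assignments))
      cbind(assignments,
            posterior = round(model$posterior, 6)),
    manifest = list(
      package = "smaclass",
      package_version = as.character(packageVersion("smaclass")),
      r_version = R.version.string,
      config = list(input = config$input,
                    spec = if (is.null(config$input))
                      spec_to_list(config$spec),
                    k_range = config$k_range, schemes = config$schemes,
                    n_starts = config$n_starts, blrt = config$blrt,
                    n_boot = config$n_boot, tol = config$tol,
                    seed = config$seed),
      child_seeds = seeds,
      n_input = nrow(raw), n_analysed = nrow(data),
      n_rejected = nrow(val$rejections),
      selected_k = if (!is.null(selection)) selection$K,
      selection_audit = if (!is.null(selection)) selection$audit,
      entropy_selected = if (!is.null(model)) model$entropy,
      cronbach_alpha = cronbach_alpha(adata[BSMAS_COLS]),
      partial = length(errors) > 0,
      errors = errors))
  bundle$rejections <- val$rejections
  class(bundle) <- "sma_report_bundle"
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' @export
print.sma_report_bundle <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline report bundle",
      if (isTRUE(m$partial)) "(PARTIAL)" else "", "\n")
  cat(sprintf("  n analysed %d (rejected %d); selected K = %s\n",
              m$n_analysed, m$n_rejected,
              if (is.null(m$selected_k)) "-" else m$selected_k))
  cat("  reports:", paste(names(x)[!vapply(x, is.null, TRUE) &
                                     names(x) != "manifest"],
                          collapse = ", "), "\n")
  if (length(m$errors)) cat("  errors:", paste(m$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes each report as CSV plus the manifest as JSON. The manifest
#' (configuration echo, seeds, versions) suffices to reproduce the
#' run bit-for-bit with the same package build; no timestamps are
#' recorded, so identical runs produce byte-identical bundles.
#'
#' @param bundle An [run_pipeline()] result.
#' @param outdir Directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "sma_report_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("fit_report", "prevalence", "concordance", "descriptives",
              "risk_ratios", "profile_plot_data", "assignments",
              "rejections")
  for (nm in tables)
    if (!is.null(bundle[[nm]]))
      write.csv(as.data.frame(bundle[[nm]]),
                file.path(outdir, paste0(nm, ".csv")), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(outdir)
}
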