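## Latent profile analysis: finite Gaussian mixtures with conditionally
## independent indicators, fitted by multi-start EM.

lpa_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (all(BSMAS_COLS %in% names(x))) x <- x[BSMAS_COLS]
    x <- as.matrix(x[vapply(x, is.numeric, TRUE)])
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("indicator data must be finite", call. = FALSE)
  x
}

data_hash <- function(X) c(nrow(X), ncol(X), sum(X), sum(X^2))

## Log density of each row under each component; n x K matrix.
component_logdens <- function(X, means, sigma2) {
  K <- nrow(means)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    s <- sqrt(sigma2[k, ])
    ld <- 0
    for (j in seq_len(ncol(X)))
      ld <- ld + dnorm(X[, j], means[k, j], s[j], log = TRUE)
    out[, k] <- ld
  }
  out
}

posterior_matrix <- function(X, weights, means, sigma2) {
  ld <- sweep(component_logdens(X, means, sigma2), 2, log(weights), `+`)
  m <- apply(ld, 1, max)
  p <- exp(ld - m)
  p / rowSums(p)
}

sigma2_matrix <- function(object) {
  if (object$variance_structure == "equal")
    matrix(object$variances, object$K, length(object$variances),
           byrow = TRUE)
  else object$variances
}

n_params_lpa <- function(K, J, variance_structure) {
  if (variance_structure == "equal") (K - 1) + J * K + J
  else (K - 1) + 2 * J * K
}

random_start <- function(X, K) {
  n <- nrow(X)
  mu <- X[sample.int(n, K), , drop = FALSE]
  mu <- mu + matrix(rnorm(length(mu), 0, 0.1), nrow(mu))
  v <- apply(X, 2, stats::var) * (n - 1) / n
  list(w = rep(1 / K, K), mu = mu,
       s2 = matrix(pmax(v, 1e-3), K, ncol(X), byrow = TRUE))
}

kmeans_start <- function(X, K) {
  km <- tryCatch(suppressWarnings(kmeans(X, K, nstart = 5)),
                 error = function(e) NULL)
  if (is.null(km)) return(random_start(X, K))
  v <- apply(X, 2, stats::var) * (nrow(X) - 1) / nrow(X)
  list(w = pmax(km$size / nrow(X), 1 / nrow(X)), mu = km$centers,
       s2 = matrix(pmax(v, 1e-3), K, ncol(X), byrow = TRUE))
}

#' Fit a latent profile model
#'
#' Fits a `K`-class finite Gaussian mixture with conditionally
#' independent indicators (a latent profile model) by multi-start EM.
#' The default variance structure is class-invariant: one variance per
#' indicator shared across classes; `variance = "varying"` estimates a
#' full `K` x `J` variance matrix. Starts follow a two-stage regime:
#' `n_starts` initialisations (one k-means-based, the rest random
#' respondent rows) are run for `burn_iter` EM iterations, and the
#' `n_final` best by log-likelihood are run to convergence (absolute
#' log-likelihood change below `tol`). Within every run the
#' log-likelihood is non-decreasing; the trace of the winning run is
#' retained in the fitted object. Components are reported in ascending
#' order of their profile mean, so class 1 is always the least severe.
#'
#' A variance floor (default 0.001 on the 1-5 rating scale) prevents
#' degenerate density spikes; fits that activate it carry
#' `floored = TRUE`.
#'
#' @param x Cohort data frame (its `bsmas1`..`bsmas6` columns are
#'   used) or a numeric matrix of indicators.
#' @param K Number of latent classes (>= 1). `K = 1` is fitted in
#'   closed form.
#' @param variance `"equal"` (class-invariant, default) or
#'   `"varying"`.
#' @param n_starts,burn_iter,n_final Multi-start regime (defaults 50
#'   starts, 20 burn-in iterations, top 5 run to convergence).
#' @param max_iter Iteration cap for the convergence stage.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param var_floor Lower bound for estimated variances.
#' @param seed Optional seed for the random starts; `NULL` uses the
#'   current RNG stream.
#'
#' @return An object of class `"lpa"` with components `weights`,
#'   `means` (`K` x `J`), `variances`, `loglik`, `n_params`, `n_obs`,
#'   `posterior`, `entropy`, `converged`, `floored`, `ll_trace`.
#' @examples
#' fit <- lpa(generate_cohort(uk_like_spec(n = 300)), K = 3,
#'            n_starts = 10, seed = 1)
#' summary(fit)
#' @export
lpa <- function(x, K, variance = c("equal", "varying"), n_starts = 50,
                burn_iter = 20, n_final = 5, max_iter = 500, tol = 1e-6,
                var_floor = 1e-3, seed = NULL) {
  variance <- match.arg(variance)
  X <- lpa_matrix(x)
  n <- nrow(X); J <- ncol(X)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (n <= J * K)
    stop(sprintf("n = %d is too small to identify %d classes on %d indicators",
                 n, K, J), call. = FALSE)

  if (K == 1) {
    mu <- matrix(colMeans(X), 1, J)
    v <- colMeans(sweep(X, 2, mu[1, ])^2)
    v <- pmax(v, var_floor)
    s2 <- matrix(v, 1, J)
    ll <- sum(component_logdens(X, mu, s2))
    fit <- list(weights = 1, means = mu, sigma2 = s2, loglik = ll,
                trace = ll, converged = TRUE, floored = any(v == var_floor),
                posterior = matrix(1, n, 1))
  } else {
    fit <- with_seed(seed, {
      starts <- c(list(kmeans_start(X, K)),
                  replicate(max(n_starts - 1L, 0L), random_start(X, K),
                            simplify = FALSE))
      burns <- lapply(starts, function(s)
        cpp_em(X, s$w, s$mu, s$s2, variance == "equal", burn_iter, tol,
               var_floor))
      ok <- !vapply(burns, `[[`, TRUE, "degenerate")
      if (!any(ok)) {
        best <- burns[[which.max(vapply(burns, `[[`, 0, "loglik"))]]
        stop(structure(class = c("lpa_degenerate_error", "error", "condition"),
                       list(message = "all EM starts collapsed to a degenerate component",
                            call = sys.call(-1), best_partial = best)))
      }
      burns <- burns[ok]
      keep <- order(vapply(burns, `[[`, 0, "loglik"),
                    decreasing = TRUE)[seq_len(min(n_final, length(burns)))]
      finals <- lapply(burns[keep], function(b)
        c(cpp_em(X, b$weights, b$means, b$sigma2, variance == "equal",
                 max_iter, tol, var_floor), list(burn_trace = b$trace)))
      ok <- !vapply(finals, `[[`, TRUE, "degenerate")
      if (!any(ok))
        stop("all EM runs collapsed to a degenerate component", call. = FALSE)
      finals <- finals[ok]
      finals[[which.max(vapply(finals, `[[`, 0, "loglik"))]]
    })
    fit$trace <- c(fit$burn_trace, fit$trace)
  }

  ## canonical order: ascending profile mean (least to most severe)
  ord <- order(rowMeans(fit$means))
  weights <- as.numeric(fit$weights)[ord]
  means <- fit$means[ord, , drop = FALSE]
  s2 <- fit$sigma2[ord, , drop = FALSE]
  post <- fit$posterior[, ord, drop = FALSE]
  items <- colnames(X)
  if (is.null(items)) items <- paste0("item", seq_len(J))
  dimnames(means) <- list(paste0("class", seq_len(K)), items)
  variances <- if (variance == "equal") stats::setNames(s2[1, ], items)
               else structure(s2, dimnames = dimnames(means))

  structure(list(K = K, weights = weights, means = means,
                 variances = variances, variance_structure = variance,
                 loglik = fit$loglik,
                 n_params = n_params_lpa(K, J, variance), n_obs = n,
                 converged = fit$converged, floored = fit$floored,
                 posterior = post, entropy = entropy_from_posterior(post),
                 ll_trace = fit$trace, items = items,
                 data_hash = data_hash(X), seed = seed,
                 call = match.call()),
            class = "lpa")
}

#' @export
print.lpa <- function(x, ...) {
  cat(sprintf("Latent profile model: K = %d classes, %d indicators, n = %d\n",
              x$K, length(x$items), x$n_obs))
  cat(sprintf("  log-likelihood %.3f  (%d parameters, %s variances%s)\n",
              x$loglik, x$n_params, x$variance_structure,
              if (x$converged) "" else ", NOT converged"))
  cat("  class weights:", paste(sprintf("%.3f", x$weights), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.lpa <- function(object, ...) {
  ic <- fit_indices(object)
  structure(list(model = object, indices = ic,
                 entropy = object$entropy),
            class = "summary.lpa")
}

#' @export
print.summary.lpa <- function(x, ...) {
  print(x$model)
  cat(sprintf("  BIC %.2f  SSABIC %.2f  AIC %.2f  entropy %.3f\n",
              x$indices["BIC"], x$indices["SSABIC"], x$indices["AIC"],
              x$entropy))
  cat("\nClass profiles (means):\n")
  print(round(x$model$means, 3))
  cat("\nIndicator variances:\n")
  print(round(x$model$variances, 3))
  invisible(x)
}

#' @export
coef.lpa <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       variances = object$variances)
}

#' @export
logLik.lpa <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Posterior class probabilities or modal classes
#'
#' @param object A fitted [lpa()] model.
#' @param newdata Optional new indicator data; defaults to the
#'   training posterior.
#' @param type `"class"` for modal assignment (ties go to the
#'   lower-index, i.e. less severe, class) or `"posterior"` for the
#'   full probability matrix.
#' @param ... Unused.
#' @return Integer vector or n x K matrix.
#' @export
predict.lpa <- function(object, newdata = NULL,
                        type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  post <- if (is.null(newdata)) object$posterior
          else posterior_matrix(lpa_matrix(newdata), object$weights,
                                object$means, sigma2_matrix(object))
  if (type == "posterior") post else max.col(post, ties.method = "first")
}

#' Simulate indicator data from a fitted latent profile model
#'
#' Draws continuous data from the fitted mixture (no rounding to the
#' rating scale); this is the parametric-bootstrap generator used by
#' [blrt()].
#'
#' @param object A fitted [lpa()] model.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param n Rows per dataset; defaults to the training size.
#' @param ... Unused.
#' @return A matrix if `nsim = 1`, else a list of matrices.
#' @export
simulate.lpa <- function(object, nsim = 1, seed = NULL,
                         n = object$n_obs, ...) {
  s2 <- sigma2_matrix(object)
  J <- ncol(object$means)
  one <- function() {
    z <- sample.int(object$K, n, replace = TRUE, prob = object$weights)
    X <- matrix(0, n, J, dimnames = list(NULL, object$items))
    for (k in seq_len(object$K)) {
      idx <- which(z == k)
      if (!length(idx)) next
      for (j in seq_len(J))
        X[idx, j] <- rnorm(length(idx), object$means[k, j], sqrt(s2[k, j]))
    }
    X
  }
  with_seed(seed, {
    if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
  })
}

#' Profile plot of a fitted latent profile model
#'
#' Plots class mean profiles across the indicators (one line per
#' class). Use [profile_data()] for the underlying numbers.
#'
#' @param x A fitted [lpa()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lpa <- function(x, ...) {
  graphics::matplot(t(x$means), type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "criterion", ylab = "mean rating",
                    ylim = c(1, 5), ...)
  graphics::axis(1, at = seq_along(x$items), labels = x$items, las = 2,
                 cex.axis = 0.8)
  graphics::legend("topleft", legend = sprintf("class %d (%.1f%%)",
                                               seq_len(x$K), 100 * x$weights),
                   col = seq_len(x$K), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' @rdname plot.lpa
#' @return `profile_data()` returns a data frame of class-by-item
#'   means in long format (columns `class`, `item`, `mean`).
#' @export
profile_data <- function(x) {
  stopifnot(inherits(x, "lpa"))
  data.frame(class = rep(rownames(x$means), ncol(x$means)),
             item = rep(colnames(x$means), each = nrow(x$means)),
             mean = as.vector(x$means))
}

#' Information criteria for a latent profile model
#'
#' `BIC = -2LL + p log n`, `AIC = -2LL + 2p`, and the
#' sample-size-adjusted `SSABIC = -2LL + p log((n + 2) / 24)`; lower
#' values indicate better fit.
#'
#' @param model A fitted [lpa()] model.
#' @return Named numeric vector `c(BIC, SSABIC, AIC)`.
#' @examples
#' # with LL = -100, p = 5, n = 100: AIC 210, BIC 223.03, SSABIC 207.23
#' @export
fit_indices <- function(model) {
  stopifnot(inherits(model, "lpa"))
  n <- model$n_obs
  if (n <= 0) stop("model has no observations", call. = FALSE)
  p <- model$n_params; ll <- model$loglik
  c(BIC = -2 * ll + p * log(n),
    SSABIC = -2 * ll + p * log((n + 2) / 24),
    AIC = -2 * ll + 2 * p)
}

entropy_from_posterior <- function(post) {
  K <- ncol(post)
  if (K == 1) return(1)
  p <- pmax(post, .Machine$double.xmin)
  1 - sum(-p * log(p)) / (nrow(post) * log(K))
}

#' Relative entropy of a classification
#'
#' `E = 1 - sum_i sum_k (-p_ik log p_ik) / (n log K)`: 1 for one-hot
#' (perfectly certain) posteriors, 0 for uniform ones. By convention a
#' one-class model has entropy 1 (assignment is trivially certain);
#' that value is excluded from the `< 0.80` screening rule in
#' [select_model()].
#'
#' @param x A fitted [lpa()] model or an n x K posterior matrix whose
#'   rows sum to 1.
#' @return A number in `[0, 1]`.
#' @export
lpa_entropy <- function(x) {
  if (inherits(x, "lpa")) return(x$entropy)
  x <- as.matrix(x)
  if (any(x < -1e-10 | x > 1 + 1e-10))
    stop("posterior entries must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(x) - 1) > 1e-8))
    stop("posterior rows must sum to 1", call. = FALSE)
  entropy_from_posterior(x)
}

#' Bootstrap likelihood ratio test for K vs K - 1 classes
#'
#' Parametric bootstrap: the observed statistic is
#' `2 (LL_K - LL_(K-1))` on the data; each replicate simulates a
#' same-size dataset from the fitted `K - 1` model and refits both
#' models. The p-value is `(1 + #(replicate >= observed)) /
#' (n_boot + 1)`. Replicates whose fits collapse are redrawn up to
#' `retry_cap` times, then excluded with a warning.
#'
#' When the observed indicators are integer ratings (e.g. the 1-5
#' symptom scale), replicates are drawn on the same discrete support:
#' a class is drawn from the fitted `K - 1` weights and each item
#' from the empirical (nonparametric) item distribution within that
#' class's modal-assignment stratum. This is the conditional-
#' independence null with the observed within-class item shapes.
#' Simulating continuous Gaussian data instead would let the
#' discreteness of the rating scale inflate the observed statistic
#' relative to the null draws, and the test would keep rejecting
#' spurious extra classes that merely absorb rounding structure. Set
#' `discretize` explicitly to override the automatic detection.
#'
#' @param x Cohort data frame or indicator matrix.
#' @param K Number of classes under the alternative (>= 2).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Optional seed governing the whole test.
#' @param n_starts,burn_iter,n_final Reduced multi-start regime for
#'   the many internal fits.
#' @param variance Variance structure passed to [lpa()].
#' @param discretize `NULL` (auto: `TRUE` when every observed value is
#'   an integer), or logical: round and clip replicate draws to the
#'   observed integer grid.
#' @param retry_cap Redraw attempts per failed replicate.
#' @return An object of class `"htest"` with the observed statistic,
#'   p-value and number of replicates used.
#' @export
blrt <- function(x, K, n_boot = 99, seed = NULL, n_starts = 5,
                 burn_iter = 10, n_final = 2,
                 variance = c("equal", "varying"), discretize = NULL,
                 retry_cap = 3) {
  variance <- match.arg(variance)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  X <- lpa_matrix(x)
  if (is.null(discretize)) discretize <- all(X == round(X))
  fit2 <- function(dat) {
    m0 <- lpa(dat, K - 1, variance = variance, n_starts = n_starts,
              burn_iter = burn_iter, n_final = n_final)
    m1 <- lpa(dat, K, variance = variance, n_starts = n_starts,
              burn_iter = burn_iter, n_final = n_final)
    list(stat = 2 * (m1$loglik - m0$loglik), null = m0)
  }
  with_seed(seed, {
    obs <- fit2(X)
    ## null generator: Gaussian draws from the K-1 fit, or for rating
    ## data the class-conditional empirical item distributions
    draw_null <- if (!discretize) {
      function() simulate(obs$null, n = nrow(X))
    } else {
      cls <- predict(obs$null)
      pool <- lapply(seq_len(obs$null$K), function(k) {
        rows <- which(cls == k)
        if (length(rows) < 2) seq_len(nrow(X)) else rows
      })
      function() {
        z <- sample.int(obs$null$K, nrow(X), replace = TRUE,
                        prob = obs$null$weights)
        out <- matrix(0, nrow(X), ncol(X))
        for (k in seq_len(obs$null$K)) {
          idx <- which(z == k)
          if (!length(idx)) next
          for (j in seq_len(ncol(X)))
            out[idx, j] <- sample(X[pool[[k]], j], length(idx),
                                  replace = TRUE)
        }
        out
      }
    }
    reps <- numeric(0)
    dropped <- 0L
    for (b in seq_len(n_boot)) {
      got <- NA_real_
      for (try in seq_len(retry_cap)) {
        sim <- draw_null()
        r <- tryCatch(fit2(sim)$stat, error = function(e) NA_real_)
        if (is.finite(r)) { got <- r; break }
      }
      if (is.finite(got)) reps <- c(reps, got) else dropped <- dropped + 1L
    }
    if (dropped > 0L)
      warning(sprintf("%d bootstrap replicate(s) excluded after repeated non-convergence",
                      dropped))
    p <- (1 + sum(reps >= obs$stat)) / (length(reps) + 1)
    structure(list(statistic = c(LRT = obs$stat), p.value = p,
                   parameter = c(K = K, n_boot = length(reps)),
                   method = "Parametric bootstrap likelihood ratio test (K vs K-1 classes)",
                   data.name = deparse(substitute(x)),
                   replicates = reps),
              class = "htest")
  })
}

#' Approximate adjusted likelihood ratio test for K vs K - 1 classes
#'
#' An approximation in the spirit of the Lo-Mendell-Rubin adjusted
#' test: the statistic `2 (LL_K - LL_(K-1))` is shrunk by the ad hoc
#' factor `c = 1 + 1 / (d log n)` (with `d` the parameter difference)
#' and referred to a chi-squared distribution with `d` degrees of
#' freedom. This reference distribution is *approximate* (the
#' regularity conditions for the classical LRT fail at the mixture
#' boundary, making the test conservative); [blrt()] is the
#' authoritative test when the two disagree. A significant result
#' indicates that the K-class model improves on the K - 1 class model.
#'
#' @param model_K,model_Km1 Fitted [lpa()] models on the same data
#'   with `model_K$K == model_Km1$K + 1`.
#' @return An object of class `"htest"`.
#' @export
adjusted_lrt <- function(model_K, model_Km1) {
  stopifnot(inherits(model_K, "lpa"), inherits(model_Km1, "lpa"))
  if (model_K$K != model_Km1$K + 1)
    stop("models must differ by exactly one class", call. = FALSE)
  if (!isTRUE(all.equal(model_K$data_hash, model_Km1$data_hash)))
    stop("models were fitted to different data", call. = FALSE)
  n <- model_K$n_obs
  d <- model_K$n_params - model_Km1$n_params
  lr <- max(0, 2 * (model_K$loglik - model_Km1$loglik))
  stat <- lr / (1 + 1 / (d * log(n)))
  p <- pchisq(stat, df = d, lower.tail = FALSE)
  structure(list(statistic = c(`adjusted LRT` = stat),
                 parameter = c(df = d), p.value = p,
                 method = paste("Approximate adjusted likelihood ratio test",
                                "(Lo-Mendell-Rubin type; approximate reference",
                                "distribution)"),
                 data.name = sprintf("%d- vs %d-class latent profile models",
                                     model_K$K, model_Km1$K)),
            class = "htest")
}

#' Fit and compare latent profile models over a range of class counts
#'
#' Fits models for each `K` in `k_range` (plus `K - 1` below the range
#' so the first adjusted LRT is defined) and tabulates BIC, SSABIC,
#' AIC, entropy and the adjusted LRT p-value for each `K` vs `K - 1`;
#' optionally also the bootstrap LRT.
#'
#' @param x Cohort data frame or indicator matrix.
#' @param k_range Integer vector of candidate class counts (default
#'   `2:5`).
#' @param blrt Also run the bootstrap LRT for each comparison?
#' @param n_boot Bootstrap replicates when `blrt = TRUE`.
#' @param blrt_stop_early Stop bootstrap testing at the first
#'   non-significant comparison (sequential class enumeration); later
#'   comparisons are recorded as `NA`. Default `TRUE`.
#' @param seed Optional seed governing all fits.
#' @param ... Passed to [lpa()] (e.g. `n_starts`, `variance`).
#' @return An object of class `"lpa_scan"`: a list with the
#'   comparison table `report` (one row per `K`) and the fitted
#'   `models`.
#' @export
lpa_scan <- function(x, k_range = 2:5, blrt = FALSE, n_boot = 99,
                     blrt_stop_early = TRUE, seed = NULL, ...) {
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range) || min(k_range) < 1)
    stop("k_range must be a nonempty set of class counts >= 1", call. = FALSE)
  X <- lpa_matrix(x)
  ks <- sort(unique(c(max(1L, min(k_range) - 1L), k_range)))
  with_seed(seed, {
    models <- lapply(ks, function(k) lpa(X, k, ...))
    names(models) <- paste0("K", ks)
    rows <- list()
    blrt_active <- blrt
    for (k in k_range) {
      m <- models[[paste0("K", k)]]
      ic <- fit_indices(m)
      lmr <- if (paste0("K", k - 1L) %in% names(models))
        adjusted_lrt(m, models[[paste0("K", k - 1L)]])$p.value else NA_real_
      bl <- NA_real_
      if (blrt_active && k >= 2) {
        bl <- blrt(X, k, n_boot = n_boot)$p.value
        if (blrt_stop_early && bl >= 0.05) blrt_active <- FALSE
      }
      rows[[length(rows) + 1L]] <-
        data.frame(K = k, loglik = m$loglik, n_params = m$n_params,
                   BIC = ic["BIC"], SSABIC = ic["SSABIC"], AIC = ic["AIC"],
                   entropy = m$entropy, lmr_p = lmr, blrt_p = bl,
                   row.names = NULL)
    }
    structure(list(report = do.call(rbind, rows), models = models,
                   k_range = k_range, call = match.call()),
              class = "lpa_scan")
  })
}

#' @export
print.lpa_scan <- function(x, digits = 3, ...) {
  cat("Latent profile model comparison\n")
  print(cbind(x$report[1], round(x$report[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' Select the number of latent classes
#'
#' Applies the screening protocol: (1) class counts with relative
#' entropy below `entropy_min` (default 0.80) are ruled out; (2) among
#' the survivors, a candidate `K` must have a significant K vs K - 1
#' likelihood ratio test (p < `alpha`), and the largest such `K` whose
#' successor's test is non-significant is preferred; (3) if no
#' survivor has a significant test, or criteria conflict, the smaller
#' `K` wins (parsimony). Every elimination is recorded in the audit
#' trail.
#'
#' @param scan An [lpa_scan()] object or its `report` data frame.
#' @param alpha Significance level for the LRT (default 0.05).
#' @param entropy_min Entropy screening threshold (default 0.80).
#' @param test Which LRT p-value column to use: `"auto"` (default)
#'   takes the bootstrap LRT - the authoritative test - whenever its
#'   column carries any values, otherwise the adjusted LRT; `"blrt"`
#'   and `"lmr"` force one of the two.
#' @return An object of class `"lpa_selection"`: list with the chosen
#'   `K` and the `audit` trail.
#' @export
select_model <- function(scan, alpha = 0.05, entropy_min = 0.80,
                         test = c("auto", "blrt", "lmr")) {
  test <- match.arg(test)
  report <- if (inherits(scan, "lpa_scan")) scan$report else as.data.frame(scan)
  if (test == "auto")
    test <- if ("blrt_p" %in% names(report) && any(!is.na(report$blrt_p)))
      "blrt" else "lmr"
  pcol <- paste0(test, "_p")
  if (!pcol %in% names(report))
    stop("report has no '", pcol, "' column", call. = FALSE)
  report <- report[order(report$K), ]
  audit <- character(0)

  surv <- report$entropy >= entropy_min | report$K == 1
  for (i in which(!surv))
    audit <- c(audit, sprintf("K=%d ruled out: entropy %.3f < %.2f",
                              report$K[i], report$entropy[i], entropy_min))
  if (!any(surv))
    stop("every candidate class count was ruled out by the entropy filter; ",
         "consider expanding k_range or revisiting the indicators",
         call. = FALSE)
  sr <- report[surv, ]

  p <- sr[[pcol]]
  sig <- !is.na(p) & p < alpha
  succ_p <- function(k) {
    i <- match(k + 1L, report$K)   # successor judged on the full report
    if (is.na(i)) NA_real_ else report[[pcol]][i]
  }
  cand <- sr$K[sig]
  if (!length(cand)) {
    K <- min(sr$K)
    audit <- c(audit, sprintf(
      "no surviving K has a significant %s test at alpha=%.2f; parsimony fallback to smallest K=%d",
      toupper(test), alpha, K))
  } else {
    good <- vapply(cand, function(k) {
      ps <- succ_p(k)
      is.na(ps) || ps >= alpha
    }, TRUE)
    if (any(good)) {
      K <- max(cand[good])
      audit <- c(audit, sprintf(
        "K=%d selected: %s p significant and successor's test non-significant",
        K, toupper(test)))
    } else {
      K <- min(cand)
      audit <- c(audit, sprintf(
        "all candidate successors significant; parsimony resolves to K=%d", K))
    }
  }
  structure(list(K = K, audit = audit, alpha = alpha,
                 entropy_min = entropy_min, test = test, report = report),
            class = "lpa_selection")
}

#' @export
print.lpa_selection <- function(x, ...) {
  cat(sprintf("Selected K = %d (test: %s, alpha = %.2f, entropy >= %.2f)\n",
              x$K, toupper(x$test), x$alpha, x$entropy_min))
  for (a in x$audit) cat("  -", a, "\n")
  invisible(x)
}

#' Assign respondents to risk tiers
#'
#' Modal posterior assignment (ties to the lower-index class), with
#' classes labelled by ascending profile severity: the least severe
#' class is `low-risk`, the most severe `high-risk`, and any classes
#' in between `at-risk`. The binary benchmark used downstream is
#' high-risk vs the rest (low- and at-risk coded 0).
#'
#' @param model A fitted [lpa()] model.
#' @param posterior Optional posterior matrix overriding the model's.
#' @return Data frame with columns `class` (integer), `tier` (factor
#'   `low-risk`/`at-risk`/`high-risk`) and `highrisk` (logical
#'   benchmark). The class-to-tier map is attached as attribute
#'   `"tiers"`.
#' @export
assign_risk <- function(model, posterior = NULL) {
  stopifnot(inherits(model, "lpa"))
  post <- if (is.null(posterior)) model$posterior else as.matrix(posterior)
  cls <- max.col(post, ties.method = "first")
  K <- model$K
  tiers <- if (K == 1) "low-risk"
           else c("low-risk", rep("at-risk", K - 2), "high-risk")
  ## fitted classes are already ordered by ascending profile mean
  tier <- factor(tiers[cls], levels = c("low-risk", "at-risk", "high-risk"))
  out <- data.frame(class = cls, tier = tier,
                    highrisk = tier == "high-risk")
  attr(out, "tiers") <- stats::setNames(tiers, paste0("class", seq_len(K)))
  out
}

#' Pairwise group contrasts for each criterion
#'
#' For every item, compares all pairs of groups with Welch two-sample
#' t tests, Bonferroni-adjusted within the item (family = number of
#' pairs). Also reports whether the group means increase strictly
#' along the severity ordering of the groups (ordered by their grand
#' mean across items). Pairs involving a group with fewer than 2
#' members are flagged not computable.
#'
#' @param x Cohort data frame or rating matrix.
#' @param groups Factor (or vector) of group memberships.
#' @param conf.level Unused placeholder for future interval output.
#' @return A list of class `"profile_contrasts"` with elements
#'   `contrasts` (data frame: item, pair, means, t, p, adjusted p,
#'   computable) and `ordering_holds` (named logical per item).
#' @export
profile_contrasts <- function(x, groups, conf.level = 0.95) {
  X <- lpa_matrix(x)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(X))
  lev <- levels(groups)[table(groups) > 0]
  if (length(lev) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  sev <- sort(vapply(lev, function(g)
    mean(X[groups == g, , drop = FALSE]), 0))
  sev_order <- names(sev)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- list()
  for (j in seq_len(ncol(X))) {
    item <- colnames(X)[j] %||% paste0("item", j)
    prow <- lapply(pairs, function(pr) {
      a <- X[groups == pr[1], j]; b <- X[groups == pr[2], j]
      ok <- length(a) >= 2 && length(b) >= 2 &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)
      if (ok) {
        tt <- stats::t.test(a, b)
        data.frame(item = item, group1 = pr[1], group2 = pr[2],
                   mean1 = mean(a), mean2 = mean(b),
                   t = unname(tt$statistic), p = tt$p.value,
                   computable = TRUE)
      } else {
        data.frame(item = item, group1 = pr[1], group2 = pr[2],
                   mean1 = if (length(a)) mean(a) else NA_real_,
                   mean2 = if (length(b)) mean(b) else NA_real_,
                   t = NA_real_, p = NA_real_, computable = FALSE)
      }
    })
    prow <- do.call(rbind, prow)
    prow$p_bonferroni <- pmin(1, prow$p * sum(prow$computable))
    rows[[j]] <- prow
  }
  contrasts <- do.call(rbind, rows)
  ordering <- vapply(seq_len(ncol(X)), function(j) {
    m <- vapply(sev_order, function(g) mean(X[groups == g, j]), 0)
    all(diff(m) > 0)
  }, TRUE)
  names(ordering) <- colnames(X) %||% paste0("item", seq_len(ncol(X)))
  structure(list(contrasts = contrasts, ordering_holds = ordering,
                 severity_order = sev_order),
            class = "profile_contrasts")
}

#' @export
print.profile_contrasts <- function(x, ...) {
  cat("Pairwise criterion contrasts (Welch t, Bonferroni within item)\n")
  cat("Severity order:", paste(x$severity_order, collapse = " < "), "\n")
  df <- x$contrasts
  df$p_bonferroni <- signif(df$p_bonferroni, 3)
  print(df[c("item", "group1", "group2", "mean1", "mean2", "p_bonferroni",
             "computable")], row.names = FALSE, digits = 3)
  cat("Monotone ordering holds:",
      paste(names(x$ordering_holds)[x$ordering_holds], collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
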