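test_that("one-class fit equals the closed-form Gaussian MLE", {
  set.seed(3)
  X <- matrix(rnorm(200 * 6, mean = 3, sd = 0.8), 200)
  f <- lpa(X, 1)
  expect_equal(as.vector(f$means), colMeans(X), tolerance = 1e-10)
  ml_var <- colMeans(sweep(X, 2, colMeans(X))^2)  # divide-by-n variance
  expect_equal(unname(f$variances), unname(ml_var), tolerance = 1e-10)
  direct <- sum(vapply(1:6, function(j)
    sum(dnorm(X[, j], mean(X[, j]), sqrt(ml_var[j]), log = TRUE)), 0))
  expect_equal(f$loglik, direct, tolerance = 1e-8)
  expect_equal(f$entropy, 1)
})

test_that("EM recovers a well-separated two-class mixture", {
  d <- two_cluster_data(n = 2000, seed = 11)
  f <- lpa(d$X, 2, n_starts = 10, seed = 2)
  expect_true(f$converged)
  expect_true(all(abs(f$means[1, ] - 1.5) < 0.05))
  expect_true(all(abs(f$means[2, ] - 4.5) < 0.05))
  expect_true(all(abs(f$weights - 0.5) < 0.02))
  # modal classes agree with truth up to label order
  cls <- predict(f)
  expect_gt(mean(cls == d$z), 0.999)
})

test_that("reported log-likelihood matches the direct-summation oracle", {
  d <- two_cluster_data(n = 300, seed = 21)
  for (vs in c("equal", "varying")) {
    f <- lpa(d$X, 2, variance = vs, n_starts = 5, seed = 5)
    expect_equal(f$loglik,
                 oracle_loglik(d$X, f$weights, f$means, f$variances),
                 tolerance = 1e-8)
  }
})

test_that("log-likelihood trace is monotone non-decreasing in every run", {
  for (seed in 1:5) {
    co <- generate_cohort(random_spec(seed, n = 400))
    f <- lpa(co, 3, n_starts = 8, seed = seed)
    expect_true(all(diff(f$ll_trace) > -1e-8))
  }
})

test_that("posterior rows and weights are proper probabilities", {
  co <- generate_cohort(uk_like_spec(n = 500, seed = 31))
  f <- lpa(co, 3, n_starts = 10, seed = 3)
  expect_true(all(abs(rowSums(f$posterior) - 1) < 1e-10))
  expect_equal(sum(f$weights), 1, tolerance = 1e-10)
  expect_true(all(f$posterior >= 0 & f$posterior <= 1))
})

test_that("entropy and likelihood are invariant to class relabelling", {
  co <- generate_cohort(uk_like_spec(n = 500, seed = 37))
  f <- lpa(co, 3, n_starts = 10, seed = 3)
  perm <- c(3, 1, 2)
  expect_equal(lpa_entropy(f$posterior[, perm]), lpa_entropy(f$posterior))
  s2 <- matrix(f$variances, 3, 6, byrow = TRUE)
  expect_equal(oracle_loglik(as.matrix(co[paste0("bsmas", 1:6)]),
                             f$weights[perm], f$means[perm, ], s2[perm, ]),
               f$loglik, tolerance = 1e-8)
})

test_that("duplicating every row doubles the likelihood and fixes the MLE", {
  d <- two_cluster_data(n = 300, seed = 41)
  f <- lpa(d$X, 2, n_starts = 5, seed = 7)
  X2 <- rbind(d$X, d$X)
  s2 <- matrix(f$variances, 2, 6, byrow = TRUE)
  expect_equal(oracle_loglik(X2, f$weights, f$means, s2), 2 * f$loglik,
               tolerance = 1e-6)
  # the fitted parameters are an EM fixed point on the doubled data
  refit <- smaclass:::cpp_em(X2, f$weights, f$means, s2, TRUE, 50, 1e-10,
                             1e-3)
  expect_equal(as.vector(refit$means), as.vector(f$means), tolerance = 1e-4)
  expect_equal(as.vector(refit$weights), f$weights, tolerance = 1e-4)
})

test_that("maximised likelihood agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  d <- two_cluster_data(n = 800, seed = 51)
  f <- lpa(d$X, 2, n_starts = 10, seed = 5)
  m <- mclust::Mclust(d$X, G = 2, modelNames = "EEI", verbose = FALSE)
  expect_equal(f$loglik, m$loglik, tolerance = 1e-6)
})

test_that("identifiability floor and degenerate inputs are rejected", {
  X <- matrix(rnorm(60), 10, 6)
  expect_error(lpa(X, 2), "too small")
  expect_error(lpa(matrix(c(1, NA), 4, 6), 1), "finite")
})

test_that("information criteria match their closed forms", {
  fake <- structure(list(loglik = -100, n_params = 5, n_obs = 100),
                    class = "lpa")
  ic <- fit_indices(fake)
  expect_equal(unname(ic["AIC"]), 210)
  expect_equal(unname(ic["BIC"]), 200 + 5 * log(100), tolerance = 1e-9)
  expect_equal(unname(ic["BIC"]), 223.026, tolerance = 1e-4)
  expect_equal(unname(ic["SSABIC"]), 200 + 5 * log(102 / 24),
               tolerance = 1e-9)
  expect_equal(unname(ic["SSABIC"]), 207.235, tolerance = 1e-4)
  # AIC/BIC generics agree through logLik
  f <- lpa(two_cluster_data(n = 200, seed = 1)$X, 2, n_starts = 5, seed = 1)
  expect_equal(unname(stats::AIC(f)), unname(fit_indices(f)["AIC"]))
  expect_equal(unname(stats::BIC(f)), unname(fit_indices(f)["BIC"]))
})

test_that("entropy has its limiting and hand-computed values", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(lpa_entropy(onehot), 1)
  expect_equal(lpa_entropy(matrix(1 / 4, 5, 4)), 0)
  mixed <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(lpa_entropy(mixed), 0.2655, tolerance = 1e-4)
  expect_error(lpa_entropy(rbind(c(0.5, 0.2))), "sum to 1")
})

test_that("the adjusted LRT behaves across null and separated data", {
  d <- two_cluster_data(n = 500, seed = 61)
  f2 <- lpa(d$X, 2, n_starts = 5, seed = 6)
  f1 <- lpa(d$X, 1)
  sep <- adjusted_lrt(f2, f1)
  expect_lt(sep$p.value, 0.05)
  expect_match(sep$method, "pproximate")
  # identical log-likelihoods: zero statistic, p = 1
  f2b <- f2; f2b$loglik <- f1$loglik
  same <- adjusted_lrt(f2b, f1)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  # mismatched data are refused
  other <- lpa(two_cluster_data(n = 500, seed = 62)$X, 1)
  expect_error(adjusted_lrt(f2, other), "different data")
  # null single-Gaussian data: non-significant in the large majority
  rej <- 0L
  for (s in 1:10) {
    set.seed(s + 100)
    X0 <- matrix(rnorm(500 * 6), 500)
    g2 <- lpa(X0, 2, n_starts = 5, burn_iter = 10, n_final = 2)
    g1 <- lpa(X0, 1)
    if (adjusted_lrt(g2, g1)$p.value < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 2L)
})

test_that("model selection applies the entropy filter and LRT ladder", {
  report <- data.frame(K = 2:5,
                       entropy = c(0.94, 0.90, 0.90, 0.93),
                       lmr_p = c(0.004, 0.001, 0.32, 0.08))
  sel <- select_model(report)
  expect_equal(sel$K, 3)   # significant at 3, successor non-significant

  forced <- data.frame(K = 2:4, entropy = c(0.85, 0.5, 0.6),
                       lmr_p = c(0.5, 0.001, 0.001))
  expect_equal(select_model(forced)$K, 2)  # only survivor of the filter

  nonsig <- data.frame(K = 2:4, entropy = c(0.9, 0.9, 0.9),
                       lmr_p = c(0.3, 0.4, 0.5))
  sel3 <- select_model(nonsig)
  expect_equal(sel3$K, 2)  # parsimony fallback to smallest
  expect_true(any(grepl("parsimony", sel3$audit)))

  empty <- data.frame(K = 2:3, entropy = c(0.5, 0.6), lmr_p = c(0.01, 0.01))
  expect_error(select_model(empty), "entropy filter")
})

test_that("risk tiers follow modal assignment with documented tie-breaks", {
  fake <- structure(list(K = 3,
                         posterior = rbind(c(0.7, 0.2, 0.1),
                                           c(0.5, 0.5, 0.0),
                                           c(0.1, 0.2, 0.7))),
                    class = "lpa")
  a <- assign_risk(fake)
  expect_equal(a$class, c(1L, 1L, 3L))  # tie resolves to lower index
  expect_equal(as.character(a$tier),
               c("low-risk", "low-risk", "high-risk"))
  expect_equal(a$highrisk, c(FALSE, FALSE, TRUE))
})

test_that("fitted UK-like classes map onto ordered risk tiers", {
  co <- generate_cohort(uk_like_spec(n = 1500, seed = 71))
  f <- lpa(co, 3, n_starts = 20, seed = 7)
  a <- assign_risk(f)
  # class profile means ascend with tier severity
  expect_true(all(diff(rowMeans(f$means)) > 0))
  expect_true(all(f$means[3, ] > 3.18))  # high-risk above the cutoff
  # recovered high-risk share close to the generating 11.9%
  expect_lt(abs(mean(a$highrisk) - 0.119), 0.03)
})

test_that("pairwise criterion contrasts detect planted separation", {
  set.seed(81)
  X <- rbind(matrix(rnorm(100 * 6, 1, 0.3), 100),
             matrix(rnorm(100 * 6, 3, 0.3), 100),
             matrix(rnorm(100 * 6, 5, 0.3), 100))
  g <- rep(c("low", "mid", "high"), each = 100)
  pc <- profile_contrasts(X, g)
  expect_true(all(pc$contrasts$p_bonferroni < 0.05))
  expect_true(all(pc$ordering_holds))
  expect_equal(pc$severity_order, c("low", "mid", "high"))
})

test_that("contrasts control false positives and degenerate groups", {
  # identical groups: adjusted significance rate stays near the nominal level
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(90 * 6), 90)
    pc <- profile_contrasts(X, rep(c("a", "b", "c"), each = 30))
    hits <- hits + sum(pc$contrasts$p_bonferroni < 0.05)
    total <- total + nrow(pc$contrasts)
  }
  expect_lt(hits / total, 0.05)
  # two groups: a single comparison per item, Bonferroni factor 1
  set.seed(9)
  X <- matrix(rnorm(40 * 6), 40)
  pc2 <- profile_contrasts(X, rep(c("a", "b"), each = 20))
  expect_equal(nrow(pc2$contrasts), 6)
  expect_equal(pc2$contrasts$p_bonferroni, pc2$contrasts$p)
  # a singleton group is flagged not computable
  pc3 <- profile_contrasts(X, c("solo", rep(c("a", "b"), length.out = 39)))
  expect_true(any(!pc3$contrasts$computable))
})
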