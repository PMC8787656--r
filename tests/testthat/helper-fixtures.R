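# Shared fixtures: all synthetic, built in code at test time.

# A single-profile spec whose ratings are forced to a constant by
# rounding and clipping.
ceiling_spec <- function(n = 50, seed = 1) {
  cohort_spec(n = n,
              profiles = list(class_profile("only", 1, rep(5, 6), 0.01,
                                            depression_mean = 10,
                                            depression_sd = 2,
                                            anxiety_mean = 30,
                                            anxiety_sd = 2)),
              sex_split = 0.5, age_splits = c(1, 1, 1) / 3, seed = seed)
}

# Random but valid cohort spec for property tests.
random_spec <- function(seed, n = 400) {
  set.seed(seed)
  K <- sample(2:4, 1)
  w <- runif(K) + 0.2
  w <- w / sum(w)
  profiles <- lapply(seq_len(K), function(k)
    class_profile(paste0("c", k), w[k],
                  item_means = runif(6, 1, 5),
                  item_sds = runif(6, 0.3, 1.2),
                  depression_mean = runif(1, 5, 40), depression_sd = 8,
                  anxiety_mean = runif(1, 25, 60), anxiety_sd = 8))
  cohort_spec(n = n, profiles = profiles, sex_split = runif(1, 0.3, 0.7),
              age_splits = c(0.4, 0.3, 0.3), seed = seed + 1000L)
}

# Two well-separated spherical clusters on the 6 indicators
# (continuous, no rounding), used for mixture-recovery checks.
two_cluster_data <- function(n = 2000, mean1 = 1.5, mean2 = 4.5,
                             sd = 0.4, w = 0.5, seed = 1) {
  set.seed(seed)
  z <- rbinom(n, 1, 1 - w) + 1
  X <- matrix(rnorm(n * 6, mean = c(mean1, mean2)[z], sd = sd), n, 6)
  list(X = X, z = z)
}

# Direct-summation mixture log-likelihood: the independent oracle
# against which the EM-reported value is checked. Deliberately naive.
oracle_loglik <- function(X, weights, means, sigma2) {
  if (is.null(dim(sigma2)))
    sigma2 <- matrix(sigma2, nrow(means), ncol(means), byrow = TRUE)
  total <- 0
  for (i in seq_len(nrow(X))) {
    dens <- 0
    for (k in seq_along(weights)) {
      comp <- weights[k]
      for (j in seq_len(ncol(X)))
        comp <- comp * dnorm(X[i, j], means[k, j], sqrt(sigma2[k, j]))
      dens <- dens + comp
    }
    total <- total + log(dens)
  }
  as.numeric(total)
}

# Exhaustive enumeration of all 2^6 criterion patterns.
all_criterion_patterns <- function() {
  as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 6)))
}
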