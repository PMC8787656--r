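test_that("probable-case screening uses inclusive cutoffs 16 and 40", {
  expect_equal(probable_case(c(0, 15, 16, 17), "depression"),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(probable_case(c(20, 39, 40, 41), "anxiety"),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_error(probable_case(61, "depression"), "out of range")
  expect_error(probable_case(19, "anxiety"), "out of range")
  # monotone in the score
  s <- 20:80
  expect_true(all(diff(probable_case(s, "anxiety")) >= 0))
})

test_that("risk ratios match hand calculations and degenerate contracts", {
  exp1 <- rep(c(TRUE, FALSE), each = 20)
  out1 <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 15))
  expect_equal(risk_ratio(exp1, out1)$rr, 2.0)
  # identical risks
  expect_equal(risk_ratio(rep(c(TRUE, FALSE), each = 20),
                          rep(c(TRUE, FALSE, TRUE, FALSE), each = 10))$rr,
               1.0)
  # zero reference risk: not computable
  out3 <- c(rep(TRUE, 5), rep(FALSE, 35))
  rr3 <- risk_ratio(exp1, out3)
  expect_true(is.na(rr3$rr)); expect_false(rr3$computable)
  # doubling every observation leaves the ratio unchanged
  rr1 <- risk_ratio(exp1, out1)
  rr2 <- risk_ratio(rep(exp1, 2), rep(out1, 2))
  expect_equal(rr1$rr, rr2$rr)
  expect_error(risk_ratio(c(TRUE, NA), c(TRUE, FALSE)), "missing")
})

test_that("item-level risk ratios single out a planted criterion", {
  set.seed(7)
  n <- 5000
  r <- matrix(sample(1:5, n * 6, replace = TRUE), n)
  # outcome driven only by the withdrawal criterion (item 5)
  p <- ifelse(r[, 5] >= 4, 0.6, 0.1)
  outcome <- runif(n) < p
  rrs <- item_level_rr(r, 4, outcome)
  vals <- vapply(rrs, `[[`, 0, "rr")
  expect_equal(names(which.max(vals)), "withdrawal")
  expect_gt(vals["withdrawal"], 3)
  # independent outcome: all six near 1
  out0 <- runif(n) < 0.3
  null_vals <- vapply(item_level_rr(r, 3, out0), `[[`, 0, "rr")
  expect_true(all(null_vals > 0.8 & null_vals < 1.25))
  # constant item: empty unexposed stratum is not computable
  r5 <- r; r5[, 2] <- 5L
  expect_true(is.na(item_level_rr(r5, 4, outcome)[["tolerance"]]$rr))
})

test_that("group comparison runs the one-tailed Welch test", {
  same <- group_comparison(c(1, 2, 3, 4, 1, 2, 3, 4),
                           rep(c(TRUE, FALSE), each = 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  set.seed(8)
  scores <- c(rnorm(100, 1), rnorm(400, 0))
  shifted <- group_comparison(scores, rep(c(TRUE, FALSE), c(100, 400)))
  expect_lt(shifted$p, 0.001)
  reversed <- group_comparison(-scores, rep(c(TRUE, FALSE), c(100, 400)))
  expect_gt(reversed$p, 0.5)
  tiny <- group_comparison(1:10, c(TRUE, rep(FALSE, 9)))
  expect_false(tiny$computable)
})

test_that("Welch and pooled t decisions agree on balanced equal variances", {
  agree <- 0L
  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(50, 0.5); b <- rnorm(50, 0)
    w <- stats::t.test(a, b, alternative = "greater")$p.value < 0.05
    p <- stats::t.test(a, b, alternative = "greater",
                       var.equal = TRUE)$p.value < 0.05
    agree <- agree + (w == p)
  }
  expect_gte(agree, 18L)
})

test_that("Cronbach's alpha hits its closed-form limits", {
  set.seed(9)
  base <- rnorm(200)
  dup <- cbind(base, base, base)
  expect_equal(cronbach_alpha(dup), 1, tolerance = 1e-12)
  indep <- matrix(rnorm(5000 * 6), 5000)
  expect_lt(abs(cronbach_alpha(indep)), 0.1)
  # two items with correlation 0.5: Spearman-Brown gives 2r/(1+r) = 2/3
  f <- rnorm(20000)
  x1 <- sqrt(0.5) * f + sqrt(0.5) * rnorm(20000)
  x2 <- sqrt(0.5) * f + sqrt(0.5) * rnorm(20000)
  expect_equal(cronbach_alpha(cbind(x1, x2)), 2 / 3, tolerance = 0.02)
  expect_true(is.na(cronbach_alpha(matrix(1, 5, 3))))
  expect_error(cronbach_alpha(matrix(1, 5, 1)), "at least 2")
})

test_that("demographic risk ratios use the stated reference strata", {
  sex <- factor(rep(c("male", "female"), c(40, 60)),
                levels = c("male", "female"))
  lab <- c(rep(TRUE, 20), rep(FALSE, 20),   # male risk 0.5
           rep(TRUE, 15), rep(FALSE, 45))   # female risk 0.25
  rr <- demographic_rr(lab, sex, "female")
  expect_equal(rr$male$rr, 2.0)
  # zero reference risk mirrors the N/A convention
  lab0 <- c(rep(TRUE, 10), rep(FALSE, 90))
  sex0 <- factor(rep(c("male", "female"), c(50, 50)),
                 levels = c("male", "female"))
  expect_true(is.na(demographic_rr(lab0[c(1:50, 51:100)], sex0,
                                   "female")$male$rr))
})
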