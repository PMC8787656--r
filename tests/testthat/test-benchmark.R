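test_that("cross-tabulation counts the 2x2 cells exactly", {
  ct <- cross_tabulate(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(ct[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  agree <- cross_tabulate(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(agree$FP + agree$FN, 0)
  neg <- cross_tabulate(rep(FALSE, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(neg$TP, 0); expect_equal(neg$FN, 3)
  expect_error(cross_tabulate(c(1, 0), c(1, 0, 1)), "length")
})

test_that("diagnostic indices reproduce hand-computed values", {
  di <- diagnostic_indices(list(TP = 10, FN = 2, FP = 3, TN = 85))
  expect_equal(unname(di["sensitivity"]), 10 / 12, tolerance = 1e-12)
  expect_equal(unname(di["specificity"]), 85 / 88, tolerance = 1e-12)
  expect_equal(unname(di["ppv"]), 10 / 13, tolerance = 1e-12)
  expect_equal(unname(di["npv"]), 85 / 87, tolerance = 1e-12)
  expect_equal(unname(di["overall_consistency"]), 0.95, tolerance = 1e-12)
  expect_equal(round(unname(di["sensitivity"]), 3), 0.833)
  expect_equal(round(unname(di["ppv"]), 3), 0.769)

  perfect <- diagnostic_indices(list(TP = 5, FN = 0, FP = 0, TN = 5))
  expect_true(all(unclass(perfect) == 1))

  degen <- diagnostic_indices(list(TP = 0, FN = 4, FP = 0, TN = 6))
  expect_true(is.na(degen["ppv"]))           # zero denominator
  expect_equal(unname(degen["sensitivity"]), 0)
  expect_false(attr(degen, "computable")["ppv"])
})

test_that("consistency is the prevalence-weighted mean of sens and spec", {
  set.seed(5)
  for (i in 1:20) {
    s <- runif(80) < 0.3; b <- runif(80) < 0.2
    ct <- cross_tabulate(s, b)
    di <- diagnostic_indices(ct)
    if (anyNA(di[c("sensitivity", "specificity")])) next
    wpos <- (ct$TP + ct$FN) / ct$n
    expect_equal(unname(di["overall_consistency"]),
                 unname(wpos * di["sensitivity"] +
                          (1 - wpos) * di["specificity"]),
                 tolerance = 1e-12)
    expect_equal(unname(di["sensitivity"]) * (ct$TP + ct$FN), ct$TP,
                 tolerance = 1e-12)
  }
})

test_that("swapping scheme and benchmark swaps sens<->PPV and spec<->NPV", {
  set.seed(6)
  s <- runif(200) < 0.25; b <- runif(200) < 0.15
  a <- diagnostic_indices(cross_tabulate(s, b))
  r <- diagnostic_indices(cross_tabulate(b, s))
  expect_equal(unname(a["sensitivity"]), unname(r["ppv"]))
  expect_equal(unname(a["ppv"]), unname(r["sensitivity"]))
  expect_equal(unname(a["specificity"]), unname(r["npv"]))
  expect_equal(unname(a["npv"]), unname(r["specificity"]))
})

test_that("relaxing a scheme never lowers sensitivity or raises specificity", {
  for (seed in 1:10) {
    co <- generate_cohort(random_spec(seed))
    bench <- apply_scheme(co, "strict polythetic")  # any fixed benchmark
    rep <- scheme_benchmark_report(co, benchmark = bench)
    rownames(rep) <- rep$scheme
    relaxations <- list(c("strict monothetic", "monothetic"),
                        c("strict polythetic", "polythetic"),
                        c("strict monothetic", "strict polythetic"),
                        c("monothetic", "polythetic"))
    for (rl in relaxations) {
      sens <- rep[rl, "sensitivity"]
      spec <- rep[rl, "specificity"]
      if (!anyNA(sens)) expect_gte(sens[2], sens[1])
      if (!anyNA(spec)) expect_lte(spec[2], spec[1])
    }
  }
})

test_that("the scheme report matches the benchmark row by row", {
  co <- generate_cohort(uk_like_spec(n = 400, seed = 21))
  bench <- apply_scheme(co, "polythetic")
  rep <- scheme_benchmark_report(co, benchmark = bench)
  expect_equal(nrow(rep), 4)
  # the scheme identical to the benchmark scores 100 everywhere
  row <- rep[rep$scheme == "polythetic", ]
  expect_true(all(row[c("sensitivity", "specificity", "ppv", "npv",
                        "overall_consistency")] == 1))
  expect_equal(row$TP + row$FP + row$FN + row$TN, nrow(co))
})
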