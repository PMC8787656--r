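---
title: "Benchmarking classification schemes for social media addiction against latent profiles"
author: "smaclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking classification schemes for social media addiction against latent profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smaclass)
```

## The problem

Social media addiction is commonly screened with a six-item symptom
scale (salience, tolerance, mood modification, loss of control,
withdrawal, conflict), each item rated 1 ("very rarely") to 5 ("very
often"). There is no diagnostic gold standard, and survey studies
classify cases with ad hoc criterion-counting rules that differ on two
axes:

* **item cutoff** — a criterion counts as "met" at the scale midpoint
  (rating ≥ 3) or only at a stricter rating ≥ 4;
* **counting rule** — *monothetic* rules require every criterion to be
  met, *polythetic* rules require more than half (≥ 4 of 6).

Crossing the axes gives the four schemes in `sma_schemes()`: strict
monothetic, strict polythetic, monothetic, polythetic. Because the
positive sets are nested (raising the cutoff or requiring all criteria
can only remove positives), prevalence is ordered across schemes on
*every* dataset — a property the tests exercise directly.

`smaclass` evaluates the four schemes against a data-driven benchmark:
a latent profile analysis (LPA) of the six ratings. Respondents are
assigned to latent classes ordered by symptom severity; the most
severe class is the *high-risk* group and the scheme-vs-benchmark
agreement is summarised by sensitivity, specificity, positive and
negative predictive value, and overall consistency. Scale- and
item-level risk ratios connect the classifications to probable
depression (CES-D total ≥ 16) and probable anxiety (STAI state total
≥ 40).

## The latent profile model

`lpa()` fits a `K`-component Gaussian mixture with conditionally
independent indicators: observation $x_i \in \mathbb{R}^J$ has density

$$f(x_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J}
  \phi\!\left(x_{ij};\, \mu_{kj},\, \sigma_j^2\right),$$

with mixing weights $\pi_k$, class-specific item means $\mu_{kj}$ and
— by default — *class-invariant* diagonal variances $\sigma_j^2$ (one
variance per item, shared across classes), the convention of the
mixture software generally used for LPA. `variance = "varying"`
estimates $\sigma_{kj}^2$ instead. The parameter counts are
$(K-1) + JK + J$ and $(K-1) + 2JK$.

Estimation is multi-start EM, with the loop implemented in C++:

* **Starts.** `n_starts = 50` initialisations — one from k-means
  centroids, the rest from randomly drawn respondent rows with small
  jitter — are each run for `burn_iter = 20` iterations; the
  `n_final = 5` best by log-likelihood continue to convergence.
* **Convergence.** Aitken acceleration on the log-likelihood sequence
  (stop when the projected asymptote is within `tol = 1e-6`), with the
  plain absolute-change criterion as a fallback. Within every run the
  log-likelihood is non-decreasing; the winning run's trace is kept in
  the fitted object and asserted in the tests.
* **Variance floor.** Estimated variances are bounded below by
  `var_floor = 1e-3` (on the 1–5 scale) to rule out degenerate density
  spikes; fits that touch the floor are flagged `floored`.
* **Degeneracy.** A component whose effective size falls below one
  observation aborts that run; if every start collapses the fit errors
  out, carrying the best partial result.
* **Ordering.** Components are reported in ascending order of their
  profile mean, so class 1 is always the least severe; this makes
  labelling (`assign_risk()`) and reproducibility straightforward and
  all likelihood-based quantities are invariant to it.

`K = 1` is fitted in closed form (sample means, maximum-likelihood
variances).

## Model comparison and class enumeration

`lpa_scan()` tabulates, for each candidate `K` (default 2–5):

* `BIC = -2LL + p log n`, `AIC = -2LL + 2p`, and the
  sample-size-adjusted `SSABIC = -2LL + p log((n+2)/24)` — lower is
  better;
* relative entropy
  $E = 1 - \sum_{ik} (-p_{ik} \log p_{ik}) / (n \log K)$, which is 1
  for perfectly certain assignment and 0 for uniform posteriors (a
  one-class model is defined to have entropy 1, and is exempt from the
  entropy screen);
* an **adjusted likelihood ratio test** for `K` vs `K − 1`:
  the statistic $2\Delta LL$ shrunk by the ad hoc factor
  $c = 1 + 1/(d \log n)$ ($d$ = parameter difference) and referred to
  $\chi^2_d$. This reference distribution is *approximate* — the usual
  regularity conditions fail at the mixture boundary — and the test is
  labelled as such wherever it is printed;
* the **bootstrap likelihood ratio test** (`blrt()`), which is the
  authoritative test when the two disagree.

### The bootstrap null for rating-scale data

For continuous indicators `blrt()` is the classic parametric
bootstrap: replicates are simulated from the fitted `K − 1` Gaussian
mixture, both models are refitted, and
$p = (1 + \#\{LRT^{(b)} \ge LRT_{obs}\})/(B + 1)$.

Integer ratings need more care. A 1–5 scale discretises the latent
severity: within-class item distributions are heaped on five values
and clipped at the ends (a low-severity class piles up on rating 1).
A Gaussian mixture fitted to such data is *misspecified in shape*, and
extra components can always buy a large, genuinely significant
likelihood gain by absorbing that discreteness — even when no further
latent group exists. If the bootstrap null simulates smooth Gaussian
data, none of that gain appears in the null distribution and the test
enumerates classes without end. `blrt()` therefore detects integer
indicators automatically (override with `discretize`) and draws
replicates on the observed support: a class from the fitted `K − 1`
weights, then each item from the empirical item distribution within
that class's modal-assignment stratum. This is the conditional-
independence null with the observed within-class item shapes, so the
discreteness-induced part of the statistic is present under the null
and only evidence of an *additional class* rejects. On default
UK-like synthetic cohorts this stops the enumeration at the generating
three classes, while smooth two-cluster data still reject K = 1
overwhelmingly.

`lpa_scan(blrt = TRUE)` runs the bootstrap ladder sequentially and
stops testing after the first non-significant comparison, as class
enumeration in practice does.

### Selection rule

`select_model()` applies, in order: (1) rule out class counts with
entropy below 0.80; (2) among survivors, require a significant
(`p < .05`) `K` vs `K − 1` test and prefer the largest such `K` whose
successor's test is non-significant; (3) resolve ties and conflicts to
the smaller `K` (parsimony). Every elimination is recorded in an audit
trail, and the scan report is written even when the entropy screen
eliminates everything (the selection then errors with advice rather
than failing silently). The bootstrap test is used whenever its column
is available, otherwise the adjusted test.

## Concordance with the benchmark

`assign_risk()` assigns each respondent to the modal posterior class
(ties to the less severe class) and labels the least severe class
low-risk, the most severe high-risk, all middle classes at-risk. The
binary benchmark codes high-risk as 1 and low-plus-at-risk as 0.
`diagnostic_indices()` computes, from the 2×2 table of scheme vs
benchmark,

$$\text{sens} = \frac{TP}{TP+FN},\;
  \text{spec} = \frac{TN}{TN+FP},\;
  \text{PPV} = \frac{TP}{TP+FP},\;
  \text{NPV} = \frac{TN}{TN+FN},\;
  \text{cons} = \frac{TP+TN}{n},$$

returning a flagged "not computable" value for any zero denominator
(a convention used consistently throughout the package, e.g. for risk
ratios with an empty stratum or a zero reference risk, rather than
erroring).

Two structural facts are worth keeping in mind when reading such
tables. Because the schemes nest, relaxing a scheme (cutoff 4 → 3, or
all-criteria → more-than-half) can never decrease sensitivity and can
never increase specificity — this holds exactly, on any dataset and
any benchmark. PPV moves the other way: a stricter scheme's positives
are a subset of a looser scheme's positives concentrated at higher
severity, so under any benchmark that is monotone in severity the
strict schemes tend to the *highest* positive predictive value and the
polythetic scheme to the highest *sensitivity*. On default UK-like
cohorts the package reproduces precisely this signature (the
polythetic scheme wins on sensitivity, the strict monothetic scheme on
PPV, with specificity and NPV high for all four schemes).

## Comorbidity analyses

* `probable_case()` applies the standard screening cutoffs
  inclusively: CES-D ≥ 16, STAI state ≥ 40.
* `risk_ratio()` computes
  $(a/n_1)/(b/n_0)$ from a binary exposure and outcome;
  `item_level_rr()` dummy-codes each criterion at cutoff 3 or 4;
  `demographic_rr()` uses the reference strata female and ages 50–65.
  No confidence intervals are reported by default (`conf.int = TRUE`
  adds a log-normal interval).
* `group_comparison()` reports means and SDs (n−1 denominator) for the
  high-risk vs low-to-at-risk groups with a Welch independent-samples
  t test, one-tailed in the direction "high-risk mean greater". Welch
  was chosen over the pooled-variance test because group sizes and
  spreads are very unequal in this design; on balanced equal-variance
  data the two tests agree (checked in the suite).
* `cronbach_alpha()` is the usual
  $\frac{k}{k-1}\bigl(1 - \sum_j s_j^2 / s_{total}^2\bigr)$.

## The synthetic cohort generator

No respondent-level data are distributed with the package;
`generate_cohort()` draws cohorts whose structure matches what the
analysis stages assume, and `uk_like_spec()` / `us_like_spec()` encode
two published survey samples:

* three latent classes with weights 55/33.1/11.9 % (UK-like, n = 573)
  and 62.2/28.7/9.1 % (US-like, n = 474);
* class item means respecting the published profile bounds — UK:
  low-risk < 1.34 on all six items (1.2 used), at-risk ≈ 2.8–2.9 on
  salience/tolerance/mood modification and 1.8 on the rest, high-risk
  3.5–3.8 (> 3.18) on all six; US: low-risk 1.3 (< 1.45), at-risk
  2.85–3.0 on the first three items, high-risk > 3.34 on
  salience/tolerance/mood modification/withdrawal only, with loss of
  control and conflict below the midpoint;
* item ratings generated as normal deviates with the class mean,
  rounded to the nearest integer and clipped to 1–5. The latent SD is
  fixed at 0.7 for every class and item — a realistic within-class
  spread for 5-point symptom ratings that keeps the published
  mean-profile bounds attainable after rounding and yields entropy
  well above the 0.80 screening bar. Rounding preserves the ordering
  of class means, which the tests check empirically;
* depression and anxiety totals as class-conditional normals rounded
  and clipped to 0–60 / 20–80, with class parameters chosen so the
  mixture reproduces the published high-risk vs low-to-at-risk
  contrast (the published tables only report that two-group contrast;
  the low- and at-risk classes are given values around it whose
  weighted mean matches the printed low-to-at-risk mean);
* sex and age drawn from the published sample margins, independent of
  class by default; a per-class `age_weights` knob exists because
  age-graded prevalence is plausible, but the dependence is not
  parameterised in the source tables.

The generating class is stored in `true_class` for parameter-recovery
checks only; the pipeline drops it before analysis.

**What the generator does not emulate.** Items are conditionally
independent within class (no residual correlation, no
ordinal-threshold measurement model); comorbidity totals are
symmetric normals, whereas real CES-D/STAI distributions are strongly
right-skewed. The skewness matters for risk ratios: with normal
scores, the published group means put the reference-group case rate
near 0.5, so scale-level risk ratios on synthetic cohorts land around
1.4–1.6 rather than the 3–6 range reported from real data. Passing
tests therefore demonstrate that the *procedures* are correct and that
mixture-structure recovery works at survey scale — not that every
published magnitude is reproduced by this simplified data model.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; `run_pipeline()` derives
deterministic child seeds from one master seed (offsets of a fixed
prime, folded into the 32-bit range), so toggling one stage never
perturbs another and identical configurations produce byte-identical
report bundles (the manifest records versions, seeds and the full
configuration echo, and deliberately no timestamps).

The checks in the test suite run at sizes chosen to give stable
verdicts on one CPU in minutes: mixture recovery and scheme-pattern
checks on 20 cohorts of n = 2000; bootstrap-test calibration with 200
outer replicates of n = 500 and 99 bootstrap draws each (the exact
binomial band around the nominal 5 % level is asserted); exhaustive
enumeration over all 64 criterion patterns for the schemes.

## Known limitations

* The adjusted likelihood ratio test is an approximation; its χ²
  reference is conservative for mixtures and it is not a reimplementation
  of the proprietary weighted-null variant used by commercial software.
  Use the bootstrap test for decisions.
* Continuous Gaussian components on 5-point ratings are a working
  approximation, as is conventional for LPA on Likert indicators; an
  ordinal (graded-response) measurement model is out of scope.
* Risk ratios from the default synthetic cohorts are compressed toward
  1 relative to real-data reports (see above).
* Covariates on class membership, multilevel extensions and
  factor-mixture hybrids are not implemented.
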