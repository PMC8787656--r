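# smaclass

Benchmarking diagnostic classification schemes for social media
addiction against latent profiles.

## What problem this solves

Social media addiction is screened with a six-item symptom scale
(salience, tolerance, mood modification, loss of control, withdrawal,
conflict; each rated 1–5), but studies classify "cases" with four
different criterion-counting schemes, crossing an item cutoff (scale
midpoint 3, or strict 4) with a counting rule (**monothetic**: all 6
criteria met; **polythetic**: more than half, i.e. ≥ 4 of 6). Reported
prevalences differ several-fold depending on the scheme. With no
diagnostic gold standard, a data-driven benchmark is needed to judge
them.

`smaclass` implements the complete workflow for researchers in
psychiatric epidemiology and psychometrics:

* the four schemes and their prevalence tables (`sma_schemes()`,
  `apply_scheme()`, `prevalence()`);
* a latent profile analysis benchmark — a K-class Gaussian mixture
  with conditionally independent indicators,
  `f(x) = Σ_k π_k Π_j φ(x_j; μ_kj, σ_j²)`, fitted by multi-start EM
  (`lpa()`), compared across K by BIC, sample-size-adjusted BIC, AIC,
  relative entropy, an approximate adjusted likelihood-ratio test and
  the bootstrap likelihood-ratio test (`lpa_scan()`, `blrt()`), with a
  documented selection rule (`select_model()`) and severity-ordered
  risk tiers (`assign_risk()`);
* concordance of each scheme with the latent high-risk group —
  sensitivity, specificity, PPV, NPV, overall consistency
  (`scheme_benchmark_report()`);
* comorbidity analyses: probable depression (CES-D ≥ 16) and anxiety
  (STAI ≥ 40) screening, risk ratios at scheme, demographic and
  single-criterion level, one-tailed group contrasts, Cronbach's α;
* a synthetic-cohort generator (`generate_cohort()`, `uk_like_spec()`,
  `us_like_spec()`) emulating two published survey samples, so the
  whole pipeline is testable without access to raw survey data;
* a one-call orchestrator (`run_pipeline()`) producing a reproducible
  CSV/JSON report bundle from a master seed.

## Worked example

```r
library(smaclass)

co <- generate_cohort(uk_like_spec())      # n = 573, three latent classes
scan <- lpa_scan(co, k_range = 2:5, blrt = TRUE, seed = 1)
scan
#> Latent profile model comparison
#>  K    loglik n_params      BIC   SSABIC      AIC entropy lmr_p blrt_p
#>  2 -4105.704       19 8332.075 8271.758 8249.408   0.921     0   0.01
#>  3 -3737.530       26 7640.182 7557.644 7527.059   0.964     0   0.01
#>  4 -3720.497       33 7650.574 7545.813 7506.995   0.874     0   0.55
#>  5 -3662.391       40 7578.818 7451.835 7404.783   0.967     0     NA

(sel <- select_model(scan))
#> Selected K = 3 (test: BLRT, alpha = 0.05, entropy >= 0.80)
#>   - K=3 selected: BLRT p significant and successor's test non-significant

bench <- assign_risk(scan$models[[paste0("K", sel$K)]])
scheme_benchmark_report(co, benchmark = bench$highrisk)
#> Concordance with latent benchmark (%)
#>             scheme sensitivity specificity ppv npv overall_consistency
#>  strict monothetic           2         100 100  90                  90
#>  strict polythetic          48         100 100  95                  95
#>         monothetic          79         100 100  98                  98
#>         polythetic         100          95  69 100                  96
```

The bootstrap test stops the class enumeration at the generating
three-class solution (the 4-vs-3 comparison is non-significant,
p = .55), entropy 0.96 indicates precise assignment, and the
concordance table shows the structural trade-off between the schemes:
the liberal polythetic scheme captures the entire latent high-risk
group (sensitivity 100 %) at the cost of positive predictive value,
while the strict schemes are almost perfectly predictive but miss most
high-risk respondents. Continuing with prevalence and comorbidity:

```r
prevalence(apply_scheme(co, "polythetic"))
#>   stratum   n positive proportion  percent
#> 1   total 573       81  0.1413613 14.13613

dep <- probable_case(co$cesd_total, "depression")
risk_ratio(apply_scheme(co, "polythetic"), dep)
#> Risk ratio: 1.51  (exposed 62/81 vs unexposed 249/492)

cronbach_alpha(co[paste0("bsmas", 1:6)])
#> [1] 0.863
```

So 14.1 % of this synthetic UK-like cohort is polythetic-positive, a
positive classification carries a 1.5-fold risk of probable
depression, and the six items are internally consistent (α = .86).
The full report bundle — model comparison, prevalence by sex and age
with risk ratios, concordance, group descriptives and scale/item-level
risk ratios, plus a manifest that reproduces the run bit for bit — is
one call:

```r
bundle <- run_pipeline(run_config(spec = uk_like_spec(), seed = 1),
                       outdir = "reports")
```

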