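# agreemeta

When every randomized trial in a meta-analysis reports a continuous outcome
in the same unit, the analyst may pool either the **mean difference** (MD,
in outcome units) or the **standardized mean difference** (SMD, in
within-group SD units — here always Hedges' adjusted *g*). The choice is
consequential: if trial populations differ in outcome variability, a stable
standardized effect implies an unstable absolute effect and vice versa.
agreemeta is for meta-analysts and methodologists who want to quantify that
trade-off: it measures, over a whole corpus of meta-analyses, which metric
is less heterogeneous, more generalizable, and more powerful.

## What it computes

Per trial (treatment arm *t*, control arm *c*):

* MD: θ̂ = x̄ₜ − x̄꜀, with variance sₜ²/nₜ + s꜀²/n꜀
* Hedges' g: g = J(m) · (x̄ₜ − x̄꜀)/sₚ, with pooled SD sₚ, m = nₜ+n꜀−2,
  small-sample correction J(m) = 1 − 3/(4m−1), and variance
  (nₜ+n꜀)/(nₜn꜀) + g²/(2(nₜ+n꜀))

Per meta-analysis, inverse-variance pooling under the fixed-effect model
(weights 1/vᵢ) and the DerSimonian–Laird random-effects model (weights
1/(vᵢ+τ̂²)), with Cochran's Q, τ̂², I² = max(0, (Q−df)/Q)·100, Z-score and
95% CI.

Across a corpus, the package's centerpiece is the **leave-one-out
percentage agreement**: for each trial, the remaining trials are pooled as
a self-contained meta-analysis and the trial agrees when its point estimate
lands inside the pooled 95% CI; a review's agreement is the fraction of its
trials that agree. MD and SMD are then compared pairwise by exact sign
tests (on I², on agreement, and on |Z| within the I² < 30% stratum) and by
McNemar tests on significant/non-significant cross-classifications, within
nested heterogeneity strata (all, I² of both metrics < 60%, < 30%).

A calibrated generator (`simulate_corpus()`) produces synthetic corpora of
two-arm trial summaries — median 5 studies per review (IQR 3–8), median
total participants ≈ 490, median |SMD| ≈ 0.29 — with a switch for whether
the true effect is constant on the SMD or the MD scale, which is what makes
one metric or the other the generalizable one.

## Worked example

```r
library(agreemeta)

corpus <- simulate_corpus(sim_config(n_reviews = 300), seed = 123)
calibration_summary(corpus)
#> # A tibble: 1 × 6
#>   n_reviews median_k  k_q1  k_q3 median_total_n median_abs_smd
#>       <int>    <dbl> <dbl> <dbl>          <dbl>          <dbl>
#> 1       300        5     4     7            531          0.326

report <- build_report(corpus)
report
#> MD vs SMD comparison report: 300 reviews; models: fixed, random
#>
#> Percentage agreement (median of per-review %, sign test MD vs SMD):
#>   all        fixed   n= 300  MD  33.3%  SMD  40.0%  p=1.155e-06
#>   all        random  n= 300  MD  57.1%  SMD  55.6%  p=0.6255
#>   i2_lt_60   fixed   n= 163  MD  50.0%  SMD  50.0%  p=0.003833
#>   i2_lt_60   random  n= 163  MD  60.0%  SMD  57.1%  p=1
#>   i2_lt_30   fixed   n=  93  MD  60.0%  SMD  66.7%  p=0.01045
#>   i2_lt_30   random  n=  93  MD  60.0%  SMD  66.7%  p=0.09191
#>
#> I-squared (all reviews): median MD 53.7%, SMD 43.5%, sign test p=3.76e-17
#>
#> Significance cross-tabs (McNemar exact, alpha 0.05):
#>   all        fixed   both=198 md_only=8 smd_only=9 neither=85 p=1
#>   all        random  both=166 md_only=4 smd_only=5 neither=125 p=1
#>   ...
```

Reading this: the corpus was generated with the true effect constant on the
SMD scale and trial-level SDs dispersed, so the SMD should be the better
behaved metric — and it is: the paired I² comparison favors SMD decisively
(median 43.5% vs 53.7%, sign test p ≈ 4·10⁻¹⁷), agreement favors SMD in the
fixed model and in the most homogeneous stratum, and significance calls
barely differ between metrics (McNemar p ≈ 1). The sparser random-model
agreement contrast at 300 reviews shows medians are a noisy summary; the
sign-test tallies in `tidy(report)` carry the paired information.

`tidy(report)` returns every paired comparison as a tibble,
`glance(report)` the one-row headline summary, `autoplot(report)` an
agreement bar chart, and `run_analysis()` writes JSON/TSV artifacts. A thin
CLI for shell use lives at `inst/scripts/md-smd-compare.R`
(`simulate` / `analyze` subcommands).

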