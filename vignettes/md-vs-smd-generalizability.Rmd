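---
title: "Comparing the generalizability of MD and SMD in meta-analysis of continuous outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the generalizability of MD and SMD in meta-analysis of continuous outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agreemeta)
```

## The question

When every trial in a meta-analysis measures a continuous outcome in the
same unit, the analyst can pool either the mean difference (MD, in outcome
units) or the standardized mean difference (SMD, in within-group SD units).
The two choices are not equivalent: if trial populations differ in their
outcome variability, an intervention with a stable *standardized* effect has
an unstable *absolute* effect, and vice versa. agreemeta implements a
head-to-head comparison of the two metrics across a corpus of meta-analyses
using three outcome families:

1. **Heterogeneity** — the I² index of each meta-analysis, computed once per
   metric.
2. **Generalizability** — a leave-one-out percentage agreement: for each
   trial, pool the *remaining* trials and ask whether the held-out trial's
   point estimate falls inside the 95% CI of that pooled estimate. The
   fraction of agreeing trials is the review's percentage agreement.
3. **Statistical power** — the absolute pooled Z-score, compared between
   metrics only among meta-analyses homogeneous enough (I² of both metrics
   below 30%) for the comparison to be meaningful.

MD and SMD are compared pairwise within each review, so the corpus-level
tests are an exact sign test (ties excluded, doubled binomial tail) on the
paired differences and a McNemar test on the discordant cells of the
significant/non-significant cross-classification.

## Models and formulas

Per trial, `effect_sizes()` computes

* MD: \(\hat\theta = \bar x_t - \bar x_c\), \(v = s_t^2/n_t + s_c^2/n_c\);
* SMD as Hedges' adjusted \(g\): \(d = (\bar x_t - \bar x_c)/s_p\) with the
  pooled SD \(s_p\), multiplied by the small-sample correction
  \(J(m) = 1 - 3/(4m-1)\), \(m = n_t + n_c - 2\). The closed-form \(J\) is
  used rather than the exact gamma ratio; the two differ by \(O(m^{-2})\)
  (about \(10^{-4}\) at \(m = 20\)), far below every tolerance in play. The
  default variance is the large-sample Hedges–Olkin form
  \((n_t+n_c)/(n_t n_c) + g^2/(2(n_t+n_c))\); `smd_variance = "revman"`
  swaps the second denominator for \(2(n_t+n_c-3.94)\), the convention of
  Cochrane's review software. Both are offered because published analyses
  rarely say which their software used; the default is the textbook form.

`pool_effects()` pools by inverse variance. The fixed-effect weights are
\(1/v_i\); the random-effects weights are \(1/(v_i + \hat\tau^2)\) with the
DerSimonian–Laird moment estimator
\(\hat\tau^2 = \max\{0, (Q - df)/C\}\),
\(C = \sum w_i - \sum w_i^2 / \sum w_i\). Cochran's \(Q\), its df and
\(I^2 = \max\{0, (Q - df)/Q\} \cdot 100\) are always computed from the
fixed-effect weights: heterogeneity is a property of the data, not of the
pooling model, so one I² per metric describes the review under both models.
Confidence intervals use the exact normal quantile (1.959964...), not 1.96,
so independent implementations can match to full precision. Knapp–Hartung
adjustments, REML/Paule–Mandel estimators and prediction intervals are
deliberately out of scope.

## The leave-one-out agreement statistic

`loo_agreement()` re-pools the remaining \(k-1\) trials as a self-contained
meta-analysis for every holdout — in particular \(\tau^2\) is re-estimated
on each subset rather than frozen from the full review, because each
leave-one-out pool is the meta-analysis a reviewer would have had without
that trial. The held-out trial contributes its *point estimate* only (not
its CI), and a point exactly on a CI endpoint counts as agreement — a
measure-zero choice made for definiteness. Reviews need \(k \ge 3\) trials
so every leave-one-out pool still has two.

Corpus-wide, two summaries are reported: the median of the per-review
percentage agreements and the pooled proportion of agreeing trials. They
answer slightly different questions ("the typical review's agreement"
versus "the typical trial's chance of agreeing") and differ when review
sizes vary, so `corpus_agreement()` computes both and asserts neither as
canonical. The paired sign tests operate on per-review percentages, which
is the pairing the sign test needs.

Two subtleties of the statistic are worth knowing. First, under the fixed
model an extreme precise outlier drags every leave-one-out pool toward
itself, so *nothing* agrees — including the concordant trials; under the
random model the contaminated pools inflate \(\hat\tau^2\) and widen their
CIs, so typically only the outlier disagrees. Second, random-effects CIs
are at least as wide as fixed-effect CIs on the same subset, so
random-model agreement is, in practice, at least the fixed-model agreement.

## The synthetic corpus generator

No public corpus of trial summaries at this scale is redistributable, so
`simulate_corpus()` generates one with the reported shape of a large
Cochrane-style collection. Per review: the number of trials is
\(k = 3 + \mathrm{NegBin}(\text{size}=0.9, \mu=3.2)\), giving quartiles
3/5/8; a review-level per-arm base size is lognormal(3.82, 0.95), jittered
per trial by a log-normal factor (SD 0.2), giving total-participant
quartiles of roughly 240/500/1050; the true review effect is
\(\delta \sim N(0, 0.43)\), so the median absolute effect is about 0.29 SD
units. These three calibration targets — median 5 studies (IQR 3–8), a
median near 490 total participants, and median |SMD| near 0.29 — are the
published descriptives of the corpus being emulated; everything else about
the generative structure (negative-binomial counts, lognormal sizes, normal
effects, equal arms) is this package's modelling choice, stated here
because the source reports only those quantiles. Default between-trial
heterogeneity is \(\tau = 0.2\) on the effect scale, which puts median I²
in the mid-40s (%), matching the heterogeneity level typical of such
corpora.

The key design axis is `effect_scale`. Trial-level population SDs are
dispersed as \(\sigma_i = \sigma_0 \exp(\eta \zeta_i)\) with
\(\eta =\) `sd_dispersion` (default 0.3). With `effect_scale = "smd_fixed"`
the true effect is constant on the SMD scale, so the MD
(\(\theta_i \sigma_i\)) inherits the SD dispersion and becomes the
heterogeneous metric; `"md_fixed"` reverses the roles. This is precisely
the mechanism under which a standardized metric should generalize better,
and flipping the switch must flip the direction of every corpus-level sign
test — the package's strongest end-to-end check of its own machinery. In
the separation scenarios \(\tau = 0\), because "the effect is fixed on a
scale" means constant on that scale; the \(\tau > 0\) default instead
emulates realistic corpora where both metrics carry residual
heterogeneity. One empirical asymmetry is expected and real: MD sampling
variances are proportional to the noisy, dispersed \(\sigma_i^2\), which
destabilizes MD weights and CIs in *both* worlds, so the `"md_fixed"`
reversal is directionally clear but weaker than the `"smd_fixed"` signal.

Observed summaries are exact normal-theory draws — means from
\(N(\mu, \sigma^2/n)\), SDs from \(\sigma\sqrt{\chi^2_{n-1}/(n-1)}\) — so
the downstream formulas see the inputs they assume. What the generator does
*not* emulate: publication bias, small-study effects, non-normal outcomes,
unequal arms, and correlation between effect size and trial size. Passing
tests therefore validate the machinery and the direction of the MD/SMD
contrast under SD dispersion; they do not certify the corpus-level
percentages observed in any real review collection.

Each review gets its own RNG substream, with substream seeds drawn once
from the master seed, so a corpus is a pure function of (configuration,
seed) and enlarging `n_reviews` never perturbs existing reviews.

## Numerical and procedural choices

* Trials with non-positive SDs or arms under two participants are invalid
  (the SMD is undefined at \(s_p=0\)); strict validation rejects them,
  lenient validation drops and counts them, then drops reviews left with
  fewer than three trials.
* \(\hat\tau^2\) and I² are truncated at zero; \(I^2 = 0\) when
  \(Q \le df\) (and when \(Q = 0\)). Note the truncation gives I² a
  positive bias of order \(\sqrt{2/df}\) under perfect homogeneity — the
  homogeneous-limit test uses 200 trials per review for exactly this
  reason.
* Significance is strict: \(p < \alpha\), so \(|z|\) exactly at the
  critical value is non-significant. `alpha = 0.0042` reproduces a
  Bonferroni correction of 0.05 over 12 comparisons.
* I² strata use strict inequality on *both* metrics (a review with
  \(I^2_{MD} = 30\) is excluded from the <30% stratum), and are nested.
* The sign test excludes ties and doubles the smaller exact binomial tail,
  capping at 1; all-ties yields \(p = 1\) with a warning. The McNemar
  default is the exact binomial on discordant pairs, because the discordant
  counts in this design are typically small; the continuity-corrected
  \(\chi^2\) is available as `mcnemar_method = "cc_chi2"`.
* Reports serialize at full double precision (JSON) alongside 1-decimal
  human tables (TSV), and identical configuration + seed reproduces both
  byte-for-byte.

## Validation strategy and problem sizes

The test suite checks closed-form arithmetic to \(10^{-10}\); verifies
leave-one-out agreement flag-by-flag against a brute-force re-pooling
oracle on 1,000 random groups for all metric × model combinations; matches
the exact sign test and McNemar p-values against a full binomial pmf
enumeration up to \(n = 25\); confirms the reduction identities
(\(\tau^2 = 0\) collapses random onto fixed; perfect homogeneity gives
\(I^2 = 0\) and 100% agreement; rescaling the outcome unit leaves the SMD
side invariant and scales the MD side equivariantly); recovers a known
\(\tau^2\) within 10% on average at 50 trials per review over 500
replicates; and reproduces the directional contrast — lower I² and higher
agreement for SMD — on a 300-review corpus with \(\eta = 0.3\), with the
direction flipping under `"md_fixed"`. Cross-checks against the metafor
package (exact-J effect sizes, FE/DL pooling) guard against shared
mistakes; metafor is never on the computation path. These problem sizes
(300–1068 reviews, 500 replicates) keep every run in the minutes range on
one core while leaving Monte Carlo error well inside the asserted margins.

## A worked run

```{r example, eval = FALSE}
corpus <- simulate_corpus(sim_config(n_reviews = 300), seed = 123)
calibration_summary(corpus)
report <- build_report(corpus)
report
glance(report)
autoplot(report)
```

## Known limitations

The agreement statistic inherits the weaknesses of any coverage-style
criterion: it depends on the CI width convention (normal quantiles, no
small-sample t adjustment) and treats the held-out trial's estimate as if
measured without error. The generator's equal-arm, normal-summary world is
favorable to both metrics; real corpora contain imputed SDs, skewed
outcomes and change scores, none of which are modelled. And the MD/SMD
contrast examined here concerns generalizability of the pooled estimate,
not clinical interpretability of the units — a separate debate on which
this package is silent.
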