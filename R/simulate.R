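#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the shape of a large collection of Cochrane-style
#' meta-analyses of continuous outcomes. Defaults are calibrated so a
#' simulated corpus reproduces the reported corpus descriptives: a median of
#' 5 studies per meta-analysis (IQR 3-8, minimum 3), a median of roughly 490
#' total participants per meta-analysis (IQR roughly 240-1050), and a median
#' absolute pooled SMD of about 0.29.
#'
#' The data-generating model: each review draws a number of trials
#' k = 3 + NegBin(`k_size`, `k_mu`), a review-level base per-arm size
#' L ~ Lognormal(`n_meanlog`, `n_sdlog`) jittered per trial on the log scale
#' by `n_jitter`, and a true review effect delta ~ Normal(0, `delta_sd`).
#' Trial-level true effects are theta_i = delta + `tau` * e_i (e standard
#' normal), and trial-level population SDs are
#' sigma_i = `sigma_base` * exp(`sd_dispersion` * z_i). With
#' `effect_scale = "smd_fixed"` the true effect theta_i is on the SMD scale
#' (true MD = theta_i * sigma_i), so dispersed SDs make the MD heterogeneous
#' while the SMD stays homogeneous; `"md_fixed"` puts theta_i on the MD
#' scale and reverses the roles. Observed arm means are normal with variance
#' sigma_i^2 / n and observed arm SDs follow the exact scaled chi-square
#' sampling distribution, so downstream normal-theory formulas see the
#' inputs they assume.
#'
#' @param n_reviews Number of meta-analyses to generate.
#' @param k_min Minimum trials per review (>= 3; the inclusion rule).
#' @param k_size,k_mu Negative-binomial parameters of the studies-per-review
#'   count above `k_min`; `k_mu = 0` makes the count degenerate at `k_min`.
#' @param n_meanlog,n_sdlog Lognormal parameters of the review-level base
#'   per-arm sample size.
#' @param n_jitter Log-scale SD of the per-trial sample-size jitter.
#' @param delta_sd SD of the true review-level effect (median |delta| is
#'   0.6745 * delta_sd).
#' @param tau Between-trial heterogeneity SD on the effect scale.
#' @param sigma_base Control-arm population SD in outcome units.
#' @param sd_dispersion Log-scale SD of the per-trial population SDs.
#' @param effect_scale `"smd_fixed"` (default) or `"md_fixed"`.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_reviews = 300,
                       k_min = 3, k_size = 0.9, k_mu = 3.2,
                       n_meanlog = 3.82, n_sdlog = 0.95, n_jitter = 0.2,
                       delta_sd = 0.43, tau = 0.2,
                       sigma_base = 1, sd_dispersion = 0.3,
                       effect_scale = c("smd_fixed", "md_fixed")) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(
    n_reviews >= 1, k_min >= 3, k_size > 0, k_mu >= 0, n_sdlog >= 0,
    n_jitter >= 0, delta_sd >= 0, tau >= 0, sigma_base > 0,
    sd_dispersion >= 0
  )
  structure(list(
    n_reviews = as.integer(n_reviews), k_min = as.integer(k_min),
    k_size = k_size, k_mu = k_mu,
    n_meanlog = n_meanlog, n_sdlog = n_sdlog, n_jitter = n_jitter,
    delta_sd = delta_sd, tau = tau, sigma_base = sigma_base,
    sd_dispersion = sd_dispersion, effect_scale = effect_scale
  ), class = "sim_config")
}

#' Simulate one two-arm trial summary
#'
#' Draws observed arm means from Normal(mu, sigma^2 / n) and observed arm
#' variances from sigma^2 * chisq(n - 1) / (n - 1). The control mean is 0;
#' the treatment mean is `theta * sigma` when the true effect is on the SMD
#' scale and `theta` when it is on the MD scale.
#'
#' @param theta True effect for this trial.
#' @param sigma True population SD (> 0), shared by both arms.
#' @param n_t,n_c Arm sizes (>= 2).
#' @param effect_scale `"smd_fixed"` or `"md_fixed"`.
#' @param review_id,study_id Labels for the output row.
#' @return A one-row corpus tibble. Uses the current RNG state; seed it
#'   (or use [simulate_corpus()], which manages per-review substreams).
#' @export
simulate_trial <- function(theta, sigma, n_t, n_c,
                           effect_scale = c("smd_fixed", "md_fixed"),
                           review_id = "r1", study_id = "s1") {
  effect_scale <- match.arg(effect_scale)
  stopifnot(sigma > 0, n_t >= 2, n_c >= 2)
  mu_t <- if (effect_scale == "smd_fixed") theta * sigma else theta
  tibble::tibble(
    review_id = review_id, study_id = study_id,
    n_t = as.integer(n_t),
    mean_t = stats::rnorm(1, mu_t, sigma / sqrt(n_t)),
    sd_t = sigma * sqrt(stats::rchisq(1, n_t - 1) / (n_t - 1)),
    n_c = as.integer(n_c),
    mean_c = stats::rnorm(1, 0, sigma / sqrt(n_c)),
    sd_c = sigma * sqrt(stats::rchisq(1, n_c - 1) / (n_c - 1))
  )
}

#' Simulate one meta-analysis (a review's trials)
#'
#' @param config A [sim_config()].
#' @param review_id Label for the review.
#' @return A corpus tibble with at least 3 trial rows. Uses the current RNG
#'   state.
#' @export
simulate_review <- function(config, review_id = "r1") {
  stopifnot(inherits(config, "sim_config"))
  k <- config$k_min +
    if (config$k_mu > 0) stats::rnbinom(1, size = config$k_size,
                                        mu = config$k_mu) else 0L
  base_n <- stats::rlnorm(1, config$n_meanlog, config$n_sdlog)
  delta <- stats::rnorm(1, 0, config$delta_sd)
  theta <- delta + config$tau * stats::rnorm(k)
  sigma <- config$sigma_base * exp(config$sd_dispersion * stats::rnorm(k))
  n <- pmax(2L, as.integer(round(base_n *
    exp(stats::rnorm(k, 0, config$n_jitter)))))
  mu_t <- if (config$effect_scale == "smd_fixed") theta * sigma else theta
  tibble::tibble(
    review_id = review_id,
    study_id = sprintf("s%02d", seq_len(k)),
    n_t = n,
    mean_t = stats::rnorm(k, mu_t, sigma / sqrt(n)),
    sd_t = sigma * sqrt(stats::rchisq(k, n - 1) / (n - 1)),
    n_c = n,
    mean_c = stats::rnorm(k, 0, sigma / sqrt(n)),
    sd_c = sigma * sqrt(stats::rchisq(k, n - 1) / (n - 1))
  )
}

#' Simulate a corpus of meta-analyses
#'
#' Each review is generated under its own RNG substream whose seed is drawn
#' once from the master seed, so the corpus is a pure function of
#' (config, seed) and extending `n_reviews` leaves earlier reviews
#' unchanged.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return A validated corpus tibble with a `"calibration"` attribute
#'   (see [calibration_summary()]).
#' @export
#' @examples
#' corpus <- simulate_corpus(sim_config(n_reviews = 20), seed = 1)
#' calibration_summary(corpus)
simulate_corpus <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  review_seeds <- withr::with_seed(
    as.integer(seed),
    sample.int(.Machine$integer.max, config$n_reviews)
  )
  corpus <- purrr::map_dfr(seq_len(config$n_reviews), function(i) {
    withr::with_seed(
      review_seeds[i],
      simulate_review(config, review_id = sprintf("r%04d", i))
    )
  })
  attr(corpus, "calibration") <- compute_calibration(corpus)
  corpus
}

compute_calibration <- function(corpus) {
  per_review <- corpus |>
    dplyr::group_by(.data$review_id) |>
    dplyr::summarise(k = dplyr::n(), total_n = sum(.data$n_t + .data$n_c),
                     .groups = "drop")
  smd <- pool_corpus(corpus, metrics = "SMD", models = "random")
  tibble::tibble(
    n_reviews = nrow(per_review),
    median_k = stats::median(per_review$k),
    k_q1 = stats::quantile(per_review$k, 0.25, names = FALSE),
    k_q3 = stats::quantile(per_review$k, 0.75, names = FALSE),
    median_total_n = stats::median(per_review$total_n),
    median_abs_smd = stats::median(abs(smd$estimate))
  )
}

#' Calibration summary of a corpus
#'
#' The descriptives against which the generator defaults were calibrated:
#' median and IQR of studies per review, median total participants per
#' review, and the median absolute random-effects pooled SMD.
#'
#' @param corpus A corpus tibble (if it came from [simulate_corpus()] the
#'   cached summary is returned; otherwise it is computed).
#' @return A one-row tibble.
#' @export
calibration_summary <- function(corpus) {
  s <- attr(corpus, "calibration")
  if (!is.null(s)) return(s)
  compute_calibration(corpus)
}
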