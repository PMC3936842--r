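#' DerSimonian-Laird between-trial variance
#'
#' Moment estimator tau^2 = max(0, (Q - df) / C) with
#' C = sum(w) - sum(w^2)/sum(w), where w are the fixed-effect
#' inverse-variance weights and Q is Cochran's heterogeneity statistic.
#' Truncated at zero; returns 0 with a warning when C = 0 (a single
#' effective study).
#'
#' @param estimate Per-trial effect estimates.
#' @param variance Per-trial sampling variances (all > 0).
#' @return Non-negative scalar tau^2.
#' @export
tau2_dl <- function(estimate, variance) {
  stopifnot(length(estimate) == length(variance), length(estimate) >= 2)
  if (any(variance <= 0)) stop("variances must be > 0", call. = FALSE)
  w <- 1 / variance
  mu <- sum(w * estimate) / sum(w)
  q <- sum(w * (estimate - mu)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  if (c_dl <= 0) {
    warning("single effective study; tau2 set to 0", call. = FALSE)
    return(0)
  }
  max(0, (q - (length(estimate) - 1)) / c_dl)
}

# Core inverse-variance pooling on bare vectors; shared by pool_effects()
# and the leave-one-out loop, where tibble overhead would dominate.
# Q, df and I2 always come from the fixed-effect weights: heterogeneity is
# a property of the data, not of the pooling model.
pool_core <- function(y, v, model, conf_level = 0.95) {
  k <- length(y)
  w <- 1 / v
  sw <- sum(w)
  mu_fe <- sum(w * y) / sw
  q <- sum(w * (y - mu_fe)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0

  if (model == "random") {
    c_dl <- sw - sum(w^2) / sw
    tau2 <- if (c_dl > 0) max(0, (q - df) / c_dl) else 0
    ws <- 1 / (v + tau2)
    estimate <- sum(ws * y) / sum(ws)
    se <- sqrt(1 / sum(ws))
  } else {
    tau2 <- 0
    estimate <- mu_fe
    se <- sqrt(1 / sw)
  }
  z <- estimate / se
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    model = model, k = k, estimate = estimate, se = se,
    ci_low = estimate - crit * se, ci_high = estimate + crit * se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    q = q, df = df, tau2 = tau2, i2 = i2
  )
}

#' Pool per-trial effect estimates
#'
#' Inverse-variance pooling of a set of effect estimates sharing one metric:
#' fixed-effect weights are 1/v_i; DerSimonian-Laird random-effects weights
#' are 1/(v_i + tau^2) with tau^2 from [tau2_dl()]. Cochran's Q, its degrees
#' of freedom and I^2 = max(0, (Q - df)/Q) * 100 are computed from the
#' fixed-effect weights under both models, so one heterogeneity summary
#' describes the meta-analysis regardless of model. The confidence interval
#' uses the exact standard-normal quantile (1.959964... for 95%).
#'
#' @param data A tibble from [effect_sizes()]: columns `estimate`,
#'   `variance`, and optionally `metric` and `review_id` (carried through).
#' @param model `"fixed"` or `"random"`.
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return A one-row tibble: `review_id`, `metric`, `model`, `k`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `z`, `p`, `q`, `df`, `tau2`,
#'   `i2` (percent).
#' @export
#' @examples
#' es <- tibble::tibble(estimate = c(0, 2), variance = c(1, 1))
#' pool_effects(es, model = "fixed")  # estimate 1, Q = 2, I2 = 50
#' pool_effects(es, model = "random") # tau2 = 1, se = 1
pool_effects <- function(data, model = c("fixed", "random"),
                         conf_level = 0.95) {
  model <- match.arg(model)
  if (nrow(data) < 2) {
    stop("pooling requires at least 2 effect estimates", call. = FALSE)
  }
  has_metric <- "metric" %in% names(data)
  has_review <- "review_id" %in% names(data)
  if (has_metric && length(unique(data$metric)) > 1) {
    stop("cannot pool estimates with mixed metrics", call. = FALSE)
  }
  if (any(!is.finite(data$estimate)) || any(data$variance <= 0)) {
    stop("estimates must be finite and variances > 0", call. = FALSE)
  }
  res <- pool_core(data$estimate, data$variance, model, conf_level)
  tibble::tibble(
    review_id = if (has_review) as.character(data$review_id[1]) else
      NA_character_,
    metric = if (has_metric) data$metric[1] else NA_character_,
    model = model,
    k = res$k, estimate = res$estimate, se = res$se,
    ci_low = res$ci_low, ci_high = res$ci_high,
    z = res$z, p = res$p, q = res$q, df = res$df,
    tau2 = res$tau2, i2 = res$i2
  )
}

#' Pool every review in a corpus under both metrics and models
#'
#' @param corpus A validated corpus tibble.
#' @param metrics Subset of `c("MD", "SMD")`.
#' @param models Subset of `c("fixed", "random")`.
#' @inheritParams effect_sizes
#' @inheritParams pool_effects
#' @return A tibble with one row per review x metric x model, the columns of
#'   [pool_effects()].
#' @export
pool_corpus <- function(corpus, metrics = c("MD", "SMD"),
                        models = c("fixed", "random"),
                        smd_variance = c("hedges_olkin", "revman"),
                        conf_level = 0.95) {
  smd_variance <- match.arg(smd_variance)
  groups <- split_reviews(corpus)
  grid <- tidyr::expand_grid(metric = metrics, model = models)
  purrr::map_dfr(groups, function(g) {
    purrr::pmap_dfr(grid, function(metric, model) {
      es <- effect_sizes(g, metric, smd_variance)
      pool_effects(es, model, conf_level)
    })
  })
}

#' Two-sided significance call on a pooled result
#'
#' `TRUE` iff the two-sided normal p-value is strictly below `alpha`
#' (a |z| of exactly 1.959964 at alpha 0.05 is not significant).
#'
#' @param result A pooled-result tibble (rows from [pool_effects()] or
#'   [pool_corpus()]).
#' @param alpha Significance level in (0, 1); 0.0042 reproduces a
#'   Bonferroni correction of 0.05 across 12 comparisons.
#' @return Logical vector, one element per row.
#' @export
significance <- function(result, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  result$p < alpha
}
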