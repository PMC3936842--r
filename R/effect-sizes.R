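#' Hedges' small-sample bias correction factor
#'
#' The multiplicative correction J(df) = 1 - 3 / (4 df - 1) applied to
#' Cohen's d to remove its upward small-sample bias, with df = n_t + n_c - 2.
#' This is the standard closed-form approximation to the exact
#' gamma-function ratio; the two differ negligibly for df >= 2.
#'
#' @param df Degrees of freedom, n_t + n_c - 2; must be >= 2.
#' @return J(df), strictly between 0 and 1, increasing to 1 as df grows.
#' @export
#' @examples
#' hedges_j(18) # 1 - 3/71
hedges_j <- function(df) {
  if (any(!is.finite(df)) || any(df < 2)) {
    stop("hedges_j() requires df >= 2", call. = FALSE)
  }
  1 - 3 / (4 * df - 1)
}

#' Per-trial effect sizes with sampling variances
#'
#' Computes, for every trial row, the point estimate and sampling variance of
#' either the mean difference (MD) or the standardized mean difference (SMD),
#' the latter as Hedges' adjusted g:
#' \deqn{MD = \bar{x}_t - \bar{x}_c, \quad
#'       Var(MD) = s_t^2/n_t + s_c^2/n_c}
#' \deqn{g = J(n_t+n_c-2)\,\frac{\bar{x}_t - \bar{x}_c}{s_p}, \quad
#'       s_p^2 = \frac{(n_t-1)s_t^2 + (n_c-1)s_c^2}{n_t+n_c-2}}
#' with the large-sample Hedges-Olkin variance
#' \eqn{(n_t+n_c)/(n_t n_c) + g^2 / (2(n_t+n_c))} by default. The
#' `"revman"` alternative replaces the second denominator with
#' \eqn{2(n_t+n_c-3.94)}, matching the convention used in Cochrane's review
#' software.
#'
#' @param data A corpus tibble (or any data frame with the arm-summary
#'   columns of [corpus_columns()]).
#' @param metric `"MD"` or `"SMD"`.
#' @param smd_variance Variance convention for Hedges' g:
#'   `"hedges_olkin"` (default) or `"revman"`.
#' @return A tibble with columns `review_id`, `study_id`, `metric`,
#'   `estimate`, `variance`.
#' @export
#' @examples
#' trial <- tibble::tibble(review_id = "r1", study_id = "s1",
#'   n_t = 10, mean_t = 11, sd_t = 1, n_c = 10, mean_c = 10, sd_c = 1)
#' effect_sizes(trial, "SMD") # g = 0.9577, var = 0.2229
effect_sizes <- function(data, metric = c("MD", "SMD"),
                         smd_variance = c("hedges_olkin", "revman")) {
  metric <- match.arg(metric)
  smd_variance <- match.arg(smd_variance)
  ok <- trial_is_valid(data)
  if (any(!ok)) {
    stop(sum(!ok), " invalid trial row(s) passed to effect_sizes()",
         call. = FALSE)
  }
  n_t <- data$n_t; n_c <- data$n_c
  if (metric == "MD") {
    estimate <- data$mean_t - data$mean_c
    variance <- data$sd_t^2 / n_t + data$sd_c^2 / n_c
  } else {
    df <- n_t + n_c - 2
    sp <- sqrt(((n_t - 1) * data$sd_t^2 + (n_c - 1) * data$sd_c^2) / df)
    if (any(sp <= 0)) stop("degenerate trial: pooled SD is zero", call. = FALSE)
    g <- hedges_j(df) * (data$mean_t - data$mean_c) / sp
    denom <- switch(smd_variance,
      hedges_olkin = 2 * (n_t + n_c),
      revman = 2 * (n_t + n_c - 3.94)
    )
    estimate <- g
    variance <- (n_t + n_c) / (n_t * n_c) + g^2 / denom
  }
  tibble::tibble(
    review_id = as.character(data$review_id),
    study_id = as.character(data$study_id),
    metric = metric,
    estimate = estimate,
    variance = variance
  )
}
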