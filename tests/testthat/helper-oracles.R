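# Independent brute-force oracles, hand-coded from the defining formulas and
# kept free of any call into the package's own pooling/agreement code paths.

oracle_effect <- function(n_t, mean_t, sd_t, n_c, mean_c, sd_c, metric) {
  if (metric == "MD") {
    est <- mean_t - mean_c
    v <- sd_t * sd_t / n_t + sd_c * sd_c / n_c
  } else {
    df <- n_t + n_c - 2
    sp2 <- ((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / df
    d <- (mean_t - mean_c) / sqrt(sp2)
    j <- 1 - 3 / (4 * df - 1)
    est <- j * d
    v <- (n_t + n_c) / (n_t * n_c) + est * est / (2 * (n_t + n_c))
  }
  c(est = est, var = v)
}

oracle_pool <- function(y, v, model) {
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_fe)^2)
  df <- length(y) - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  tau2 <- 0
  if (model == "random") {
    cc <- sum(w) - sum(w * w) / sum(w)
    tau2 <- if (cc > 0) max(0, (q - df) / cc) else 0
    w <- 1 / (v + tau2)
  }
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  crit <- qnorm(0.975)
  list(estimate = mu, se = se, z = mu / se,
       p = 2 * pnorm(-abs(mu / se)),
       ci_low = mu - crit * se, ci_high = mu + crit * se,
       q = q, df = df, tau2 = tau2, i2 = i2)
}

# Re-pools from the raw trial rows for every holdout.
oracle_loo_flags <- function(trials, metric, model) {
  k <- nrow(trials)
  es <- t(vapply(seq_len(k), function(i) {
    oracle_effect(trials$n_t[i], trials$mean_t[i], trials$sd_t[i],
                  trials$n_c[i], trials$mean_c[i], trials$sd_c[i], metric)
  }, c(est = 0, var = 0)))
  vapply(seq_len(k), function(i) {
    p <- oracle_pool(es[-i, "est"], es[-i, "var"], model)
    es[i, "est"] >= p$ci_low && es[i, "est"] <= p$ci_high
  }, logical(1))
}

# Small random trial groups for property tests (independent of the package's
# own generator).
random_group <- function(k = sample(3:8, 1), id = "r1") {
  tibble::tibble(
    review_id = id,
    study_id = sprintf("s%02d", seq_len(k)),
    n_t = sample(5:80, k, replace = TRUE),
    mean_t = rnorm(k, 0, 2),
    sd_t = runif(k, 0.3, 3),
    n_c = sample(5:80, k, replace = TRUE),
    mean_c = rnorm(k, 0, 2),
    sd_c = runif(k, 0.3, 3)
  )
}

random_corpus <- function(n_reviews, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_reviews), function(i) {
    random_group(id = sprintf("r%03d", i))
  }))
}
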