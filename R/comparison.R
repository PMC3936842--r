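#' Exact paired sign test
#'
#' Classical sign test on paired differences: ties are excluded, and the
#' two-sided p-value is the doubled exact binomial tail
#' p = min(1, 2 P(X <= min(n_pos, n_neg))) with X ~ Binomial(n_pos + n_neg,
#' 1/2). When every pair is tied the p-value is 1, with a warning.
#'
#' @param x Differences, or the first member of each pair if `y` is given.
#' @param y Optional second member of each pair; differences are `x - y`.
#' @return A one-row tibble: `n_pairs`, `n_pos`, `n_neg`, `n_ties`,
#'   `p_value`.
#' @export
#' @examples
#' sign_test(c(rep(1, 5), -1))$p_value # 2 * P(X <= 1 | 6, .5) = 0.21875
sign_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("sign test on empty input", call. = FALSE)
  n_pos <- sum(d > 0)
  n_neg <- sum(d < 0)
  m <- n_pos + n_neg
  if (m == 0) {
    warning("all pairs tied; sign test p = 1", call. = FALSE)
    p <- 1
  } else {
    p <- min(1, 2 * stats::pbinom(min(n_pos, n_neg), m, 0.5))
  }
  tibble::tibble(
    n_pairs = length(d), n_pos = n_pos, n_neg = n_neg,
    n_ties = length(d) - m, p_value = p
  )
}

#' McNemar test on discordant counts
#'
#' Paired test of marginal homogeneity from the two discordant cells of a
#' 2x2 significant/non-significant cross-classification. The exact method
#' is the two-sided binomial test on the discordant pairs (doubled tail,
#' capped at 1); `"cc_chi2"` is the continuity-corrected chi-square
#' \eqn{(|b - c| - 1)^2 / (b + c)} on 1 df. With no discordant pairs the
#' p-value is 1 under either method.
#'
#' @param md_only Count of reviews significant under MD only (b).
#' @param smd_only Count significant under SMD only (c).
#' @param method `"exact"` (default) or `"cc_chi2"`.
#' @return Scalar p-value.
#' @export
#' @examples
#' mcnemar_test(8, 11)                    # exact, ~0.648
#' mcnemar_test(8, 9, method = "cc_chi2") # statistic 0, p = 1
mcnemar_test <- function(md_only, smd_only,
                         method = c("exact", "cc_chi2")) {
  method <- match.arg(method)
  stopifnot(md_only >= 0, smd_only >= 0)
  m <- md_only + smd_only
  if (m == 0) return(1)
  if (method == "exact") {
    min(1, 2 * stats::pbinom(min(md_only, smd_only), m, 0.5))
  } else {
    stat <- (abs(md_only - smd_only) - 1)^2 / m
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Assign reviews to nested I-squared strata
#'
#' A review belongs to the stratum at threshold t iff its I^2 is strictly
#' below t for both metrics; strata are nested by construction. The
#' unrestricted stratum `"all"` always exists.
#'
#' @param i2_wide Tibble with columns `review_id`, `i2_MD`, `i2_SMD`.
#' @param thresholds Percent thresholds, strictly decreasing
#'   (default `c(60, 30)`).
#' @return A named list of review-id character vectors: `all`, then
#'   `i2_lt_60`, `i2_lt_30`, ... for each threshold.
#' @export
stratify_by_i2 <- function(i2_wide, thresholds = c(60, 30)) {
  if (length(thresholds) > 0 && any(diff(thresholds) >= 0)) {
    stop("thresholds must be strictly decreasing", call. = FALSE)
  }
  out <- list(all = i2_wide$review_id)
  for (t in thresholds) {
    keep <- i2_wide$i2_MD < t & i2_wide$i2_SMD < t
    out[[sprintf("i2_lt_%g", t)]] <- i2_wide$review_id[keep]
  }
  out
}

paired_row <- function(stratum, quantity, model, md, smd) {
  md_med <- stats::median(md)
  smd_med <- stats::median(smd)
  st <- sign_test(md, smd)
  tibble::tibble(
    stratum = stratum, quantity = quantity, model = model,
    n_pairs = st$n_pairs, n_pos = st$n_pos, n_neg = st$n_neg,
    n_ties = st$n_ties, median_md = md_med, median_smd = smd_med,
    p_value = st$p_value
  )
}

#' Corpus-level comparison report of MD versus SMD
#'
#' Runs the full comparison over a corpus: both metrics are pooled under the
#' requested models, leave-one-out percentage agreement is computed per
#' review, and reviews are stratified by I^2 heterogeneity. Within each
#' stratum the report holds paired sign tests of MD against SMD on (a) the
#' per-review I^2 values (model-free), (b) the per-review percentage
#' agreements per model, and (c) the per-review absolute pooled Z-scores per
#' model — the |Z| comparison is restricted by default to the most
#' homogeneous stratum, where comparing statistical power is meaningful —
#' plus a significant/non-significant cross-classification of the two
#' metrics per model with a McNemar p-value. In every paired row positive
#' signs mean MD > SMD.
#'
#' @param corpus A validated corpus tibble.
#' @inheritParams pool_corpus
#' @param i2_thresholds Strictly decreasing percent thresholds for the
#'   nested heterogeneity strata (default `c(60, 30)`).
#' @param alpha Two-sided significance level for the cross-tabs
#'   (default 0.05; 0.0042 gives the Bonferroni-corrected sensitivity
#'   analysis).
#' @param mcnemar_method Passed to [mcnemar_test()].
#' @param z_all_strata If `TRUE`, compute the |Z| sign test in every stratum
#'   rather than only the most homogeneous one.
#' @return An object of class `"md_smd_report"`: a list with tibbles
#'   `strata` (stratum sizes), `paired` (sign-test rows), `crosstabs`
#'   (McNemar rows), `pooled` (per review x metric x model pooling),
#'   `agreement` (per review x metric x model agreement), `i2` (per-review
#'   I^2 for both metrics), and the `config` used. Has [tidy()], [glance()],
#'   [autoplot()] and print methods.
#' @export
#' @examples
#' corpus <- simulate_corpus(sim_config(n_reviews = 30), seed = 9)
#' report <- build_report(corpus)
#' report
#' generics::tidy(report)
build_report <- function(corpus, models = c("fixed", "random"),
                         i2_thresholds = c(60, 30), alpha = 0.05,
                         smd_variance = c("hedges_olkin", "revman"),
                         mcnemar_method = c("exact", "cc_chi2"),
                         conf_level = 0.95, z_all_strata = FALSE) {
  smd_variance <- match.arg(smd_variance)
  mcnemar_method <- match.arg(mcnemar_method)
  models <- match.arg(models, c("fixed", "random"), several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1)
  corpus <- validate_corpus(corpus, strict = TRUE)

  pooled <- pool_corpus(corpus, c("MD", "SMD"), models, smd_variance,
                        conf_level)
  agreement <- corpus_agreement(corpus, c("MD", "SMD"), models, smd_variance,
                                conf_level)

  i2_wide <- pooled |>
    dplyr::filter(.data$model == models[1]) |>
    dplyr::select("review_id", "metric", "i2") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "i2",
                       names_prefix = "i2_")
  strata <- stratify_by_i2(i2_wide, i2_thresholds)
  z_strata <- if (z_all_strata || length(i2_thresholds) == 0) names(strata)
              else sprintf("i2_lt_%g", min(i2_thresholds))

  pooled_wide <- pooled |>
    dplyr::select("review_id", "metric", "model", "z", "p") |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("z", "p"))
  agree_wide <- agreement |>
    dplyr::select("review_id", "metric", "model", "pct_agreement") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "pct_agreement",
                       names_prefix = "pct_")

  paired <- list()
  crosstabs <- list()
  for (stratum in names(strata)) {
    ids <- strata[[stratum]]
    if (length(ids) == 0) {
      message("stratum ", stratum, " is empty; tests skipped")
      next
    }
    i2_s <- i2_wide[i2_wide$review_id %in% ids, ]
    paired[[length(paired) + 1]] <-
      paired_row(stratum, "i2", "model_free", i2_s$i2_MD, i2_s$i2_SMD)
    for (model in models) {
      ag <- agree_wide[agree_wide$review_id %in% ids &
                         agree_wide$model == model, ]
      paired[[length(paired) + 1]] <-
        paired_row(stratum, "pct_agreement", model, ag$pct_MD, ag$pct_SMD)
      pw <- pooled_wide[pooled_wide$review_id %in% ids &
                          pooled_wide$model == model, ]
      if (stratum %in% z_strata) {
        paired[[length(paired) + 1]] <-
          paired_row(stratum, "abs_z", model, abs(pw$z_MD), abs(pw$z_SMD))
      }
      sig_md <- pw$p_MD < alpha
      sig_smd <- pw$p_SMD < alpha
      b <- sum(sig_md & !sig_smd)
      cc <- sum(!sig_md & sig_smd)
      crosstabs[[length(crosstabs) + 1]] <- tibble::tibble(
        stratum = stratum, model = model,
        both_sig = sum(sig_md & sig_smd), md_only = b, smd_only = cc,
        neither = sum(!sig_md & !sig_smd),
        p_value = mcnemar_test(b, cc, mcnemar_method)
      )
    }
  }

  structure(list(
    strata = tibble::tibble(
      stratum = names(strata),
      n_reviews = unname(vapply(strata, length, integer(1)))
    ),
    paired = dplyr::bind_rows(paired),
    crosstabs = dplyr::bind_rows(crosstabs),
    pooled = pooled,
    agreement = agreement,
    agreement_summary = agreement_summary(agreement),
    i2 = i2_wide,
    config = list(
      models = models, i2_thresholds = i2_thresholds, alpha = alpha,
      smd_variance = smd_variance, mcnemar_method = mcnemar_method,
      conf_level = conf_level, z_all_strata = z_all_strata
    )
  ), class = "md_smd_report")
}

#' @export
print.md_smd_report <- function(x, ...) {
  cat("MD vs SMD comparison report:",
      x$strata$n_reviews[x$strata$stratum == "all"], "reviews;",
      "models:", paste(x$config$models, collapse = ", "), "\n\n")
  cat("Percentage agreement (median of per-review %, sign test MD vs SMD):\n")
  ag <- x$paired[x$paired$quantity == "pct_agreement", ]
  for (i in seq_len(nrow(ag))) {
    cat(sprintf("  %-10s %-7s n=%4d  MD %5.1f%%  SMD %5.1f%%  p=%.4g\n",
                ag$stratum[i], ag$model[i], ag$n_pairs[i],
                100 * ag$median_md[i], 100 * ag$median_smd[i],
                ag$p_value[i]))
  }
  i2r <- x$paired[x$paired$quantity == "i2" & x$paired$stratum == "all", ]
  if (nrow(i2r) == 1) {
    cat(sprintf(
      "\nI-squared (all reviews): median MD %.1f%%, SMD %.1f%%, sign test p=%.4g\n",
      i2r$median_md, i2r$median_smd, i2r$p_value))
  }
  cat("\nSignificance cross-tabs (McNemar ", x$config$mcnemar_method,
      ", alpha ", x$config$alpha, "):\n", sep = "")
  ct <- x$crosstabs
  for (i in seq_len(nrow(ct))) {
    cat(sprintf(
      "  %-10s %-7s both=%d md_only=%d smd_only=%d neither=%d p=%.4g\n",
      ct$stratum[i], ct$model[i], ct$both_sig[i], ct$md_only[i],
      ct$smd_only[i], ct$neither[i], ct$p_value[i]))
  }
  invisible(x)
}
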