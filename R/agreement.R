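#' Leave-one-out percentage agreement for one meta-analysis
#'
#' For each trial i in the review: compute its effect estimate under the
#' chosen metric, pool the remaining k-1 trials as a self-contained
#' meta-analysis under the chosen model (tau^2 re-estimated on the subset),
#' and flag agreement when the held-out point estimate lies inside the 95%
#' confidence interval of that pooled estimate, boundaries inclusive. The
#' percentage agreement is the fraction of trials flagged. Trials are
#' visited in row order.
#'
#' @param data One review's trials (a corpus tibble subset, k >= 3 rows).
#' @inheritParams pool_corpus
#' @param metric `"MD"` or `"SMD"`.
#' @param model `"fixed"` or `"random"`.
#' @return A one-row tibble: `review_id`, `metric`, `model`, `k`,
#'   `n_agree`, `pct_agreement` (= n_agree / k), and a list column `flags`
#'   of the k per-trial logicals in row order.
#' @export
#' @examples
#' corpus <- simulate_corpus(sim_config(n_reviews = 1), seed = 4)
#' loo_agreement(corpus, metric = "SMD", model = "random")
loo_agreement <- function(data, metric = c("MD", "SMD"),
                          model = c("fixed", "random"),
                          smd_variance = c("hedges_olkin", "revman"),
                          conf_level = 0.95) {
  metric <- match.arg(metric)
  model <- match.arg(model)
  smd_variance <- match.arg(smd_variance)
  k <- nrow(data)
  if (k < 3) {
    stop("leave-one-out agreement needs at least 3 trials", call. = FALSE)
  }
  if (length(unique(data$review_id)) > 1) {
    stop("loo_agreement() expects the trials of a single review",
         call. = FALSE)
  }
  es <- effect_sizes(data, metric, smd_variance)
  flags <- vapply(seq_len(k), function(i) {
    pooled <- pool_core(es$estimate[-i], es$variance[-i], model, conf_level)
    es$estimate[i] >= pooled$ci_low && es$estimate[i] <= pooled$ci_high
  }, logical(1))
  tibble::tibble(
    review_id = as.character(data$review_id[1]),
    metric = metric, model = model, k = k,
    n_agree = sum(flags), pct_agreement = sum(flags) / k,
    flags = list(flags)
  )
}

#' Leave-one-out agreement across a whole corpus
#'
#' Runs [loo_agreement()] for every review under each requested metric and
#' model. Two corpus-level summaries are attached for each metric x model
#' cell: the median of the per-review percentage agreements and the pooled
#' proportion of agreeing trials (sum of n_agree over sum of k). The two can
#' differ when reviews have unequal numbers of trials; both are reported.
#'
#' @param corpus A validated corpus tibble.
#' @inheritParams pool_corpus
#' @return A tibble of per-review agreement rows (without the flags column),
#'   with a `"summary"` attribute holding the tibble of per-cell medians and
#'   pooled proportions; retrieve it with [agreement_summary()].
#' @export
corpus_agreement <- function(corpus, metrics = c("MD", "SMD"),
                             models = c("fixed", "random"),
                             smd_variance = c("hedges_olkin", "revman"),
                             conf_level = 0.95) {
  smd_variance <- match.arg(smd_variance)
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)
  groups <- split_reviews(corpus)
  grid <- tidyr::expand_grid(metric = metrics, model = models)
  rows <- purrr::map_dfr(groups, function(g) {
    purrr::pmap_dfr(grid, function(metric, model) {
      loo_agreement(g, metric, model, smd_variance, conf_level)
    })
  })
  rows$flags <- NULL
  summary <- rows |>
    dplyr::group_by(.data$metric, .data$model) |>
    dplyr::summarise(
      n_reviews = dplyr::n(),
      median_pct = stats::median(.data$pct_agreement),
      pooled_pct = sum(.data$n_agree) / sum(.data$k),
      .groups = "drop"
    )
  attr(rows, "summary") <- summary
  rows
}

#' Corpus-level agreement summary
#'
#' @param agreement The tibble returned by [corpus_agreement()].
#' @return A tibble with one row per metric x model: `n_reviews`,
#'   `median_pct` (median of per-review percentage agreements) and
#'   `pooled_pct` (total agreeing trials over total trials).
#' @export
agreement_summary <- function(agreement) {
  s <- attr(agreement, "summary")
  if (is.null(s)) stop("no summary attribute; pass corpus_agreement() output",
                       call. = FALSE)
  s
}
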