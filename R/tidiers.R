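#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a comparison report
#'
#' One row per paired MD-vs-SMD sign test: stratum, compared quantity
#' (`i2`, `pct_agreement` or `abs_z`), model, sign tallies, the two medians
#' and the exact p-value.
#'
#' @param x An `"md_smd_report"` from [build_report()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy md_smd_report
#' @export
tidy.md_smd_report <- function(x, ...) {
  x$paired
}

#' One-row summary of a comparison report
#'
#' Corpus-level headline numbers: review count, median I^2 per metric, and
#' median percentage agreement per metric under each model (NA for a model
#' that was not run).
#'
#' @inheritParams tidy.md_smd_report
#' @return A one-row tibble.
#' @method glance md_smd_report
#' @export
glance.md_smd_report <- function(x, ...) {
  ag <- x$paired[x$paired$quantity == "pct_agreement" &
                   x$paired$stratum == "all", ]
  pick <- function(model, col) {
    v <- ag[[col]][ag$model == model]
    if (length(v) == 0) NA_real_ else unname(v)
  }
  i2 <- x$paired[x$paired$quantity == "i2" & x$paired$stratum == "all", ]
  tibble::tibble(
    n_reviews = x$strata$n_reviews[x$strata$stratum == "all"],
    median_i2_md = i2$median_md,
    median_i2_smd = i2$median_smd,
    p_sign_i2 = i2$p_value,
    agreement_md_random = pick("random", "median_md"),
    agreement_smd_random = pick("random", "median_smd"),
    agreement_md_fixed = pick("fixed", "median_md"),
    agreement_smd_fixed = pick("fixed", "median_smd")
  )
}

#' Plot percentage agreement by stratum, metric and model
#'
#' Bar chart of the median per-review percentage agreement for MD and SMD
#' in each heterogeneity stratum, faceted by pooling model.
#'
#' @param object An `"md_smd_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot md_smd_report
#' @export
autoplot.md_smd_report <- function(object, ...) {
  ag <- object$paired |>
    dplyr::filter(.data$quantity == "pct_agreement") |>
    tidyr::pivot_longer(c("median_md", "median_smd"),
                        names_to = "metric", values_to = "agreement") |>
    dplyr::mutate(
      metric = dplyr::if_else(.data$metric == "median_md", "MD", "SMD"),
      stratum = factor(.data$stratum, levels = object$strata$stratum)
    )
  ggplot2::ggplot(ag, ggplot2::aes(x = .data$stratum,
                                   y = 100 * .data$agreement,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(x = "I² stratum", y = "Median agreement (%)",
                  fill = "Metric") +
    ggplot2::theme_minimal()
}

#' Histogram of per-review I-squared values by metric
#'
#' @param report An `"md_smd_report"`.
#' @param binwidth Histogram bin width in I^2 percentage points.
#' @return A ggplot object.
#' @export
plot_i2_distribution <- function(report, binwidth = 10) {
  long <- tidyr::pivot_longer(report$i2, c("i2_MD", "i2_SMD"),
                              names_to = "metric", values_to = "i2") |>
    dplyr::mutate(metric = sub("i2_", "", .data$metric))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$i2)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = "I² (%)", y = "Reviews") +
    ggplot2::theme_minimal()
}
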