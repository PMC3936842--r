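#' Column schema of a trial-summary corpus
#'
#' A corpus is a plain tibble with one row per randomized trial, grouped into
#' meta-analyses by `review_id`. The eight columns are, in order:
#' `review_id`, `study_id` (unique within a review), the treatment arm's
#' size/mean/SD (`n_t`, `mean_t`, `sd_t`) and the control arm's
#' (`n_c`, `mean_c`, `sd_c`). Means and SDs are in the outcome's natural
#' units; SDs must be strictly positive and each arm must have at least two
#' participants so the sample SD is defined.
#'
#' @return Character vector of the eight column names, in file order.
#' @export
corpus_columns <- function() {
  c("review_id", "study_id", "n_t", "mean_t", "sd_t", "n_c", "mean_c", "sd_c")
}

trial_is_valid <- function(data) {
  ok_num <- function(x) is.finite(x)
  !is.na(data$review_id) & !is.na(data$study_id) &
    ok_num(data$n_t) & data$n_t >= 2 & data$n_t == round(data$n_t) &
    ok_num(data$n_c) & data$n_c >= 2 & data$n_c == round(data$n_c) &
    ok_num(data$mean_t) & ok_num(data$mean_c) &
    ok_num(data$sd_t) & data$sd_t > 0 &
    ok_num(data$sd_c) & data$sd_c > 0
}

#' Validate a trial-summary corpus
#'
#' Checks every row against the trial-level invariants (arm sizes at least 2,
#' strictly positive SDs, finite means) and every review against the
#' inclusion rule that a meta-analysis must contribute at least three trials.
#'
#' @param data A data frame with the columns of [corpus_columns()].
#' @param strict If `TRUE` (default) any invalid row or undersized review is
#'   an error. If `FALSE`, invalid rows are dropped with a warning, and
#'   reviews left with fewer than three valid trials are dropped with a
#'   warning.
#' @return A validated tibble (invisibly identical to the input when
#'   everything is valid).
#' @export
validate_corpus <- function(data, strict = TRUE) {
  missing_cols <- setdiff(corpus_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("corpus is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)[corpus_columns()]
  data$review_id <- as.character(data$review_id)
  data$study_id <- as.character(data$study_id)

  ok <- trial_is_valid(data)
  if (any(!ok)) {
    if (strict) {
      stop(sum(!ok), " invalid trial row(s): arm sizes must be integers >= 2, ",
           "SDs > 0, means finite", call. = FALSE)
    }
    warning("dropping ", sum(!ok), " invalid trial row(s)", call. = FALSE)
    data <- data[ok, ]
  }

  dup <- duplicated(data[c("review_id", "study_id")])
  if (any(dup)) {
    stop("duplicated study_id within review: ",
         paste(utils::head(unique(data$study_id[dup]), 5), collapse = ", "),
         call. = FALSE)
  }

  sizes <- table(data$review_id)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    if (strict) {
      stop(length(small), " review(s) with fewer than 3 trials (",
           paste(utils::head(small, 5), collapse = ", "),
           "); meta-analyses need at least three studies", call. = FALSE)
    }
    warning("dropping ", length(small),
            " review(s) with fewer than 3 valid trials", call. = FALSE)
    data <- data[!(data$review_id %in% small), ]
  }
  data
}

#' Read a trial-summary corpus from CSV
#'
#' Reads a UTF-8, header-required CSV in the fixed schema of
#' [corpus_columns()] and validates it. Row order within a review is
#' preserved; it is the deterministic iteration order for the leave-one-out
#' agreement procedure.
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_corpus
#' @return A validated corpus tibble.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_corpus(simulate_corpus(sim_config(n_reviews = 3), seed = 1), path)
#' read_corpus(path)
read_corpus <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(corpus_columns(), names(data))
  if (length(missing_cols) > 0) {
    stop("corpus is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_bad <- 0L
  for (col in setdiff(corpus_columns(), c("review_id", "study_id"))) {
    # base as.numeric is a correctly rounded strtod, so %.17g output from
    # write_corpus() round-trips bit-exactly
    parsed <- suppressWarnings(as.numeric(data[[col]]))
    n_bad <- n_bad + sum(is.na(parsed) & !is.na(data[[col]]))
    data[[col]] <- parsed
  }
  if (n_bad > 0) {
    if (strict) {
      stop("malformed numeric cells in ", path, " (", n_bad, " cell(s))",
           call. = FALSE)
    }
    warning(n_bad, " malformed cell(s) coerced to NA and dropped",
            call. = FALSE)
  }
  validate_corpus(data, strict = strict)
}

#' Write a trial-summary corpus to CSV
#'
#' Numeric fields are written at full double precision so that
#' `read_corpus(write_corpus(x))` round-trips exactly.
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  missing_cols <- setdiff(corpus_columns(), names(corpus))
  if (length(missing_cols) > 0) {
    stop("corpus is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(corpus)[corpus_columns()]
  # 17 significant digits guarantee exact double round-trip
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a corpus into per-review groups
#'
#' @param corpus A corpus tibble.
#' @return A named list of tibbles, one per `review_id`, in first-appearance
#'   order; row order within each review is preserved.
#' @keywords internal
split_reviews <- function(corpus) {
  split(tibble::as_tibble(corpus),
        factor(corpus$review_id, levels = unique(corpus$review_id)))
}
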