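test_that("sign test matches exact binomial tail sums", {
  st <- sign_test(c(rep(1, 5), -1))
  expect_equal(st$p_value, 2 * (7 / 64), tolerance = 1e-12)
  expect_equal(st$n_pos, 5); expect_equal(st$n_neg, 1)

  st2 <- sign_test(rep(2, 5))
  expect_equal(st2$p_value, 2 * (1 / 32), tolerance = 1e-12)

  expect_warning(st3 <- sign_test(rep(0, 4)), "tied")
  expect_equal(st3$p_value, 1)
  expect_equal(st3$n_ties, 4)

  expect_error(sign_test(numeric(0)), "empty")
})

test_that("sign test and exact McNemar match full pmf enumeration for n <= 25", {
  for (m in 1:25) {
    for (n_pos in 0:m) {
      n_neg <- m - n_pos
      pmf <- choose(m, 0:m) / 2^m
      expected <- min(1, 2 * sum(pmf[seq_len(min(n_pos, n_neg) + 1)]))
      d <- c(rep(1, n_pos), rep(-1, n_neg))
      expect_equal(sign_test(d)$p_value, expected, tolerance = 1e-12,
                   label = sprintf("pos=%d neg=%d", n_pos, n_neg))
      expect_equal(mcnemar_test(n_pos, n_neg), expected, tolerance = 1e-12)
    }
  }
})

test_that("sign test agrees with stats::binom.test", {
  set.seed(31)
  for (rep in 1:20) {
    m <- sample(1:40, 1)
    n_pos <- sample(0:m, 1)
    d <- c(rep(1, n_pos), rep(-1, m - n_pos), rep(0, sample(0:3, 1)))
    expect_equal(sign_test(d)$p_value,
                 stats::binom.test(n_pos, m)$p.value, tolerance = 1e-10)
  }
})

test_that("McNemar methods behave as documented on small discordant counts", {
  expect_equal(mcnemar_test(0, 0), 1)
  expect_equal(mcnemar_test(0, 0, "cc_chi2"), 1)
  expect_equal(mcnemar_test(8, 11), 2 * pbinom(8, 19, 0.5), tolerance = 1e-12)
  expect_equal(mcnemar_test(8, 9, "cc_chi2"), 1, tolerance = 1e-12)
  # symmetric in the two discordant cells
  expect_equal(mcnemar_test(3, 9), mcnemar_test(9, 3))
  expect_equal(mcnemar_test(3, 9, "cc_chi2"), mcnemar_test(9, 3, "cc_chi2"))
  # cc_chi2 matches stats::mcnemar.test with continuity correction
  tab <- matrix(c(10, 7, 2, 20), 2)
  expect_equal(mcnemar_test(7, 2, "cc_chi2"),
               stats::mcnemar.test(tab)$p.value, tolerance = 1e-10)
})

test_that("I2 strata use the strict both-metric rule and are nested", {
  i2 <- tibble::tibble(
    review_id = c("a", "b", "c", "d"),
    i2_MD = c(80, 29.9, 30, 10),
    i2_SMD = c(20, 29.9, 10, 59)
  )
  strata <- stratify_by_i2(i2, c(60, 30))
  expect_equal(strata$all, c("a", "b", "c", "d"))
  expect_equal(strata$i2_lt_60, c("b", "c", "d"))  # a fails on MD
  expect_equal(strata$i2_lt_30, c("b"))            # strict <30 on both
  expect_true(all(strata$i2_lt_30 %in% strata$i2_lt_60))
  expect_error(stratify_by_i2(i2, c(30, 60)), "decreasing")
})

test_that("report on identical homogeneous reviews is degenerate everywhere", {
  one <- tibble::tibble(
    review_id = "r", study_id = sprintf("s%d", 1:4),
    n_t = 40L, mean_t = 2, sd_t = 1, n_c = 40L, mean_c = 1, sd_c = 1
  )
  corpus <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(one, review_id = sprintf("r%d", i))
  }))
  report <- suppressWarnings(build_report(corpus))
  # I2 and agreement coincide across metrics in every review -> all ties
  degen <- report$paired[report$paired$quantity != "abs_z", ]
  expect_true(all(degen$p_value == 1))
  expect_true(all(degen$n_ties == degen$n_pairs))
  ag <- report$paired[report$paired$quantity == "pct_agreement", ]
  expect_true(all(ag$median_md == 1 & ag$median_smd == 1))
  expect_true(all(report$crosstabs$md_only == 0 &
                    report$crosstabs$smd_only == 0))
  expect_true(all(report$crosstabs$p_value == 1))
})

test_that("report structure respects the model subset and stratum nesting", {
  set.seed(33)
  corpus <- random_corpus(12)
  report <- build_report(corpus, models = "fixed")
  expect_false("random" %in% report$paired$model)
  expect_false("random" %in% report$crosstabs$model)
  n <- setNames(report$strata$n_reviews, report$strata$stratum)
  expect_true(n["all"] >= n["i2_lt_60"] && n["i2_lt_60"] >= n["i2_lt_30"])
  # |Z| rows restricted to the most homogeneous stratum by default
  z_rows <- report$paired[report$paired$quantity == "abs_z", ]
  expect_true(all(z_rows$stratum == "i2_lt_30"))
  full <- build_report(corpus, models = "fixed", z_all_strata = TRUE)
  expect_setequal(unique(full$paired$stratum[full$paired$quantity == "abs_z"]),
                  full$strata$stratum[full$strata$n_reviews > 0])
})

test_that("tidy, glance and plots expose the report", {
  set.seed(34)
  corpus <- random_corpus(8)
  report <- build_report(corpus)
  td <- tidy(report)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("stratum", "quantity", "model", "p_value") %in% names(td)))
  expect_true(all(td$n_pos + td$n_neg + td$n_ties == td$n_pairs))
  gl <- glance(report)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_reviews, 8)
  expect_s3_class(autoplot(report), "ggplot")
  expect_s3_class(plot_i2_distribution(report), "ggplot")
})
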