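es2 <- tibble::tibble(estimate = c(0, 2), variance = c(1, 1))

test_that("fixed-effect pooling matches hand-derived values", {
  p <- pool_effects(es2, "fixed")
  expect_equal(p$estimate, 1, tolerance = 1e-12)
  expect_equal(p$se, sqrt(0.5), tolerance = 1e-12)
  expect_equal(p$q, 2, tolerance = 1e-12)
  expect_equal(p$df, 1)
  expect_equal(p$i2, 50, tolerance = 1e-12)
  expect_equal(p$tau2, 0)

  # k identical effects: estimate y, se = sqrt(v/k), no heterogeneity
  same <- tibble::tibble(estimate = rep(1.3, 5), variance = rep(0.4, 5))
  ps <- pool_effects(same, "fixed")
  expect_equal(ps$estimate, 1.3, tolerance = 1e-12)
  expect_equal(ps$se, sqrt(0.4 / 5), tolerance = 1e-12)
  expect_equal(ps$q, 0, tolerance = 1e-12)
  expect_equal(ps$i2, 0)
})

test_that("DerSimonian-Laird tau2 matches hand arithmetic and is location-invariant", {
  expect_equal(tau2_dl(c(0, 2), c(1, 1)), 1, tolerance = 1e-12)
  expect_equal(tau2_dl(rep(0.7, 4), runif(4, 0.5, 1)), 0)
  set.seed(11)
  y <- rnorm(6); v <- runif(6, 0.2, 2)
  expect_equal(tau2_dl(y + 5, v), tau2_dl(y, v), tolerance = 1e-12)
})

test_that("random-effects pooling matches hand-derived values and reduces to fixed", {
  p <- pool_effects(es2, "random")
  expect_equal(p$tau2, 1, tolerance = 1e-12)
  expect_equal(p$estimate, 1, tolerance = 1e-12)
  expect_equal(p$se, 1, tolerance = 1e-12)
  expect_equal(p$ci_low, 1 - qnorm(0.975), tolerance = 1e-12)
  expect_equal(p$ci_high, 1 + qnorm(0.975), tolerance = 1e-12)
  # heterogeneity fields are the fixed-weight ones
  expect_equal(p$q, 2, tolerance = 1e-12)
  expect_equal(p$i2, 50, tolerance = 1e-12)

  # tau2 = 0 -> random equals fixed in every numeric field
  same <- tibble::tibble(estimate = rep(0.4, 4), variance = c(1, 2, 1, 3))
  num <- function(x) dplyr::select(x, -"model")
  expect_equal(num(pool_effects(same, "random")),
               num(pool_effects(same, "fixed")), ignore_attr = TRUE)
})

test_that("pooling is permutation-invariant and random se >= fixed se", {
  set.seed(12)
  for (rep in 1:25) {
    k <- sample(2:10, 1)
    es <- tibble::tibble(estimate = rnorm(k, 0, 1.5),
                         variance = runif(k, 0.05, 2))
    perm <- es[sample.int(k), ]
    for (model in c("fixed", "random")) {
      expect_equal(pool_effects(perm, model), pool_effects(es, model),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    expect_gte(pool_effects(es, "random")$se,
               pool_effects(es, "fixed")$se - 1e-12)
  }
})

test_that("pooled results match the brute-force oracle to 1e-10 relative error", {
  set.seed(13)
  fields <- c("estimate", "se", "z", "ci_low", "ci_high", "q", "tau2", "i2")
  for (rep in 1:200) {
    k <- sample(2:10, 1)
    y <- rnorm(k, 0, 2); v <- runif(k, 0.02, 3)
    es <- tibble::tibble(estimate = y, variance = v)
    for (model in c("fixed", "random")) {
      got <- pool_effects(es, model)
      want <- oracle_pool(y, v, model)
      for (f in fields) {
        expect_equal(got[[f]], want[[f]], tolerance = 1e-10, label = f)
      }
    }
  }
})

test_that("pooling agrees with metafor (FE and DL)", {
  skip_if_not_installed("metafor")
  set.seed(14)
  for (rep in 1:10) {
    k <- sample(3:12, 1)
    y <- rnorm(k); v <- runif(k, 0.05, 1)
    es <- tibble::tibble(estimate = y, variance = v)
    fe <- suppressWarnings(metafor::rma(yi = y, vi = v, method = "EE"))
    re <- suppressWarnings(metafor::rma(yi = y, vi = v, method = "DL"))
    pf <- pool_effects(es, "fixed")
    pr <- pool_effects(es, "random")
    expect_equal(pf$estimate, as.numeric(fe$beta), tolerance = 1e-8)
    expect_equal(pf$se, fe$se, tolerance = 1e-8)
    expect_equal(pf$q, fe$QE, tolerance = 1e-8)
    expect_equal(pr$estimate, as.numeric(re$beta), tolerance = 1e-8)
    expect_equal(pr$se, re$se, tolerance = 1e-8)
    expect_equal(pr$tau2, re$tau2, tolerance = 1e-8)
    expect_equal(pr$i2, re$I2, tolerance = 1e-6)
  }
})

test_that("MD pooling is scale-equivariant, SMD pooling scale-invariant", {
  set.seed(15)
  g <- random_group(6)
  c_scale <- 3.7
  g2 <- dplyr::mutate(g, dplyr::across(
    c("mean_t", "sd_t", "mean_c", "sd_c"), ~ .x * c_scale))
  for (model in c("fixed", "random")) {
    m1 <- pool_effects(effect_sizes(g, "MD"), model)
    m2 <- pool_effects(effect_sizes(g2, "MD"), model)
    expect_equal(m2$estimate, c_scale * m1$estimate, tolerance = 1e-10)
    expect_equal(m2$se, c_scale * m1$se, tolerance = 1e-10)
    expect_equal(m2$ci_low, c_scale * m1$ci_low, tolerance = 1e-10)
    for (f in c("z", "q", "i2", "p")) {
      expect_equal(m2[[f]], m1[[f]], tolerance = 1e-10, label = f)
    }
    s1 <- pool_effects(effect_sizes(g, "SMD"), model)
    s2 <- pool_effects(effect_sizes(g2, "SMD"), model)
    expect_equal(s2, s1, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("significance uses a strict two-sided normal threshold", {
  mk <- function(z) tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
  expect_false(significance(mk(0)))
  expect_false(significance(mk(qnorm(0.975))))  # p exactly alpha
  expect_true(significance(mk(2.0)))
  # Bonferroni-style alpha flips borderline calls
  borderline <- mk(2.5)  # p ~ 0.0124
  expect_true(significance(borderline, alpha = 0.05))
  expect_false(significance(borderline, alpha = 0.0042))
})

test_that("pooling rejects invalid input", {
  expect_error(pool_effects(es2[1, ], "fixed"), "at least 2")
  mixed <- tibble::tibble(estimate = c(0, 1), variance = c(1, 1),
                          metric = c("MD", "SMD"))
  expect_error(pool_effects(mixed), "mixed metrics")
  expect_error(tau2_dl(c(0, 1), c(1, 0)), "variances")
})
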