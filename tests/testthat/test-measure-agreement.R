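test_that("mean bias is the difference of arm means, antisymmetric and affine-equivariant", {
  withr::local_seed(2)
  ref <- rnorm(20, 400, 50)
  dev <- ref + rnorm(20, 10, 15)
  mb <- mean_bias(dev, ref, B = 100, seed = 1)
  expect_equal(mb$estimate, mean(dev) - mean(ref), tolerance = 1e-12)
  mb_rev <- mean_bias(ref, dev, B = 100, seed = 1)
  expect_equal(mb_rev$estimate, -mb$estimate, tolerance = 1e-12)
  # unit rescaling scales the bias with it
  mb_h <- mean_bias(dev / 60, ref / 60, B = 50, seed = 1)
  expect_equal(mb_h$estimate, mb$estimate / 60, tolerance = 1e-12)

  expect_equal(mean_bias(ref, ref, B = 50, seed = 1)$estimate, 0)
  expect_error(mean_bias(1, 1), "at least 2")
})

test_that("proportional-bias regression detects and quantifies a trend", {
  withr::local_seed(4)
  ref <- rnorm(41, 385, 60)
  # constant offset: slope 0, no proportional bias
  pb0 <- test_proportional_bias(ref + 12, ref)
  expect_equal(pb0$slope, 0, tolerance = 1e-9)
  expect_false(pb0$present)

  # exact multiplicative device: d = 0.5 ref exactly
  pb1 <- test_proportional_bias(1.5 * ref, ref)
  expect_equal(pb1$slope, 0.5, tolerance = 1e-9)
  expect_equal(pb1$intercept, 0, tolerance = 1e-6)
  expect_true(pb1$present)

  expect_error(test_proportional_bias(c(1, 2, 3), c(5, 5, 5)),
               "degenerate regressor")
})

test_that("injected proportional bias is recovered within its CI in most replicates", {
  hits <- 0
  n_rep <- 200
  withr::local_seed(88)
  for (r in seq_len(n_rep)) {
    ref <- rnorm(41, 385, 60)
    d <- 10 - 0.3 * ref + rnorm(41, 0, 20)
    pb <- test_proportional_bias(ref + d, ref)
    hits <- hits + (pb$slope_ci[1] <= -0.3 && pb$slope_ci[2] >= -0.3)
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("assumption tests flag injected structure and degenerate inputs", {
  withr::local_seed(6)
  ref <- rnorm(200, 385, 60)
  ok <- test_assumptions(ref + rnorm(200, 0, 20), ref)
  expect_true(ok$normality$pass)

  # residual spread growing with the reference level
  het <- test_assumptions(ref + rnorm(200, 0, 0.15 * ref), ref)
  expect_true(het$heteroscedastic$present)

  # constant differences: zero residuals, both tests not applicable
  degen <- test_assumptions(ref + 5, ref)
  expect_true(is.na(degen$normality$pass))
  expect_true(is.na(degen$heteroscedastic$present))
  expect_match(degen$normality$reason, "degenerate")
})

test_that("constant limits of agreement match the closed form and the oracle", {
  withr::local_seed(8)
  ref <- rnorm(10, 400, 40)
  dev <- ref + rnorm(10, 7, 12)
  ba <- bland_altman(dev, ref, B = 100, seed = 1, loa_form = "constant")
  oc <- oracle_loa_constant(dev, ref)
  expect_equal(ba$loa$lower$estimate, unname(oc["lower"]), tolerance = 1e-12)
  expect_equal(ba$loa$upper$estimate, unname(oc["upper"]), tolerance = 1e-12)
  expect_lte(ba$loa$lower$estimate, ba$bias$estimate)
  expect_gte(ba$loa$upper$estimate, ba$bias$estimate)

  # LOAs are equivariant under affine rescaling of the measure's units
  ba_h <- bland_altman(dev / 60, ref / 60, B = 50, seed = 1,
                       loa_form = "constant")
  expect_equal(ba_h$loa$lower$estimate, ba$loa$lower$estimate / 60,
               tolerance = 1e-9)

  # for large normal samples ~95% of differences fall inside constant LOAs
  ref2 <- rnorm(2000, 400, 40)
  dev2 <- ref2 + rnorm(2000, 5, 10)
  ba2 <- bland_altman(dev2, ref2, B = 20, seed = 1, loa_form = "constant")
  inside <- mean(dev2 - ref2 >= ba2$loa$lower$estimate &
                   dev2 - ref2 <= ba2$loa$upper$estimate)
  expect_equal(inside, 0.95, tolerance = 0.02)
})

test_that("heteroscedastic limits use the 2.46 x absolute-residual model", {
  # build pairs whose absolute-residual regression has known coefficients:
  # check the halfwidth function evaluates as 2.46 (c0 + c1 x)
  withr::local_seed(10)
  ref <- runif(400, 10, 150)
  dev <- ref + rnorm(400, 0, 0.5 + 0.1 * ref)
  ba <- bland_altman(dev, ref, B = 50, seed = 1, loa_form = "heteroscedastic")
  expect_equal(ba$loa$multiplier, qnorm(0.975) * sqrt(pi / 2), tolerance = 1e-12)
  c0 <- ba$loa$hw_coef[["intercept"]]
  c1 <- ba$loa$hw_coef[["slope"]]
  pr <- predict(ba, reference = c(20, 80, 140))
  expect_equal(pr$upper - pr$bias,
               ba$loa$multiplier * (c0 + c1 * c(20, 80, 140)),
               tolerance = 1e-12)
  expect_equal(pr$bias, rep(ba$bias$estimate, 3), tolerance = 1e-12)
  # halfwidth model coefficients echo the injected error structure
  expect_equal(c1 * sqrt(pi / 2), 0.1, tolerance = 0.15)

  # the fixture of the published WASO row: halfwidth 2.46 (1.32 + 0.18 x)
  ba$loa$hw_coef <- c(intercept = 1.32, slope = 0.18)
  pr2 <- predict(ba, reference = 50)
  expect_equal(pr2$upper - pr2$bias, 2.46 * (1.32 + 0.18 * 50),
               tolerance = 0.01 * (1.32 + 0.18 * 50))
})

test_that("auto form selection follows the four-case scheme", {
  withr::local_seed(12)
  ref <- rnorm(60, 385, 60)
  # homoscedastic, no trend -> constant
  expect_equal(bland_altman(ref + rnorm(60, 5, 10), ref, B = 20,
                            seed = 1)$loa$form, "constant")
  # strong trend, homoscedastic residuals -> proportional
  ba_p <- bland_altman(ref + 100 - 0.4 * ref + rnorm(60, 0, 8), ref,
                       B = 20, seed = 1)
  expect_equal(ba_p$loa$form, "proportional")
  expect_true(ba_p$prop_bias$present)
  # fitted bias line of the proportional form tracks the trend
  pr <- predict(ba_p, reference = c(300, 450))
  expect_lt(pr$bias[2], pr$bias[1])

  # trend and growing spread -> both
  refu <- runif(120, 50, 400)
  ba_b <- bland_altman(refu + 60 - 0.3 * refu + rnorm(120, 0, 0.12 * refu),
                       refu, B = 20, seed = 1)
  expect_equal(ba_b$loa$form, "both")
})

test_that("bland_altman bootstrap is seed-deterministic and flags negative halfwidths", {
  withr::local_seed(14)
  ref <- rnorm(30, 385, 60)
  dev <- ref + rnorm(30, 10, 15)
  a <- bland_altman(dev, ref, B = 60, seed = 5)
  b <- bland_altman(dev, ref, B = 60, seed = 5)
  expect_identical(a$bias$ci_low, b$bias$ci_low)
  expect_identical(a$loa$lower$ci_high, b$loa$lower$ci_high)

  # decreasing-spread fixture: halfwidth goes negative at the top of range
  refu <- runif(120, 1, 100)
  devn <- refu + rnorm(120, 0, pmax(0.1, 10 - 0.12 * refu))
  ban <- bland_altman(devn, refu, B = 20, seed = 1,
                      loa_form = "heteroscedastic")
  if (ban$loa$hw_coef[["intercept"]] +
        ban$loa$hw_coef[["slope"]] * max(refu) < 0) {
    expect_true(ban$loa$negative_halfwidth)
  }
  succeed()
})

test_that("count agreement matches hand-computed weighted kappa", {
  ca <- nawk_agreement(c(0, 1, 2), c(0, 1, 2), B = 50, seed = 1)
  expect_equal(ca$mean_diff$estimate, 0)
  expect_equal(ca$median_diff$estimate, 0)
  expect_equal(ca$weighted_kappa$estimate, 1)

  rev <- nawk_agreement(c(2, 1, 0), c(0, 1, 2), B = 50, seed = 1)
  expect_equal(rev$mean_diff$estimate, 0)
  expect_equal(rev$median_diff$estimate, 0)
  expect_equal(rev$weighted_kappa$estimate,
               oracle_weighted_kappa(c(0, 1, 2), c(2, 1, 0)),
               tolerance = 1e-12)

  # random instance vs oracle; K = 2 reduces to unweighted kappa
  withr::local_seed(16)
  a <- sample(0:4, 40, TRUE)
  b <- sample(0:4, 40, TRUE)
  expect_equal(nawk_agreement(a, b, B = 20, seed = 1)$weighted_kappa$estimate,
               oracle_weighted_kappa(b, a), tolerance = 1e-12)
  x <- sample(0:1, 40, TRUE)
  y <- sample(0:1, 40, TRUE)
  expect_equal(nawk_agreement(x, y, B = 20, seed = 1)$weighted_kappa$estimate,
               oracle_kappa(as.character(y), as.character(x),
                            classes = c("0", "1")),
               tolerance = 1e-12)

  # all-identical constant counts: kappa undefined with reason
  const <- nawk_agreement(rep(2, 5), rep(2, 5), B = 20, seed = 1)
  expect_true(is.na(const$weighted_kappa$estimate))
  expect_match(const$weighted_kappa$reason, "identical")

  # mostly-zero differences give the degenerate median interval (0, 0)
  dz <- nawk_agreement(c(1, 2, 2, 3, 1, 4, 2), c(1, 2, 2, 3, 1, 2, 2),
                       B = 200, seed = 1)
  expect_equal(dz$median_diff$estimate, 0)
  expect_equal(dz$median_diff$ci_low, 0)
  expect_equal(dz$median_diff$ci_high, 0)
})

test_that("evaluate_measures produces one entry per measure and recovers injected bias", {
  sim <- small_sim_cohort(seed = 23, n = 8)
  mt <- cohort_measures(align_cohort(sim))
  ev <- evaluate_measures(mt, B = 60, seed = 2)
  expect_length(ev$results, 8)
  expect_s3_class(ev$results$tst_min, "bland_altman")
  expect_s3_class(ev$results$nawk, "count_agreement")
  df <- as.data.frame(ev)
  expect_equal(nrow(df), 7)

  # perfect device: zero biases, weighted kappa 1
  perfect <- toy_cohort(c("WWLLWDDRWW", "WLLLLLLLWW", "LLWDDWRRWW"))
  evp <- evaluate_measures(cohort_measures(perfect), B = 30, seed = 1)
  for (m in c("tst_min", "waso_min", "se_pct", "sol_min")) {
    expect_equal(evp$results[[m]]$bias$estimate, 0)
  }
  expect_equal(evp$results$nawk$weighted_kappa$estimate, 1)

  # failure on one measure does not abort the others
  mt_bad <- mt
  mt_bad$se_pct <- 50   # zero-variance regressor for SE only
  evb <- evaluate_measures(mt_bad, B = 30, seed = 1)
  expect_s3_class(evb$results$se_pct, "measure_error")
  expect_s3_class(evb$results$tst_min, "bland_altman")
})
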