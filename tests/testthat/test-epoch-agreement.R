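test_that("confusion tables pool per-participant counts over unmasked epochs", {
  co <- toy_cohort(c("LLWW", "LWLW"), c("LLLW", "LLLL"))
  ct <- confusion_table(co, "sleepwake")
  expect_equal(sum(ct$counts), 8)
  expect_equal(ct$counts, Reduce(`+`, ct$per_participant))

  # hand count on ref S,S,S,W vs dev S,S,W,W: TP=2 FN=1 TN=1 FP=0
  co2 <- toy_cohort("LLWW", "LLLW")
  ct2 <- confusion_table(co2, "sleepwake")
  expect_equal(ct2$counts["SLEEP", "SLEEP"], 2)
  expect_equal(ct2$counts["SLEEP", "WAKE"], 1)
  expect_equal(ct2$counts["WAKE", "WAKE"], 1)
  expect_equal(ct2$counts["WAKE", "SLEEP"], 0)

  # identical arms give a diagonal table
  ctd <- confusion_table(toy_cohort(c("WLDR", "LLRR")), "device")
  expect_equal(sum(ctd$counts) - sum(diag(ctd$counts)), 0)

  # masked epochs are excluded pairwise
  co3 <- toy_cohort("LLWW", "LLLW")
  co3$records$p1$device$labels[1] <- NA
  co3$records$p1$device$missing[1] <- TRUE
  co3$records$p1$reference$labels[1] <- NA
  co3$records$p1$reference$missing[1] <- TRUE
  ct3 <- confusion_table(co3, "sleepwake")
  expect_equal(ct3$n_epochs, 3)
  expect_equal(ct3$n_masked, 1)
})

test_that("binary metrics match arithmetic and the enumeration oracle", {
  co <- toy_cohort("LLWW", "LLLW")
  bm <- binary_metrics(confusion_table(co, "sleepwake"), B = 50, seed = 1)
  expect_equal(bm$sensitivity$estimate, 2 / 3)
  expect_equal(bm$specificity$estimate, 1.0)
  expect_equal(bm$ppv$estimate, 1.0)
  expect_equal(bm$npv$estimate, 0.5)

  # table chosen to echo plain ratio arithmetic: 97/100 and 70/100
  ref <- c(rep("L", 100), rep("W", 100))
  dev <- c(rep("L", 97), rep("W", 3), rep("W", 70), rep("L", 30))
  co2 <- toy_cohort(paste(dev, collapse = ""), paste(ref, collapse = ""))
  bm2 <- binary_metrics(confusion_table(co2, "sleepwake"), B = 50, seed = 1)
  expect_equal(bm2$sensitivity$estimate, 0.97)
  expect_equal(bm2$specificity$estimate, 0.70)

  # random multi-participant instance against the brute-force oracle
  withr::local_seed(5)
  codes_r <- replicate(4, paste(sample(c("W", "L", "D", "R"), 60, TRUE),
                                collapse = ""))
  codes_d <- replicate(4, paste(sample(c("W", "L", "D", "R"), 60, TRUE),
                                collapse = ""))
  co3 <- toy_cohort(codes_d, codes_r)
  bm3 <- binary_metrics(confusion_table(co3, "sleepwake"), B = 20, seed = 1)
  map <- c(W = "WAKE", L = "SLEEP", D = "SLEEP", R = "SLEEP")
  oc <- oracle_rates(map[unlist(strsplit(codes_r, ""))],
                     map[unlist(strsplit(codes_d, ""))])
  for (nm in names(oc)) {
    expect_equal(bm3[[nm]]$estimate, unname(oc[nm]), tolerance = 1e-12)
  }

  # perfect device maxes out every rate
  bmp <- binary_metrics(confusion_table(toy_cohort(c("WLLW", "LWLD")),
                                        "sleepwake"), B = 20, seed = 1)
  for (nm in names(bmp)) expect_equal(bmp[[nm]]$estimate, 1.0)
})

test_that("undefined rates are reported with a reason, not coerced to 0", {
  bm <- binary_metrics(confusion_table(toy_cohort("LLLL"), "sleepwake"),
                       B = 20, seed = 1)
  expect_true(is.na(bm$specificity$estimate))
  expect_match(bm$specificity$reason, "negative reference")
  expect_equal(bm$sensitivity$estimate, 1.0)
})

test_that("Cohen's kappa matches hand computation in both modes", {
  co <- toy_cohort("LLWW", "LLLW")
  ct <- confusion_table(co, "sleepwake")
  k <- cohens_kappa(ct, "pooled", B = 50, seed = 1)
  # po = 0.75, pe = 0.5 -> kappa 0.5
  expect_equal(k$estimate, 0.5)

  # perfect agreement
  ctp <- confusion_table(toy_cohort(c("WLDR", "LLW")), "device")
  expect_equal(cohens_kappa(ctp, "pooled", B = 20, seed = 1)$estimate, 1.0)

  # average mode: mean of per-participant kappas, undefined ones excluded
  co2 <- toy_cohort(c("LLWW", "LLLL"), c("LLLW", "LLLL"))
  ka <- cohens_kappa(confusion_table(co2, "sleepwake"), "average",
                     B = 50, seed = 1)
  expect_equal(ka$estimate, 0.5)   # p2 all-sleep is kappa-undefined
  expect_equal(attr(ka, "n_excluded"), 1)

  # oracle equivalence on a random 4-class instance
  withr::local_seed(9)
  rc <- paste(sample(c("W", "L", "D", "R"), 80, TRUE), collapse = "")
  dc <- paste(sample(c("W", "L", "D", "R"), 80, TRUE), collapse = "")
  kp <- cohens_kappa(confusion_table(toy_cohort(dc, rc), "device"),
                     "pooled", B = 20, seed = 1)
  map <- c(W = "WAKE", L = "LIGHT", D = "DEEP", R = "REM")
  expect_equal(kp$estimate,
               oracle_kappa(map[strsplit(rc, "")[[1]]],
                            map[strsplit(dc, "")[[1]]],
                            classes = c("WAKE", "LIGHT", "DEEP", "REM")),
               tolerance = 1e-12)
})

test_that("kappa of independent random labels is near zero at large n", {
  withr::local_seed(21)
  n <- 20000
  rc <- paste(sample(c("W", "L"), n, TRUE), collapse = "")
  dc <- paste(sample(c("W", "L"), n, TRUE), collapse = "")
  k <- cohens_kappa(confusion_table(toy_cohort(dc, rc), "sleepwake"),
                    "pooled", B = 20, seed = 1)
  expect_lt(abs(k$estimate), 3 / sqrt(n))
})

test_that("per-stage one-vs-rest metrics behave at the boundaries", {
  co <- toy_cohort(c("WLDRWLDR", "LLDDRRWW"))
  ps <- per_stage_metrics(co, B = 30, seed = 1)
  for (rw in names(ps$table)) {
    expect_equal(ps$table[[rw]]$kappa$estimate, 1.0)
    expect_equal(ps$table[[rw]]$accuracy$estimate, 1.0)
  }
  expect_true(is.na(ps$table$overall$ppv$estimate))

  # device that always answers LIGHT: light sensitivity 1, PPV = prevalence
  ref_codes <- c("WLDRLLDR", "LLDDRRWW")
  dev_codes <- c("LLLLLLLL", "LLLLLLLL")
  ps2 <- per_stage_metrics(toy_cohort(dev_codes, ref_codes), B = 30, seed = 1)
  expect_equal(ps2$table$LIGHT$sensitivity$estimate, 1.0)
  prev_light <- mean(unlist(strsplit(ref_codes, "")) == "L")
  expect_equal(ps2$table$LIGHT$ppv$estimate, prev_light)

  # dichotomized true positives sum to the 4-class diagonal total
  withr::local_seed(3)
  rc <- replicate(3, paste(sample(c("W", "L", "D", "R"), 50, TRUE), collapse = ""))
  dc <- replicate(3, paste(sample(c("W", "L", "D", "R"), 50, TRUE), collapse = ""))
  co3 <- toy_cohort(dc, rc)
  ct4 <- confusion_table(co3, "device")
  ps3 <- per_stage_metrics(co3, B = 20, seed = 1)
  tp_sum <- sum(vapply(c("WAKE", "LIGHT", "DEEP", "REM"), function(s)
    ps3$table[[s]]$sensitivity$estimate * sum(ct4$counts[s, ]), 0))
  expect_equal(tp_sum, sum(diag(ct4$counts)), tolerance = 1e-9)
})

test_that("per-stage pooled sensitivities recover an injected confusion matrix", {
  C <- sim_config()$confusion_matrix
  cfg <- sim_config(n_participants = 12, tib_epochs = 720,
                    heterogeneity = Inf, seed = 17)
  co <- suppressMessages(simulate_cohort(cfg))
  ps <- per_stage_metrics(align_cohort(co), B = 20, seed = 1)
  for (s in rownames(C)) {
    expect_equal(ps$table[[s]]$sensitivity$estimate, C[s, s], tolerance = 0.05)
  }
})

test_that("cluster bootstrap is deterministic, degenerate-safe and clustered", {
  # identical participants -> zero-width interval
  co <- toy_cohort(rep("LLWW", 4), rep("LLLW", 4))
  bm <- binary_metrics(confusion_table(co, "sleepwake"), B = 100, seed = 3)
  expect_equal(bm$sensitivity$ci_low, bm$sensitivity$ci_high)
  expect_equal(bm$sensitivity$ci_low, 2 / 3)

  # same seed -> identical endpoints; different seed -> (generically) not
  sim <- small_sim_cohort()
  ct <- confusion_table(align_cohort(sim), "sleepwake")
  a <- binary_metrics(ct, B = 80, seed = 9)
  b <- binary_metrics(ct, B = 80, seed = 9)
  expect_identical(a$sensitivity$ci_low, b$sensitivity$ci_low)
  expect_identical(a$npv$ci_high, b$npv$ci_high)

  # generic engine: statistic over a plain list of units
  vals <- list(1, 2, 3, 4, 5)
  bt <- cluster_bootstrap(vals, function(u) mean(unlist(u)), B = 200, seed = 2)
  expect_equal(bt$estimate, 3)
  expect_true(bt$ci_low >= 1 && bt$ci_high <= 5)
  # statistic that is fine on the observed units but undefined on almost
  # every resample (duplicates) must abort with a diagnostic
  expect_error(
    cluster_bootstrap(vals, function(u) {
      if (anyDuplicated(unlist(u))) stop("tie") else mean(unlist(u))
    }, B = 40, seed = 1),
    "more than half")

  # kappa from identical participants equals each participant's kappa
  kp <- cohens_kappa(confusion_table(co, "sleepwake"), "pooled", B = 20, seed = 1)
  ka <- cohens_kappa(confusion_table(co, "sleepwake"), "average", B = 20, seed = 1)
  expect_equal(kp$estimate, ka$estimate)
})

test_that("cluster-bootstrap CIs achieve near-nominal coverage over cohorts", {
  # scaled-down coverage study: the pooled sleep sensitivity of each
  # simulated cohort should be covered by its 95% CI in about 95% of cohorts
  n_cohorts <- 60
  hits <- 0
  for (s in seq_len(n_cohorts)) {
    co <- suppressMessages(
      simulate_cohort(sim_config(n_participants = 12, tib_epochs = 240,
                                 seed = 1000 + s)))
    truth <- 1 - sim_config()$confusion_matrix[c("LIGHT", "DEEP", "REM"), "WAKE"]
    # population-level injected sensitivity: occupancy-weighted base rates
    # are all 0.97 by construction
    bm <- binary_metrics(confusion_table(align_cohort(co), "sleepwake"),
                         B = 200, seed = s)
    hits <- hits + (bm$sensitivity$ci_low <= 0.97 &&
                      bm$sensitivity$ci_high >= 0.97)
  }
  expect_gte(hits / n_cohorts, 0.85)
})
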