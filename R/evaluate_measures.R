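# Night-level agreement across every overnight sleep measure.

continuous_measures <- c(tst_min = "TST (min)", waso_min = "WASO (min)",
                         se_pct = "SE (%)", sol_min = "SOL (min)",
                         light_min = "Light (min)", deep_min = "Deep (min)",
                         rem_min = "REM (min)")

#' Evaluate device-vs-reference agreement for all overnight measures
#'
#' Runs [bland_altman()] on the seven continuous measures (TST, WASO, SE,
#' SOL, light/deep/REM duration) and [nawk_agreement()] on the awakening
#' count, from a paired measures table as produced by [cohort_measures()].
#' A failure on one measure (e.g. a degenerate regressor) is recorded for
#' that measure without aborting the others.
#'
#' @param measures data frame from [cohort_measures()]: one row per
#'   participant per `source`.
#' @param B,seed bootstrap replicates and seed (shared across measures so
#'   every measure sees the same participant resamples).
#' @param loa_form limits-of-agreement parameterization, see
#'   [bland_altman()].
#' @return An object of class `"measure_agreement"`: named list with one
#'   [bland_altman()] fit per continuous measure (or an error message), a
#'   [nawk_agreement()] under `nawk`, plus the per-arm summary means/SDs.
#' @export
evaluate_measures <- function(measures, B = 1000L, seed = 1L,
                              loa_form = "auto") {
  need <- c("participant_id", "source", names(continuous_measures), "nawk")
  miss <- setdiff(need, names(measures))
  if (length(miss)) stopf("measures table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  dev <- measures[measures$source == "device", , drop = FALSE]
  ref <- measures[measures$source == "reference", , drop = FALSE]
  ids <- intersect(dev$participant_id, ref$participant_id)
  if (length(ids) < 2) stopf("need at least 2 participants with both arms")
  dev <- dev[match(ids, dev$participant_id), ]
  ref <- ref[match(ids, ref$participant_id), ]

  results <- list()
  for (m in names(continuous_measures)) {
    results[[m]] <- tryCatch(
      bland_altman(dev[[m]], ref[[m]], B = B, seed = seed,
                   loa_form = loa_form, measure = continuous_measures[[m]]),
      error = function(e) structure(list(measure = continuous_measures[[m]],
                                         message = conditionMessage(e)),
                                    class = "measure_error"))
  }
  results$nawk <- tryCatch(
    nawk_agreement(dev$nawk, ref$nawk, B = B, seed = seed),
    error = function(e) structure(list(measure = "NAWK (count)",
                                       message = conditionMessage(e)),
                                  class = "measure_error"))
  arm_summary <- function(df) {
    sapply(c(names(continuous_measures), "nawk"), function(m)
      c(mean = mean(df[[m]]), sd = stats::sd(df[[m]]),
        median = stats::median(df[[m]])))
  }
  structure(list(results = results, n = length(ids),
                 summary_device = arm_summary(dev),
                 summary_reference = arm_summary(ref),
                 B = B, seed = seed),
            class = "measure_agreement")
}

#' @export
print.measure_agreement <- function(x, ...) {
  cat(sprintf("night-level agreement, %d participants (device - reference)\n",
              x$n))
  cat(sprintf("%-12s %10s %10s  %-24s %s\n",
              "measure", "ref mean", "dev mean", "bias (95% CI)", "LOA form"))
  for (m in names(continuous_measures)) {
    r <- x$results[[m]]
    if (inherits(r, "measure_error")) {
      cat(sprintf("%-12s failed: %s\n", continuous_measures[[m]], r$message))
      next
    }
    cat(sprintf("%-12s %10.2f %10.2f  %-24s %s%s\n",
                continuous_measures[[m]],
                x$summary_reference["mean", m], x$summary_device["mean", m],
                format(r$bias), r$loa$form,
                if (r$prop_bias$present) " (prop. bias)" else ""))
  }
  nk <- x$results$nawk
  if (inherits(nk, "measure_error")) {
    cat(sprintf("%-12s failed: %s\n", "NAWK (count)", nk$message))
  } else {
    cat(sprintf("%-12s %10.2f %10.2f  mean diff %s, median diff %s, kappa_w %s\n",
                "NAWK (count)", x$summary_reference["mean", "nawk"],
                x$summary_device["mean", "nawk"], format(nk$mean_diff),
                format(nk$median_diff, digits = 1), format(nk$weighted_kappa)))
  }
  invisible(x)
}

#' Flatten a measure-agreement result into a report table
#'
#' @param x a `"measure_agreement"` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A data frame with one row per measure: per-arm means/SDs, bias
#'   with CI, assumption flags, bias-model and halfwidth-model coefficients
#'   with CIs, and constant limits when applicable.
#' @export
as.data.frame.measure_agreement <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  rows <- lapply(names(continuous_measures), function(m) {
    r <- x$results[[m]]
    base <- data.frame(measure = continuous_measures[[m]],
                       ref_mean = x$summary_reference["mean", m],
                       ref_sd = x$summary_reference["sd", m],
                       dev_mean = x$summary_device["mean", m],
                       dev_sd = x$summary_device["sd", m])
    if (inherits(r, "measure_error")) {
      return(cbind(base, data.frame(error = r$message)))
    }
    cbind(base, data.frame(
      bias = r$bias$estimate, bias_lo = r$bias$ci_low, bias_hi = r$bias$ci_high,
      prop_bias = r$prop_bias$present,
      normality = if (is.na(r$normality$pass)) NA else r$normality$pass,
      heteroscedastic = if (is.na(r$heteroscedastic$present)) NA else
        r$heteroscedastic$present,
      pb_intercept = r$prop_bias$intercept, pb_slope = r$prop_bias$slope,
      pb_slope_lo = r$prop_bias$slope_ci[1], pb_slope_hi = r$prop_bias$slope_ci[2],
      loa_form = r$loa$form,
      loa_lower = r$loa$lower$estimate, loa_upper = r$loa$upper$estimate,
      hw_intercept = r$loa$hw_coef[["intercept"]],
      hw_slope = r$loa$hw_coef[["slope"]], error = NA_character_))
  })
  out <- do.call(rbind, lapply(rows, function(df) {
    for (col in c("bias", "bias_lo", "bias_hi", "prop_bias", "normality",
                  "heteroscedastic", "pb_intercept", "pb_slope", "pb_slope_lo",
                  "pb_slope_hi", "loa_form", "loa_lower", "loa_upper",
                  "hw_intercept", "hw_slope", "error")) {
      if (!col %in% names(df)) df[[col]] <- NA
    }
    df
  }))
  rownames(out) <- NULL
  out
}
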