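# Bland-Altman agreement analysis with assumption testing and modeled
# limits of agreement.

# 1.96 * sqrt(pi/2): multiplier turning a fitted mean absolute residual
# into a 95% limit-of-agreement halfwidth under normality (approx. 2.46).
LOA_ABS_MULT <- stats::qnorm(0.975) * sqrt(pi / 2)
LOA_SD_MULT <- stats::qnorm(0.975)

#' Mean bias between device and reference measures
#'
#' Mean of the per-participant differences (device minus reference), with a
#' participant-bootstrap percentile CI.  Equals
#' `mean(device) - mean(reference)` exactly.
#'
#' @param device,reference paired numeric vectors (one value per
#'   participant).
#' @param B,seed bootstrap replicates and seed.
#' @return A [metric_ci()] in the units of the measure.
#' @export
mean_bias <- function(device, reference, B = 1000L, seed = 1L) {
  d <- check_pairs(device, reference, min_n = 2)
  bt <- cluster_bootstrap(as.list(d), function(u) mean(unlist(u)),
                          B = B, seed = seed)
  boot_metric(bt)
}

check_pairs <- function(device, reference, min_n) {
  if (length(device) != length(reference)) stopf("device/reference lengths differ")
  ok <- !is.na(device) & !is.na(reference)
  if (sum(ok) < min_n) stopf("need at least %d complete pairs", min_n)
  structure(device[ok] - reference[ok], reference = reference[ok],
            device = device[ok])
}

ols_line <- function(y, x) {
  fit <- stats::lm(y ~ x)
  # zero-residual fits trip summary.lm's perfect-fit warning; the CI is
  # then legitimately zero-width and degenerate cases are handled upstream
  ci <- suppressWarnings(stats::confint(fit))
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       intercept_ci = unname(ci[1, ]), slope_ci = unname(ci[2, ]),
       residuals = unname(stats::resid(fit)))
}

#' Test for proportional bias
#'
#' Ordinary least squares of the differences `device - reference` on the
#' reference value (the reference, not the pair mean, is the regressor, so
#' fitted limits read as functions of the reference measurement).
#' Proportional bias is declared when the two-sided 95% CI of the slope
#' excludes 0.
#'
#' @param device,reference paired numeric vectors, `n >= 3`.
#' @return A list: `intercept`, `slope`, their analytic 95% CIs, `present`,
#'   and the regression `residuals`.
#' @export
test_proportional_bias <- function(device, reference) {
  d <- check_pairs(device, reference, min_n = 3)
  x <- attr(d, "reference")
  if (stats::var(x) < 1e-12) stopf("degenerate regressor: reference has zero variance")
  fit <- ols_line(as.numeric(d), x)
  fit$present <- !is.na(fit$slope_ci[1]) &&
    (fit$slope_ci[1] > 0 || fit$slope_ci[2] < 0)
  fit
}

#' Test the Bland-Altman distributional assumptions
#'
#' Normality: Shapiro-Wilk on the residuals of the proportional-bias
#' regression at alpha = 0.05.  Heteroscedasticity: OLS of the absolute
#' residuals on the reference value; heteroscedasticity is declared when the
#' slope's 95% CI excludes 0 (the fitted coefficients feed the modeled
#' limit-of-agreement halfwidth).  Degenerate residuals (all ~0) make both
#' tests not applicable.
#'
#' @param device,reference paired numeric vectors, `n >= 3`.
#' @return A list with components `normality` (`statistic`, `p`, `pass`) and
#'   `heteroscedastic` (`intercept`, `slope`, CIs, `present`), each carrying
#'   `reason` when not applicable.
#' @export
test_assumptions <- function(device, reference) {
  pb <- test_proportional_bias(device, reference)
  assumptions_from_residuals(pb$residuals, attr(check_pairs(device, reference, 3),
                                                "reference"))
}

assumptions_from_residuals <- function(res, x) {
  degen <- stats::sd(res) < 1e-10
  normality <- if (degen || length(res) < 3 || length(unique(res)) < 3) {
    list(statistic = NA_real_, p = NA_real_, pass = NA,
         reason = "degenerate residuals")
  } else {
    sw <- stats::shapiro.test(res)
    list(statistic = unname(sw$statistic), p = sw$p.value,
         pass = sw$p.value >= 0.05, reason = NULL)
  }
  het <- if (degen) {
    list(intercept = 0, slope = 0, intercept_ci = c(NA_real_, NA_real_),
         slope_ci = c(NA_real_, NA_real_), present = NA,
         reason = "degenerate residuals")
  } else {
    hfit <- ols_line(abs(res), x)
    hfit$present <- hfit$slope_ci[1] > 0 || hfit$slope_ci[2] < 0
    hfit$reason <- NULL
    hfit
  }
  list(normality = normality, heteroscedastic = het)
}

# point estimates of every BA parameter on one set of pairs; `form` fixes
# which LOA parameterization the lower/upper components use
ba_params <- function(device, reference, form) {
  d <- device - reference
  x <- reference
  out <- c(bias = mean(d), sd_d = stats::sd(d))
  if (stats::var(x) < 1e-12) stop("degenerate regressor")
  pfit <- stats::lm(d ~ x)
  res <- unname(stats::resid(pfit))
  hfit <- stats::lm(abs(res) ~ x)
  out <- c(out,
           pb_intercept = unname(stats::coef(pfit)[1]),
           pb_slope = unname(stats::coef(pfit)[2]),
           hw_intercept = unname(stats::coef(hfit)[1]),
           hw_slope = unname(stats::coef(hfit)[2]),
           sd_resid = stats::sd(res))
  lo_up <- switch(form,
    constant = c(out[["bias"]] - LOA_SD_MULT * out[["sd_d"]],
                 out[["bias"]] + LOA_SD_MULT * out[["sd_d"]]),
    proportional = c(NA_real_, NA_real_),
    heteroscedastic = c(NA_real_, NA_real_),
    both = c(NA_real_, NA_real_))
  c(out, lower = lo_up[1], upper = lo_up[2])
}

#' Bland-Altman analysis of one paired sleep measure
#'
#' Estimates the mean bias (device minus reference), tests the assumptions
#' of proportional bias, normality of residuals, and heteroscedasticity,
#' and builds 95% limits of agreement (LOA) under a four-case scheme driven
#' by the assumption tests:
#'
#' * no proportional bias, homoscedastic: `bias +/- 1.96 sd(d)`;
#' * proportional bias, homoscedastic: `(b0 + b1 x) +/- 1.96 sd(residuals)`;
#' * no proportional bias, heteroscedastic: `bias +/- 2.46 (c0 + c1 x)`;
#' * both: `(b0 + b1 x) +/- 2.46 (c0 + c1 x)`;
#'
#' where `x` is the reference value, `(b0, b1)` the difference-on-reference
#' regression, `(c0, c1)` the absolute-residual-on-reference regression, and
#' `2.46 = 1.96 sqrt(pi/2)` converts a mean absolute deviation into a 95%
#' normal halfwidth.  All parameters get participant-bootstrap percentile
#' CIs (pairs are resampled jointly).  `loa_form` can force any of the four
#' parameterizations regardless of the tests.
#'
#' @param device,reference paired per-participant measure values.
#' @param B,seed bootstrap replicates and seed.
#' @param loa_form `"auto"` (assumption-driven) or one of `"constant"`,
#'   `"proportional"`, `"heteroscedastic"`, `"both"`.
#' @param measure optional measure name carried into printouts.
#' @return An object of class `"bland_altman"` with components `n`, `data`,
#'   `bias` ([metric_ci()]), `prop_bias`, `normality`, `heteroscedastic`,
#'   and `loa` (form, multiplier, coefficient estimates with CIs, constant
#'   limits when applicable, and a `negative_halfwidth` flag raised if the
#'   fitted halfwidth goes negative over the observed reference range).
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' set.seed(1)
#' ref <- rnorm(41, 385, 60)
#' dev <- ref + 14 + rnorm(41, 0, 25)
#' ba <- bland_altman(dev, ref, B = 200, seed = 7, measure = "TST (min)")
#' ba
#' predict(ba, reference = c(300, 400, 500))
#' @export
bland_altman <- function(device, reference, B = 1000L, seed = 1L,
                         loa_form = c("auto", "constant", "proportional",
                                      "heteroscedastic", "both"),
                         measure = NULL) {
  loa_form <- match.arg(loa_form)
  d <- check_pairs(device, reference, min_n = 3)
  x <- attr(d, "reference")
  dev <- attr(d, "device")
  n <- length(x)

  pb <- test_proportional_bias(dev, x)
  assum <- assumptions_from_residuals(pb$residuals, x)
  form <- if (loa_form != "auto") loa_form else {
    het <- isTRUE(assum$heteroscedastic$present)
    if (pb$present && het) "both"
    else if (pb$present) "proportional"
    else if (het) "heteroscedastic"
    else "constant"
  }

  est <- ba_params(dev, x, form)
  pairs_df <- data.frame(device = dev, reference = x)
  bt <- cluster_bootstrap(split(pairs_df, seq_len(n)), function(u) {
    df <- do.call(rbind, u)
    ba_params(df$device, df$reference, form)
  }, B = B, seed = seed)

  mult <- if (form %in% c("heteroscedastic", "both")) LOA_ABS_MULT else LOA_SD_MULT
  bias_coef <- if (form %in% c("proportional", "both")) {
    c(intercept = est[["pb_intercept"]], slope = est[["pb_slope"]])
  } else c(intercept = est[["bias"]], slope = 0)
  hw_coef <- if (form %in% c("heteroscedastic", "both")) {
    c(intercept = est[["hw_intercept"]], slope = est[["hw_slope"]])
  } else if (form == "proportional") {
    c(intercept = est[["sd_resid"]], slope = 0)
  } else c(intercept = est[["sd_d"]], slope = 0)
  hw_range <- mult * (hw_coef[["intercept"]] + hw_coef[["slope"]] * range(x))

  loa <- list(
    form = form, multiplier = mult,
    bias_coef = bias_coef, hw_coef = hw_coef,
    pb_intercept = boot_metric(bt, "pb_intercept"),
    pb_slope = boot_metric(bt, "pb_slope"),
    hw_intercept = boot_metric(bt, "hw_intercept"),
    hw_slope = boot_metric(bt, "hw_slope"),
    sd_resid = est[["sd_resid"]], sd_d = est[["sd_d"]],
    lower = boot_metric(bt, "lower", "no constant limits for this form"),
    upper = boot_metric(bt, "upper", "no constant limits for this form"),
    negative_halfwidth = any(hw_range < 0))

  structure(list(measure = measure, n = n,
                 data = data.frame(reference = x, device = dev,
                                   difference = as.numeric(d)),
                 bias = boot_metric(bt, "bias"),
                 prop_bias = pb, normality = assum$normality,
                 heteroscedastic = assum$heteroscedastic, loa = loa,
                 B = B, seed = seed),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman analysis%s (n = %d, device - reference)\n",
              if (!is.null(x$measure)) paste0(": ", x$measure) else "", x$n))
  cat(sprintf("  mean bias        %s\n", format(x$bias)))
  cat(sprintf("  proportional bias %s: %.2f + %.2f x ref, slope CI [%.2f, %.2f]\n",
              if (x$prop_bias$present) "PRESENT" else "absent",
              x$prop_bias$intercept, x$prop_bias$slope,
              x$prop_bias$slope_ci[1], x$prop_bias$slope_ci[2]))
  nr <- x$normality
  cat(sprintf("  normality        %s\n",
              if (is.na(nr$pass)) paste0("n/a (", nr$reason, ")")
              else sprintf("%s (Shapiro-Wilk W = %.3f, p = %.3g)",
                           if (nr$pass) "pass" else "fail", nr$statistic, nr$p)))
  ht <- x$heteroscedastic
  cat(sprintf("  heteroscedastic  %s\n",
              if (is.na(ht$present)) paste0("n/a (", ht$reason, ")")
              else if (ht$present) "PRESENT" else "absent"))
  cat(sprintf("  95%% LOA (%s form):\n", x$loa$form))
  if (x$loa$form == "constant") {
    cat(sprintf("    lower %s   upper %s\n",
                format(x$loa$lower), format(x$loa$upper)))
  } else {
    b <- x$loa$bias_coef; h <- x$loa$hw_coef
    cat(sprintf("    (%.2f + %.2f x ref) +/- %.2f (%.2f + %.2f x ref)\n",
                b[1], b[2], x$loa$multiplier, h[1], h[2]))
  }
  if (x$loa$negative_halfwidth) {
    cat("  WARNING: fitted LOA halfwidth goes negative over the observed range\n")
  }
  invisible(x)
}

#' @export
summary.bland_altman <- function(object, ...) {
  print(object)
  cat(sprintf("  bootstrap: B = %d, seed = %d\n", object$B, object$seed))
  cat("  coefficients with bootstrap CIs:\n")
  for (nm in c("pb_intercept", "pb_slope", "hw_intercept", "hw_slope")) {
    cat(sprintf("    %-12s %s\n", nm, format(object$loa[[nm]], digits = 3)))
  }
  invisible(object)
}

#' @export
coef.bland_altman <- function(object, ...) {
  c(bias = object$bias$estimate,
    bias_intercept = object$loa$bias_coef[["intercept"]],
    bias_slope = object$loa$bias_coef[["slope"]],
    hw_intercept = object$loa$hw_coef[["intercept"]],
    hw_slope = object$loa$hw_coef[["slope"]],
    multiplier = object$loa$multiplier)
}

#' Predicted bias and limits of agreement at given reference values
#'
#' @param object a [bland_altman()] fit.
#' @param reference reference-measure values at which to evaluate the fitted
#'   bias and limits; defaults to the observed values.
#' @param ... ignored.
#' @return A data frame with columns `reference`, `bias`, `lower`, `upper`.
#' @export
predict.bland_altman <- function(object, reference = NULL, ...) {
  x <- reference %||% object$data$reference
  b <- object$loa$bias_coef
  h <- object$loa$hw_coef
  bias <- b[["intercept"]] + b[["slope"]] * x
  hw <- object$loa$multiplier * (h[["intercept"]] + h[["slope"]] * x)
  data.frame(reference = x, bias = bias, lower = bias - hw, upper = bias + hw)
}

#' @export
residuals.bland_altman <- function(object, ...) {
  object$data$difference -
    (object$loa$bias_coef[["intercept"]] +
       object$loa$bias_coef[["slope"]] * object$data$reference)
}

#' Bland-Altman plot
#'
#' Differences against the reference value, with the fitted bias line
#' (solid) and 95% limits of agreement (dashed).
#'
#' @param x a [bland_altman()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  xs <- seq(min(x$data$reference), max(x$data$reference), length.out = 100)
  pr <- predict(x, reference = xs)
  ylim <- range(c(x$data$difference, pr$lower, pr$upper))
  graphics::plot(x$data$reference, x$data$difference,
                 xlab = "reference", ylab = "device - reference",
                 main = x$measure %||% "Bland-Altman", ylim = ylim, pch = 16, ...)
  graphics::lines(xs, pr$bias, col = "red")
  graphics::lines(xs, pr$lower, col = "grey40", lty = 2)
  graphics::lines(xs, pr$upper, col = "grey40", lty = 2)
  graphics::abline(h = 0, col = "grey80")
  invisible(x)
}

#' Limits of agreement from completed assumption tests
#'
#' Convenience wrapper returning just the `loa` component of
#' [bland_altman()]; the four-case parameterization is documented there.
#'
#' @inheritParams bland_altman
#' @return The `loa` list of a [bland_altman()] fit.
#' @export
limits_of_agreement <- function(device, reference, B = 1000L, seed = 1L,
                                loa_form = "auto") {
  bland_altman(device, reference, B = B, seed = seed, loa_form = loa_form)$loa
}
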