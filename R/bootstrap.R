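# Participant-level (cluster) bootstrap and the metric-with-CI container.

#' Metric with bootstrap confidence interval
#'
#' Lightweight container for a point estimate and its percentile bootstrap
#' interval.  `estimate` may be `NA` with a `reason` when the statistic is
#' undefined (e.g. a zero denominator); undefined estimates are reported as
#' such, never coerced to 0.
#'
#' @param estimate point estimate.
#' @param ci_low,ci_high percentile interval endpoints.
#' @param n_boot number of bootstrap replicates behind the interval.
#' @param seed RNG seed used for the resampling.
#' @param reason why the estimate is undefined, if it is.
#' @return An object of class `"metric_ci"`.
#' @export
metric_ci <- function(estimate, ci_low = NA_real_, ci_high = NA_real_,
                      n_boot = NA_integer_, seed = NA_integer_, reason = NULL) {
  structure(list(estimate = as.numeric(estimate), ci_low = as.numeric(ci_low),
                 ci_high = as.numeric(ci_high), n_boot = n_boot, seed = seed,
                 reason = reason),
            class = "metric_ci")
}

#' @export
format.metric_ci <- function(x, digits = 2, ...) {
  if (is.na(x$estimate)) {
    return(sprintf("undefined (%s)", x$reason %||% "no reason recorded"))
  }
  if (is.na(x$ci_low)) return(formatC(x$estimate, digits = digits, format = "f"))
  sprintf("%s (%s, %s)",
          formatC(x$estimate, digits = digits, format = "f"),
          formatC(x$ci_low, digits = digits, format = "f"),
          formatC(x$ci_high, digits = digits, format = "f"))
}

#' @export
print.metric_ci <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Cluster bootstrap over participants
#'
#' Resamples participants (clusters) with replacement -- never individual
#' epochs -- so that confidence intervals respect the within-participant
#' correlation of epoch data.  Each replicate draws `n` participants from
#' the `n` observed ones and re-evaluates `statistic`; intervals are the
#' 2.5/97.5 percentile points.  Deterministic for a fixed `seed`.
#'
#' `statistic` receives a resampled object of the same kind as `x` (a
#' [paired_cohort()] or a plain list of per-participant units) and must
#' return a numeric vector (named, if longer than 1).  Replicates on which
#' it errors count as undefined; if any component is undefined on more than
#' half of the replicates the bootstrap aborts with a diagnostic.
#'
#' @param x a [paired_cohort()] or a list of per-participant units.
#' @param statistic function of the resampled object.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed RNG seed (required: intervals must be reproducible).
#' @param ... passed through to `statistic`.
#' @return An object of class `"cluster_boot"`: `estimate` (statistic on the
#'   observed data), `ci_low`, `ci_high`, `replicates` (B x k matrix),
#'   `n_boot`, `seed`.
#' @export
cluster_bootstrap <- function(x, statistic, B = 1000L, seed = 1L, ...) {
  UseMethod("cluster_bootstrap")
}

#' @export
cluster_bootstrap.list <- function(x, statistic, B = 1000L, seed = 1L, ...) {
  boot_engine(length(x), function(idx) statistic(x[idx], ...),
              statistic(x, ...), B, seed)
}

#' @export
cluster_bootstrap.paired_cohort <- function(x, statistic, B = 1000L,
                                            seed = 1L, ...) {
  ids <- names(x$records)
  boot_engine(length(ids),
              function(idx) statistic(subset_cohort(x, ids[idx]), ...),
              statistic(x, ...), B, seed)
}

boot_engine <- function(n, eval_idx, est, B, seed) {
  stopifnot(B >= 1, n >= 1)
  est <- as.numeric_named(est)
  k <- length(est)
  reps <- matrix(NA_real_, B, k, dimnames = list(NULL, names(est)))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(as.numeric_named(eval_idx(idx)),
                      error = function(e) rep(NA_real_, k))
      if (length(val) == k) reps[b, ] <- val
    }
  })
  na_frac <- colMeans(is.na(reps))
  # a component that is undefined on the observed data stays undefined (its
  # caller reports the reason); a defined component failing on most
  # replicates signals a broken statistic and aborts
  bad <- na_frac > 0.5 & !is.na(est)
  if (any(bad)) {
    stopf("statistic undefined on more than half the bootstrap replicates: %s",
          paste(names(est)[bad], collapse = ", "))
  }
  ci <- vapply(seq_len(k), function(j) {
    if (all(is.na(reps[, j]))) return(c(NA_real_, NA_real_))
    stats::quantile(reps[, j], probs = c(0.025, 0.975), na.rm = TRUE,
                    names = FALSE)
  }, numeric(2))
  dimnames(ci) <- list(NULL, names(est))
  structure(list(estimate = est, ci_low = ci[1, ], ci_high = ci[2, ],
                 replicates = reps, n_boot = B, seed = seed),
            class = "cluster_boot")
}

as.numeric_named <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

#' @export
print.cluster_boot <- function(x, digits = 3, ...) {
  cat(sprintf("cluster bootstrap, B = %d, seed = %d\n", x$n_boot, x$seed))
  tab <- cbind(estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, digits))
  invisible(x)
}

# Pull one component of a cluster_boot out as a metric_ci.
boot_metric <- function(bt, name = 1L, reason = NULL) {
  est <- bt$estimate[name]
  if (is.na(est)) {
    return(metric_ci(NA_real_, n_boot = bt$n_boot, seed = bt$seed,
                     reason = reason %||% "undefined on the observed data"))
  }
  metric_ci(est, bt$ci_low[name], bt$ci_high[name], bt$n_boot, bt$seed)
}
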