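# Count-measure (number of awakenings) agreement statistics.

# Linearly weighted Cohen's kappa over integer categories `cats`
# (weights 1 - |i - j| / (K - 1)); NA when chance-corrected agreement is
# undefined (single observed category).
weighted_kappa <- function(x, y, cats = NULL) {
  stopifnot(length(x) == length(y))
  cats <- cats %||% seq(min(c(x, y)), max(c(x, y)))
  K <- length(cats)
  if (K < 2) return(NA_real_)
  P <- unclass(table(factor(x, levels = cats), factor(y, levels = cats))) /
    length(x)
  W <- 1 - abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
  po <- sum(W * P)
  pe <- sum(W * outer(rowSums(P), colSums(P)))
  if (1 - pe < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Agreement statistics for awakening counts
#'
#' Mean and median count difference (device minus reference) with
#' participant-bootstrap CIs, and linearly weighted Cohen's kappa over the
#' observed count range (weights `1 - |i - j| / (K - 1)`).  When more than
#' half of the paired differences are 0 the median difference has the
#' degenerate interval (0, 0).  If every count in both arms is the same
#' constant, weighted kappa is undefined and reported as such.
#'
#' @param device,reference paired nonnegative integer counts, `n >= 2`.
#' @param B,seed bootstrap replicates and seed.
#' @return An object of class `"count_agreement"`: [metric_ci()] components
#'   `mean_diff`, `median_diff`, `weighted_kappa`.
#' @export
nawk_agreement <- function(device, reference, B = 1000L, seed = 1L) {
  check_pairs(device, reference, min_n = 2)
  if (any(device < 0 | reference < 0) ||
      any(device != round(device) | reference != round(reference))) {
    stopf("counts must be nonnegative integers")
  }
  cats <- seq(min(c(device, reference)), max(c(device, reference)))
  pairs <- Map(c, device, reference)
  stat <- function(u) {
    m <- do.call(rbind, u)
    d <- m[, 1] - m[, 2]
    c(mean_diff = mean(d), median_diff = stats::median(d),
      weighted_kappa = weighted_kappa(m[, 1], m[, 2], cats = cats))
  }
  kw_undef <- is.na(weighted_kappa(device, reference, cats = cats))
  if (kw_undef) {
    # bootstrap only the defined components
    stat_def <- function(u) {
      m <- do.call(rbind, u)
      d <- m[, 1] - m[, 2]
      c(mean_diff = mean(d), median_diff = stats::median(d))
    }
    bt <- cluster_bootstrap(pairs, stat_def, B = B, seed = seed)
    kw <- metric_ci(NA_real_, n_boot = B, seed = seed,
                    reason = "all counts identical: chance agreement is 1")
  } else {
    bt <- cluster_bootstrap(pairs, stat, B = B, seed = seed)
    kw <- boot_metric(bt, "weighted_kappa", "degenerate count table")
  }
  structure(list(mean_diff = boot_metric(bt, "mean_diff"),
                 median_diff = boot_metric(bt, "median_diff"),
                 weighted_kappa = kw),
            class = "count_agreement")
}

#' @export
print.count_agreement <- function(x, ...) {
  cat("count agreement (device - reference)\n")
  cat(sprintf("  mean difference    %s\n", format(x$mean_diff)))
  cat(sprintf("  median difference  %s\n", format(x$median_diff, digits = 1)))
  cat(sprintf("  weighted kappa     %s\n", format(x$weighted_kappa)))
  invisible(x)
}
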