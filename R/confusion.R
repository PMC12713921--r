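# Epoch-by-epoch confusion tables and discrimination metrics.

#' Pooled and per-participant confusion tables
#'
#' Cross-tabulates reference stage (rows) against device stage (columns)
#' over the unmasked aligned epochs of every participant, confined to the
#' lights-off to lights-on window.  Both series are first collapsed to the
#' requested scheme (`"sleepwake"`: wake vs sleep; `"device"`: the 4-class
#' wake/light/deep/REM scheme).
#'
#' @param cohort an aligned [paired_cohort()].
#' @param scheme `"sleepwake"` or `"device"`.
#' @return An object of class `"confusion_table"`: `counts` (pooled K x K
#'   integer matrix), `per_participant` (named list of per-participant
#'   matrices summing to `counts`), `class_order`, `n_epochs` (unmasked
#'   pooled total) and `n_masked`.
#' @export
confusion_table <- function(cohort, scheme = c("sleepwake", "device")) {
  stopifnot(inherits(cohort, "paired_cohort"))
  scheme <- match.arg(scheme)
  if (length(cohort$records) == 0) stopf("empty cohort")
  lev <- stage_schemes[[scheme]]
  to_scheme <- function(h) {
    if (scheme == "sleepwake") return(to_sleep_wake(h))
    if (h$scheme == "reference") return(suppressWarnings(collapse_stages(h)))
    if (h$scheme != "device") stopf("cannot lift a '%s' hypnogram to 4 classes", h$scheme)
    h
  }
  per <- list()
  n_masked <- 0L
  for (id in names(cohort$records)) {
    r <- cohort$records[[id]]
    d <- to_scheme(r$device)
    f <- to_scheme(r$reference)
    if (n_epochs(d) != n_epochs(f)) {
      stopf("participant '%s' is not aligned (%d vs %d epochs)",
            id, n_epochs(d), n_epochs(f))
    }
    ok <- !d$missing & !f$missing
    n_masked <- n_masked + sum(!ok)
    per[[id]] <- unclass(table(factor(f$labels[ok], levels = lev),
                               factor(d$labels[ok], levels = lev)))
  }
  counts <- Reduce(`+`, per)
  structure(list(counts = counts, per_participant = per, class_order = lev,
                 n_epochs = sum(counts), n_masked = n_masked),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> %d participants, %d epochs (%d masked)\n",
              length(x$per_participant), x$n_epochs, x$n_masked))
  cat("rows = reference, columns = device\n")
  print(x$counts)
  invisible(x)
}

# TP/FP/TN/FN of a 2-class table with the stated positive class.
cells_2x2 <- function(m, positive, class_order) {
  neg <- setdiff(class_order, positive)
  list(tp = m[positive, positive], fn = m[positive, neg],
       fp = m[neg, positive], tn = m[neg, neg])
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

rates_from_tables <- function(per, positive, class_order) {
  m <- Reduce(`+`, per)
  z <- cells_2x2(m, positive, class_order)
  c(sensitivity = safe_ratio(z$tp, z$tp + z$fn),
    specificity = safe_ratio(z$tn, z$tn + z$fp),
    ppv = safe_ratio(z$tp, z$tp + z$fp),
    npv = safe_ratio(z$tn, z$tn + z$fn))
}

#' Sensitivity, specificity, PPV and NPV with cluster-bootstrap CIs
#'
#' Point estimates are computed on the pooled epoch counts (sleep as the
#' positive class by default: sensitivity = TP/(TP+FN) over reference sleep
#' epochs, specificity = TN/(TN+FP) over reference wake epochs); intervals
#' come from resampling participants via [cluster_bootstrap()].  A rate
#' whose denominator is zero is reported as undefined with its reason, not
#' as 0.
#'
#' @param ct a 2-class [confusion_table()].
#' @param positive the positive class (default `"SLEEP"`).
#' @param B,seed bootstrap replicates and seed.
#' @return An object of class `"binary_metrics"`: named list of
#'   [metric_ci()] for `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
binary_metrics <- function(ct, positive = "SLEEP", B = 1000L, seed = 1L) {
  stopifnot(inherits(ct, "confusion_table"))
  if (length(ct$class_order) != 2) stopf("binary_metrics needs a 2-class table")
  if (!positive %in% ct$class_order) stopf("unknown positive class '%s'", positive)
  bt <- cluster_bootstrap(ct$per_participant, rates_from_tables, B = B,
                          seed = seed, positive = positive,
                          class_order = ct$class_order)
  reasons <- c(sensitivity = "no positive reference epochs",
               specificity = "no negative reference epochs",
               ppv = "no positive device epochs",
               npv = "no negative device epochs")
  out <- lapply(names(reasons), function(nm) boot_metric(bt, nm, reasons[[nm]]))
  names(out) <- names(reasons)
  structure(out, class = "binary_metrics", positive = positive)
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("sleep/wake discrimination (positive class: %s)\n",
              attr(x, "positive")))
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Cohen's kappa of one K x K count matrix; NA when chance agreement is 1
# (single-class degenerate table) or the table is empty.
kappa_from_table <- function(m) {
  n <- sum(m)
  if (n == 0) return(NA_real_)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - pe < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

average_kappa <- function(per) {
  ks <- vapply(per, kappa_from_table, 0)
  if (all(is.na(ks))) return(NA_real_)
  mean(ks, na.rm = TRUE)
}

#' Cohen's kappa with cluster-bootstrap CI
#'
#' Chance-corrected agreement for a K-class confusion table.  `"pooled"`
#' computes kappa once on the pooled epoch counts; `"average"` computes
#' kappa per participant and takes the arithmetic mean across participants,
#' excluding (and counting) participants for whom kappa is undefined
#' (single-class nights).
#'
#' @param ct a [confusion_table()].
#' @param mode `"pooled"` or `"average"`.
#' @param B,seed bootstrap replicates and seed.
#' @return A [metric_ci()] with attribute `n_excluded` (average mode).
#' @export
cohens_kappa <- function(ct, mode = c("pooled", "average"), B = 1000L,
                         seed = 1L) {
  stopifnot(inherits(ct, "confusion_table"))
  mode <- match.arg(mode)
  stat <- if (mode == "pooled") {
    function(per) c(kappa = kappa_from_table(Reduce(`+`, per)))
  } else {
    function(per) c(kappa = average_kappa(per))
  }
  bt <- cluster_bootstrap(ct$per_participant, stat, B = B, seed = seed)
  out <- boot_metric(bt, "kappa", "kappa undefined (degenerate table)")
  if (mode == "average") {
    ks <- vapply(ct$per_participant, kappa_from_table, 0)
    attr(out, "n_excluded") <- sum(is.na(ks))
  }
  attr(out, "mode") <- mode
  out
}

# one-vs-rest reduction of a K x K matrix; class_order c(stage, "other")
dichotomize_table <- function(m, stage) {
  k <- match(stage, rownames(m))
  out <- matrix(c(m[k, k], sum(m[k, -k]), sum(m[-k, k]), sum(m[-k, -k])),
                2, 2, byrow = TRUE,
                dimnames = list(c(stage, "other"), c(stage, "other")))
  out
}

per_stage_stat <- function(per, stages) {
  pooled <- Reduce(`+`, per)
  out <- c(overall.kappa = average_kappa(per),
           overall.accuracy = sum(diag(pooled)) / sum(pooled))
  for (s in stages) {
    per2 <- lapply(per, dichotomize_table, stage = s)
    m2 <- Reduce(`+`, per2)
    z <- cells_2x2(m2, s, c(s, "other"))
    v <- c(average_kappa(per2),
           (z$tp + z$tn) / sum(m2),
           safe_ratio(z$tp, z$tp + z$fp),
           safe_ratio(z$tp, z$tp + z$fn))
    names(v) <- paste(s, c("kappa", "accuracy", "ppv", "sensitivity"), sep = ".")
    out <- c(out, v)
  }
  out
}

#' Per-stage agreement metrics (one-vs-rest) with cluster-bootstrap CIs
#'
#' For each of the four device stages, the 4-class epoch data are
#' dichotomized to that stage against all others; kappa is computed by the
#' average method (per-participant kappa, averaged, undefined participants
#' excluded and counted) while accuracy, PPV and sensitivity are pooled
#' rates.  The overall row carries the 4-class kappa (average method) and
#' pooled accuracy; PPV/sensitivity are not applicable there.
#'
#' @param cohort an aligned [paired_cohort()] with 4- or 5-class series.
#' @param B,seed bootstrap replicates and seed.
#' @return An object of class `"per_stage_metrics"`: list with `table`
#'   (rows overall/WAKE/LIGHT/DEEP/REM, entries [metric_ci()]) and
#'   `n_excluded` per row.
#' @export
per_stage_metrics <- function(cohort, B = 1000L, seed = 1L) {
  ct <- confusion_table(cohort, scheme = "device")
  stages <- ct$class_order
  bt <- cluster_bootstrap(ct$per_participant, per_stage_stat, B = B,
                          seed = seed, stages = stages)
  rows <- c("overall", stages)
  cols <- c("kappa", "accuracy", "ppv", "sensitivity")
  tab <- list()
  n_excluded <- integer()
  for (rw in rows) {
    tab[[rw]] <- list()
    for (cl in cols) {
      nm <- paste(rw, cl, sep = ".")
      tab[[rw]][[cl]] <- if (nm %in% names(bt$estimate)) {
        boot_metric(bt, nm, "undefined on the observed data")
      } else {
        metric_ci(NA_real_, reason = "not applicable")
      }
    }
    per_s <- if (rw == "overall") ct$per_participant else
      lapply(ct$per_participant, dichotomize_table, stage = rw)
    n_excluded[[rw]] <- sum(is.na(vapply(per_s, kappa_from_table, 0)))
  }
  structure(list(table = tab, n_excluded = n_excluded, confusion = ct),
            class = "per_stage_metrics")
}

#' @export
print.per_stage_metrics <- function(x, ...) {
  cat("per-stage agreement (one-vs-rest; kappa by the average method)\n")
  cols <- c("kappa", "accuracy", "ppv", "sensitivity")
  wide <- sapply(cols, function(cl)
    vapply(x$table, function(rw) {
      v <- rw[[cl]]
      if (is.na(v$estimate)) "NA" else format(v)
    }, ""))
  print(noquote(wide))
  if (any(x$n_excluded > 0)) {
    cat("participants excluded from average kappa:",
        paste(sprintf("%s=%d", names(x$n_excluded), x$n_excluded)[x$n_excluded > 0],
              collapse = ", "), "\n")
  }
  invisible(x)
}
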