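# Overnight sleep-measure derivation from a single hypnogram.

#' Sleep onset epoch
#'
#' Index (0-based, on the lights-off epoch grid) of the epoch at which sleep
#' onset occurs.  The default rule takes the first epoch scored as any sleep
#' stage, the convention most device-validation studies use;
#' `"first_k_consecutive"` instead requires `k` consecutive sleep epochs and
#' returns the first of them.
#'
#' @param h a [hypnogram()] (2-, 4- or 5-class).
#' @param rule onset rule.
#' @param k run length for `"first_k_consecutive"` (default 3, i.e. 1.5 min
#'   of 30-s epochs).
#' @return Integer epoch index, or `NA` if the night contains no sleep (no
#'   qualifying run).
#' @examples
#' sleep_onset_epoch(hypnogram(c("WAKE", "WAKE", "LIGHT"), scheme = "device"))
#' @export
sleep_onset_epoch <- function(h, rule = c("first_epoch", "first_k_consecutive"),
                              k = 3L) {
  stopifnot(inherits(h, "hypnogram"))
  rule <- match.arg(rule)
  asleep <- !h$missing & !(h$labels %in% wake_labels)
  if (!any(asleep)) return(NA_integer_)
  if (rule == "first_epoch") return(which(asleep)[1] - 1L)
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_integer_)
  as.integer(ends[hit[1]] - r$lengths[hit[1]])
}

#' Overnight sleep measures for one night
#'
#' Derives the standard overnight summaries from a hypnogram over its
#' lights-off to lights-on window: total sleep time (TST), sleep onset
#' latency (SOL), wake after sleep onset (WASO), sleep efficiency
#' (SE = 100 TST / TIB with TIB the in-bed duration), number of awakenings
#' (NAWK = maximal contiguous wake runs at or after onset), and per-stage
#' durations for 4-class input.  Default conventions: onset is the first
#' sleep epoch; terminal wake before lights-on counts toward WASO and NAWK,
#' which preserves the identity SOL + TST + WASO = TIB; awakenings of any
#' length (>= 1 epoch) count.  Each is configurable.  An all-wake night
#' yields TST = 0, SOL = TIB, WASO = 0, SE = 0, NAWK = 0.
#'
#' Missing epochs contribute to no numerator (they are neither sleep nor
#' wake); the conservation identity therefore holds exactly only for
#' complete nights.
#'
#' @param h a [hypnogram()] (2- or 4-class; 5-class input is collapsed
#'   first).
#' @param onset_rule,k passed to [sleep_onset_epoch()].
#' @param terminal_wake `"include"` (default) counts wake between the last
#'   sleep epoch and lights-on toward WASO/NAWK; `"exclude"` stops the night
#'   at the final awakening.
#' @param min_awakening_epochs shortest wake run counted as an awakening.
#' @return An object of class `"sleep_measures"`: list with `tst_min`,
#'   `waso_min`, `se_pct`, `sol_min`, `nawk`, `light_min`, `deep_min`,
#'   `rem_min` (the stage durations are `NA` for 2-class input) and
#'   `tib_min`.
#' @examples
#' h <- hypnogram(c("WAKE","WAKE","LIGHT","LIGHT","WAKE",
#'                  "DEEP","DEEP","REM","WAKE","WAKE"), scheme = "device")
#' unlist(sleep_measures(h))
#' @export
sleep_measures <- function(h, onset_rule = c("first_epoch", "first_k_consecutive"),
                           k = 3L, terminal_wake = c("include", "exclude"),
                           min_awakening_epochs = 1L) {
  stopifnot(inherits(h, "hypnogram"))
  onset_rule <- match.arg(onset_rule)
  terminal_wake <- match.arg(terminal_wake)
  if (n_epochs(h) == 0) stopf("empty window")
  if (h$scheme == "reference") h <- collapse_stages(h)
  epm <- h$epoch_seconds / 60
  n <- n_epochs(h)
  tib <- (h$lights_on_s - h$lights_off_s) / 60
  wake <- !h$missing & h$labels %in% wake_labels
  sleep <- !h$missing & !(h$labels %in% wake_labels)
  stage_min <- function(s) if (h$scheme == "device") sum(!h$missing & h$labels == s) * epm else NA_real_
  onset <- sleep_onset_epoch(h, rule = onset_rule, k = k)
  if (is.na(onset)) {
    m <- list(tst_min = 0, waso_min = 0, se_pct = 0, sol_min = tib, nawk = 0L,
              light_min = stage_min("LIGHT"), deep_min = stage_min("DEEP"),
              rem_min = stage_min("REM"), tib_min = tib)
    return(structure(m, class = "sleep_measures"))
  }
  post <- seq.int(onset + 1L, n)   # 1-based indices at/after onset
  wake_post <- wake[post]
  if (terminal_wake == "exclude" && length(wake_post) && wake_post[length(wake_post)]) {
    r <- rle(wake_post)
    keep <- length(wake_post) - r$lengths[length(r$lengths)]
    wake_post <- wake_post[seq_len(keep)]
  }
  runs <- rle(wake_post)
  nawk <- sum(runs$values & runs$lengths >= min_awakening_epochs)
  tst <- sum(sleep) * epm
  waso <- sum(wake_post) * epm
  sol <- onset * epm
  structure(list(tst_min = tst, waso_min = waso,
                 se_pct = 100 * tst / tib, sol_min = sol, nawk = as.integer(nawk),
                 light_min = stage_min("LIGHT"), deep_min = stage_min("DEEP"),
                 rem_min = stage_min("REM"), tib_min = tib),
            class = "sleep_measures")
}

#' @export
print.sleep_measures <- function(x, ...) {
  cat(sprintf(paste0("overnight sleep measures (TIB %.1f min):\n",
                     "  TST %.1f  SOL %.1f  WASO %.1f min,  SE %.1f%%,  NAWK %d\n"),
              x$tib_min, x$tst_min, x$sol_min, x$waso_min, x$se_pct, x$nawk))
  if (!is.na(x$light_min)) {
    cat(sprintf("  light %.1f  deep %.1f  REM %.1f min\n",
                x$light_min, x$deep_min, x$rem_min))
  }
  invisible(x)
}

measure_names <- c("tst_min", "waso_min", "se_pct", "sol_min", "nawk",
                   "light_min", "deep_min", "rem_min", "tib_min")

#' Per-participant paired sleep measures for a cohort
#'
#' Runs [sleep_measures()] on the device series and on the collapsed
#' reference series of every (aligned) record.
#'
#' @param cohort a [paired_cohort()] (alignment recommended first; see
#'   [align_cohort()]).
#' @param ... measure conventions passed to [sleep_measures()].
#' @return A data frame with one row per participant per source (`source`
#'   is `"device"` or `"reference"`) and the measure columns.
#' @export
cohort_measures <- function(cohort, ...) {
  stopifnot(inherits(cohort, "paired_cohort"))
  rows <- list()
  for (id in names(cohort$records)) {
    r <- cohort$records[[id]]
    ref <- if (r$reference$scheme == "reference") {
      suppressWarnings(collapse_stages(r$reference))
    } else r$reference
    for (src in c("device", "reference")) {
      h <- if (src == "device") r$device else ref
      m <- tryCatch(sleep_measures(h, ...), error = function(e) {
        stopf("participant '%s' (%s): %s", id, src, conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant_id = id, source = src, stringsAsFactors = FALSE),
        as.data.frame(unclass(m)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
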