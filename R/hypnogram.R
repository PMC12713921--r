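# Hypnogram container, stage schemes, I/O and epoch-grid alignment.

#' Stage vocabularies
#'
#' Controlled stage vocabularies used throughout the package.  The reference
#' (polysomnography) scheme scores each epoch as wake (`W`), `N1`, `N2`, `N3`
#' or REM (`R`); the device scheme emits `WAKE`, `LIGHT`, `DEEP`, `REM`;
#' the sleep/wake scheme dichotomizes to `WAKE` vs `SLEEP`.  Collapsing the
#' reference scheme maps `W -> WAKE`, `N1 -> LIGHT`, `N2 -> LIGHT`,
#' `N3 -> DEEP`, `R -> REM`.
#'
#' @format A named list of character vectors, one per scheme.
#' @export
stage_schemes <- list(
  reference = c("W", "N1", "N2", "N3", "R"),
  device    = c("WAKE", "LIGHT", "DEEP", "REM"),
  sleepwake = c("WAKE", "SLEEP")
)

# reference -> device collapse map (total on the reference scheme)
collapse_map <- c(W = "WAKE", N1 = "LIGHT", N2 = "LIGHT", N3 = "DEEP", R = "REM")

wake_labels <- c("W", "WAKE")

#' Construct a hypnogram
#'
#' A hypnogram is one participant-night of epoch-gridded stage labels over
#' the in-bed (lights-off to lights-on) window.  The epoch grid is 0-based
#' and half-open: epoch `i` covers
#' `[lights_off_s + i * epoch_seconds, lights_off_s + (i + 1) * epoch_seconds)`.
#'
#' @param labels character vector of stage labels, one per epoch; `NA` marks
#'   a missing epoch.
#' @param scheme one of `"reference"`, `"device"`, `"sleepwake"`.
#' @param epoch_seconds epoch duration in seconds (default 30).
#' @param lights_off_s start of the in-bed window, seconds (default 0).
#' @param lights_on_s exclusive end of the window, seconds; defaults to
#'   `lights_off_s + length(labels) * epoch_seconds`.
#' @param participant_id participant identifier.
#' @return An object of class `"hypnogram"`.
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "R"), scheme = "reference")
#' n_epochs(h)
#' @export
hypnogram <- function(labels, scheme = c("reference", "device", "sleepwake"),
                      epoch_seconds = 30, lights_off_s = 0,
                      lights_on_s = NULL, participant_id = "p1") {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  if (epoch_seconds <= 0) stopf("epoch_seconds must be positive")
  if (is.null(lights_on_s)) {
    lights_on_s <- lights_off_s + length(labels) * epoch_seconds
  }
  n_win <- (lights_on_s - lights_off_s) / epoch_seconds
  if (abs(n_win - round(n_win)) > 1e-9) {
    stopf("window (%s, %s) is not an integer number of %s-s epochs",
          lights_off_s, lights_on_s, epoch_seconds)
  }
  n_win <- as.integer(round(n_win))
  if (length(labels) != n_win) {
    stopf("%d labels but the window holds %d epochs", length(labels), n_win)
  }
  known <- stage_schemes[[scheme]]
  bad <- !is.na(labels) & !(labels %in% known)
  if (any(bad)) {
    stopf("label(s) outside the '%s' scheme at epoch(s) %s: %s", scheme,
          paste(which(bad)[seq_len(min(3, sum(bad)))] - 1L, collapse = ", "),
          paste(unique(labels[bad]), collapse = ", "))
  }
  structure(
    list(participant_id = as.character(participant_id),
         epoch_seconds = epoch_seconds,
         lights_off_s = lights_off_s,
         lights_on_s = lights_on_s,
         labels = labels,
         missing = is.na(labels),
         scheme = scheme),
    class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %s: %d x %gs epochs [%g, %g) s, scheme '%s'",
              x$participant_id, n_epochs(x), x$epoch_seconds,
              x$lights_off_s, x$lights_on_s, x$scheme))
  if (any(x$missing)) cat(sprintf(", %d missing", sum(x$missing)))
  cat("\n")
  tb <- table(factor(x$labels, levels = stage_schemes[[x$scheme]]))
  print(tb)
  invisible(x)
}

#' Number of epochs in a hypnogram window
#' @param h a [hypnogram()].
#' @return Integer epoch count.
#' @export
n_epochs <- function(h) length(h$labels)

#' Read a hypnogram from an epoch CSV file
#'
#' The expected format has a header
#' `participant_id,epoch_index,onset_s,stage` with `onset_s` relative to
#' lights-off, one row per 30-s (or other uniform-length) epoch, and the
#' missing sentinel `NA` in the `stage` column.  Labels outside the declared
#' scheme are an error; a user-supplied `remap` table translates label
#' dialects (e.g. `c(N4 = "N3", REM = "R")`) before validation.
#'
#' @param path path to the epoch CSV.
#' @param scheme stage scheme of the file (see [stage_schemes]).
#' @param lights_off_s,lights_on_s analysis window in seconds relative to the
#'   file's time origin; defaults to the file's own extent.  Epochs outside
#'   the window are dropped (a message reports the count).
#' @param remap optional named character vector mapping file labels to scheme
#'   labels.
#' @param epoch_seconds epoch length used when the file holds a single row
#'   (otherwise inferred from the onset grid).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, scheme = c("reference", "device", "sleepwake"),
                           lights_off_s = NULL, lights_on_s = NULL,
                           remap = NULL, epoch_seconds = 30) {
  scheme <- match.arg(scheme)
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(stage = "character"))
  need <- c("participant_id", "epoch_index", "onset_s", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (nrow(df) == 0) stopf("%s: no epochs", path)
  df <- df[order(df$onset_s), , drop = FALSE]
  if (nrow(df) > 1) {
    steps <- diff(df$onset_s)
    if (any(abs(steps - steps[1]) > 1e-9)) {
      bad <- which(abs(steps - steps[1]) > 1e-9)[1] + 1L
      stopf("%s: non-uniform epoch grid at row %d", path, bad)
    }
    epoch_seconds <- steps[1]
  }
  stage <- df$stage
  stage[stage %in% c("", "NA")] <- NA_character_
  if (!is.null(remap)) {
    hit <- !is.na(stage) & stage %in% names(remap)
    stage[hit] <- unname(remap[stage[hit]])
  }
  known <- stage_schemes[[scheme]]
  bad <- !is.na(stage) & !(stage %in% known)
  if (any(bad)) {
    stopf("%s: label '%s' outside the '%s' scheme at row %d",
          path, stage[which(bad)[1]], scheme, which(bad)[1])
  }
  lights_off_s <- lights_off_s %||% min(df$onset_s)
  lights_on_s <- lights_on_s %||% (max(df$onset_s) + epoch_seconds)
  inside <- df$onset_s >= lights_off_s & df$onset_s < lights_on_s
  if (any(!inside)) {
    message(sprintf("%s: dropped %d epoch(s) outside [%g, %g) s",
                    basename(path), sum(!inside), lights_off_s, lights_on_s))
  }
  df <- df[inside, , drop = FALSE]
  stage <- stage[inside]
  # the retained onsets must tile the window exactly
  expect_on <- seq(lights_off_s, lights_on_s - epoch_seconds, by = epoch_seconds)
  if (nrow(df) != length(expect_on) || any(abs(df$onset_s - expect_on) > 1e-9)) {
    stopf("%s: epoch onsets do not tile the analysis window", path)
  }
  hypnogram(stage, scheme = scheme, epoch_seconds = epoch_seconds,
            lights_off_s = lights_off_s, lights_on_s = lights_on_s,
            participant_id = df$participant_id[1])
}

#' Write a hypnogram to an epoch CSV file
#'
#' Writes the format read by [read_hypnogram()] (missing epochs get the
#' `NA` sentinel).
#'
#' @param h a [hypnogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  n <- n_epochs(h)
  df <- data.frame(
    participant_id = h$participant_id,
    epoch_index = seq_len(n) - 1L,
    onset_s = h$lights_off_s + (seq_len(n) - 1L) * h$epoch_seconds,
    stage = ifelse(h$missing, "NA", h$labels),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse a reference hypnogram to the 4-class device scheme
#'
#' Applies the stage collapse `W -> WAKE`, `N1/N2 -> LIGHT`, `N3 -> DEEP`,
#' `R -> REM`.  Length, window and missingness are unchanged.  An
#' already-collapsed (device-scheme) input is returned unchanged with a
#' warning.
#'
#' @param h a [hypnogram()] in the reference scheme.
#' @return A device-scheme [hypnogram()].
#' @examples
#' h <- hypnogram(c("W", "N1", "N2", "N3", "R"), scheme = "reference")
#' collapse_stages(h)$labels
#' @export
collapse_stages <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (h$scheme == "device") {
    warnf("hypnogram already uses the device scheme; returning unchanged")
    return(h)
  }
  if (h$scheme != "reference") {
    stopf("cannot collapse a '%s'-scheme hypnogram", h$scheme)
  }
  lab <- unname(collapse_map[h$labels])
  hypnogram(lab, scheme = "device", epoch_seconds = h$epoch_seconds,
            lights_off_s = h$lights_off_s, lights_on_s = h$lights_on_s,
            participant_id = h$participant_id)
}

#' Dichotomize a hypnogram to sleep vs wake
#'
#' Every non-wake label becomes `SLEEP`; `W`/`WAKE` become `WAKE`.  Sleep is
#' the positive class in downstream discrimination metrics.
#'
#' @param h a [hypnogram()] in any scheme.
#' @return A sleep/wake [hypnogram()].
#' @export
to_sleep_wake <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (h$scheme == "sleepwake") return(h)
  lab <- ifelse(is.na(h$labels), NA_character_,
                ifelse(h$labels %in% wake_labels, "WAKE", "SLEEP"))
  hypnogram(lab, scheme = "sleepwake", epoch_seconds = h$epoch_seconds,
            lights_off_s = h$lights_off_s, lights_on_s = h$lights_on_s,
            participant_id = h$participant_id)
}

#' Align a device/reference hypnogram pair on a common epoch grid
#'
#' Both hypnograms are truncated to the overlap of their in-bed windows, and
#' epochs missing on either side are masked on both, so that downstream
#' epoch statistics are pairwise complete.
#'
#' @param device,reference [hypnogram()]s for the same participant with the
#'   same epoch length.
#' @return A list with elements `device`, `reference` (aligned hypnograms)
#'   and `report` (class `"alignment_report"`: epochs dropped from each side
#'   and the number of jointly masked epochs).
#' @export
align_pair <- function(device, reference) {
  stopifnot(inherits(device, "hypnogram"), inherits(reference, "hypnogram"))
  if (device$participant_id != reference$participant_id) {
    stopf("participant mismatch: '%s' vs '%s'",
          device$participant_id, reference$participant_id)
  }
  if (abs(device$epoch_seconds - reference$epoch_seconds) > 1e-9) {
    stopf("epoch lengths differ (%g vs %g s)",
          device$epoch_seconds, reference$epoch_seconds)
  }
  es <- device$epoch_seconds
  off <- max(device$lights_off_s, reference$lights_off_s)
  on <- min(device$lights_on_s, reference$lights_on_s)
  if (on - off < es) stopf("windows of '%s' do not overlap", device$participant_id)
  take <- function(h) {
    i0 <- as.integer(round((off - h$lights_off_s) / es))
    n <- as.integer(round((on - off) / es))
    lab <- h$labels[(i0 + 1):(i0 + n)]
    hypnogram(lab, scheme = h$scheme, epoch_seconds = es,
              lights_off_s = off, lights_on_s = on,
              participant_id = h$participant_id)
  }
  d <- take(device)
  r <- take(reference)
  joint <- d$missing | r$missing
  newly_masked <- sum(joint) - sum(d$missing & r$missing)
  d$labels[joint] <- NA_character_
  r$labels[joint] <- NA_character_
  d$missing <- joint
  r$missing <- joint
  report <- structure(
    list(participant_id = d$participant_id,
         dropped_device = n_epochs(device) - n_epochs(d),
         dropped_reference = n_epochs(reference) - n_epochs(r),
         masked = sum(joint),
         newly_masked = newly_masked),
    class = "alignment_report")
  list(device = d, reference = r, report = report)
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment> %s: dropped %d (device) / %d (reference), %d masked\n",
              x$participant_id, x$dropped_device, x$dropped_reference, x$masked))
  invisible(x)
}
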