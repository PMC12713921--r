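# Paired device/reference cohorts: container, alignment, file I/O.

#' Construct a paired device/reference cohort
#'
#' @param records named list (names = participant ids) of lists with
#'   elements `device` and `reference`, each a [hypnogram()].
#' @param covariates data frame with one row per participant and at least a
#'   `participant_id` column; typical columns are `age`, `sex`, `bmi`,
#'   `skin_tone`, `arm_hair_density`, with arbitrary extras carried along.
#' @param validate skip structural checks when `FALSE` (internal fast path).
#' @return An object of class `"paired_cohort"`.
#' @export
paired_cohort <- function(records, covariates = NULL, validate = TRUE) {
  if (is.null(names(records)) || any(names(records) == "")) {
    names(records) <- vapply(records, function(r) r$reference$participant_id, "")
  }
  if (is.null(covariates)) {
    covariates <- data.frame(participant_id = names(records),
                             stringsAsFactors = FALSE)
  }
  if (validate) {
    if (length(records) == 0) stopf("empty cohort")
    es <- vapply(records, function(r) r$reference$epoch_seconds, 0)
    if (any(abs(es - es[1]) > 1e-9)) stopf("epoch_seconds differ across the cohort")
    for (id in names(records)) {
      r <- records[[id]]
      if (r$device$participant_id != id || r$reference$participant_id != id) {
        stopf("record '%s' holds hypnograms for another participant", id)
      }
      if (abs(r$device$epoch_seconds - r$reference$epoch_seconds) > 1e-9) {
        stopf("record '%s': device/reference epoch lengths differ", id)
      }
    }
    if (!"participant_id" %in% names(covariates)) {
      stopf("covariates need a participant_id column")
    }
    if (!setequal(covariates$participant_id, names(records)) ||
        anyDuplicated(covariates$participant_id)) {
      stopf("covariates must have exactly one row per participant in records")
    }
  }
  covariates <- covariates[match(names(records), covariates$participant_id), ,
                           drop = FALSE]
  rownames(covariates) <- NULL
  structure(list(records = records, covariates = covariates),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  ne <- vapply(x$records, function(r) n_epochs(r$reference), 0L)
  cat(sprintf("<paired_cohort> %d participants, %s epochs/night, %gs epochs\n",
              length(x$records),
              if (length(unique(ne)) == 1) unique(ne) else
                sprintf("%d-%d", min(ne), max(ne)),
              x$records[[1]]$reference$epoch_seconds))
  cat("covariates:", paste(setdiff(names(x$covariates), "participant_id"),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Number of participants in a cohort
#' @param c a [paired_cohort()].
#' @return Integer count.
#' @export
n_participants <- function(c) length(c$records)

#' Align every pair of a cohort on common epoch grids
#'
#' Applies [align_pair()] to each record.  Participants whose windows do not
#' overlap (or that otherwise fail alignment) are dropped with their reason
#' recorded.
#'
#' @param cohort a [paired_cohort()].
#' @return The aligned cohort, with attributes `"alignment"` (list of
#'   per-participant [align_pair()] reports) and `"excluded"` (named
#'   character vector of failure reasons, possibly empty).
#' @export
align_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "paired_cohort"))
  reports <- list()
  excluded <- character()
  out <- list()
  for (id in names(cohort$records)) {
    r <- cohort$records[[id]]
    a <- tryCatch(align_pair(r$device, r$reference), error = function(e) e)
    if (inherits(a, "error")) {
      excluded[[id]] <- conditionMessage(a)
    } else {
      out[[id]] <- list(device = a$device, reference = a$reference)
      reports[[id]] <- a$report
    }
  }
  if (length(out) == 0) stopf("alignment excluded every participant")
  cov <- cohort$covariates[cohort$covariates$participant_id %in% names(out), ,
                           drop = FALSE]
  res <- paired_cohort(out, cov)
  attr(res, "alignment") <- reports
  attr(res, "excluded") <- excluded
  res
}

#' Subset a cohort by participant
#' @param x a [paired_cohort()].
#' @param ids participant ids to keep (duplicates allowed: bootstrap use).
#' @param ... ignored.
#' @return A [paired_cohort()].
#' @export
subset_cohort <- function(x, ids, ...) {
  stopifnot(all(ids %in% names(x$records)))
  recs <- x$records[ids]
  if (anyDuplicated(ids)) {
    # bootstrap resample: give clones unique ids so the container stays valid
    names(recs) <- make.unique(ids)
    cov <- x$covariates[match(ids, x$covariates$participant_id), , drop = FALSE]
    cov$participant_id <- names(recs)
    for (i in seq_along(recs)) {
      recs[[i]]$device$participant_id <- names(recs)[i]
      recs[[i]]$reference$participant_id <- names(recs)[i]
    }
    return(paired_cohort(recs, cov, validate = FALSE))
  }
  paired_cohort(recs, x$covariates[match(ids, x$covariates$participant_id), ,
                                   drop = FALSE])
}

#' Write a cohort to epoch CSV files plus a manifest
#'
#' Creates `device/<id>.csv` and `reference/<id>.csv` in [write_hypnogram()]
#' format, and `manifest.csv` with the in-bed window and covariates.  If the
#' cohort carries simulator ground truth it is written as
#' `ground_truth.json`.
#'
#' @param cohort a [paired_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(file.path(dir, "device"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reference"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$records)) {
    write_hypnogram(cohort$records[[id]]$device,
                    file.path(dir, "device", paste0(id, ".csv")))
    write_hypnogram(cohort$records[[id]]$reference,
                    file.path(dir, "reference", paste0(id, ".csv")))
  }
  man <- cohort$covariates
  man$lights_off_s <- vapply(cohort$records[man$participant_id],
                             function(r) r$reference$lights_off_s, 0)
  man$lights_on_s <- vapply(cohort$records[man$participant_id],
                            function(r) r$reference$lights_on_s, 0)
  front <- c("participant_id", "lights_off_s", "lights_on_s")
  man <- man[, c(front, setdiff(names(man), front)), drop = FALSE]
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort from epoch CSV files plus a manifest
#'
#' Counterpart of [write_cohort()].  Device files are read in the device
#' scheme, reference files in the reference scheme; the manifest supplies
#' the analysis window and covariates.
#'
#' @param dir directory holding `device/`, `reference/` and `manifest.csv`,
#'   or `NULL` if the three paths are given explicitly.
#' @param device_dir,reference_dir,manifest explicit paths, overriding `dir`.
#' @param remap optional label remap passed to [read_hypnogram()] for the
#'   reference files.
#' @return A [paired_cohort()].
#' @export
read_cohort <- function(dir = NULL, device_dir = NULL, reference_dir = NULL,
                        manifest = NULL, remap = NULL) {
  if (!is.null(dir)) {
    device_dir <- device_dir %||% file.path(dir, "device")
    reference_dir <- reference_dir %||% file.path(dir, "reference")
    manifest <- manifest %||% file.path(dir, "manifest.csv")
  }
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "lights_off_s", "lights_on_s") %in% names(man))) {
    stopf("manifest needs participant_id, lights_off_s, lights_on_s columns")
  }
  records <- list()
  for (i in seq_len(nrow(man))) {
    id <- as.character(man$participant_id[i])
    records[[id]] <- list(
      device = read_hypnogram(file.path(device_dir, paste0(id, ".csv")),
                              scheme = "device",
                              lights_off_s = man$lights_off_s[i],
                              lights_on_s = man$lights_on_s[i]),
      reference = read_hypnogram(file.path(reference_dir, paste0(id, ".csv")),
                                 scheme = "reference",
                                 lights_off_s = man$lights_off_s[i],
                                 lights_on_s = man$lights_on_s[i],
                                 remap = remap))
  }
  cov <- man[, setdiff(names(man), c("lights_off_s", "lights_on_s")),
             drop = FALSE]
  cov$participant_id <- as.character(cov$participant_id)
  paired_cohort(records, cov)
}
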