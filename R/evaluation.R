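# End-to-end evaluation driver, subgroup stratification and report output.

default_eval_config <- function() {
  list(B = 1000L, seed = 1L,
       onset_rule = "first_epoch", onset_k = 3L,
       terminal_wake = "include", min_awakening_epochs = 1L,
       loa_form = "auto", min_subgroup_n = 10L)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_eval_config(), config %||% list())
  cfg$B <- as.integer(cfg$B)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full device-vs-reference evaluation
#'
#' Executes the whole pipeline on a paired cohort: epoch-grid alignment,
#' stage collapsing, epoch-by-epoch discrimination (sleep vs wake:
#' sensitivity/specificity/PPV/NPV), 4-class and per-stage agreement
#' (Cohen's kappa by the pooled and average methods, accuracy), overnight
#' sleep-measure derivation, and night-level Bland-Altman / count
#' agreement.  All intervals are participant-level cluster-bootstrap
#' percentile CIs.  Participants that fail alignment are dropped and
#' listed in the result.
#'
#' @param cohort a [paired_cohort()], or `NULL` if `config` provides
#'   `device_dir`, `reference_dir` and `manifest` (or `dir`) to read one
#'   with [read_cohort()].
#' @param config named list (or path to a YAML file) overriding the
#'   defaults: `B` (bootstrap replicates, 1000), `seed` (1), `onset_rule`,
#'   `onset_k`, `terminal_wake`, `min_awakening_epochs` (measure
#'   conventions, see [sleep_measures()]), `loa_form` (see
#'   [bland_altman()]), `min_subgroup_n` (10).
#' @return An object of class `"sleep_evaluation"`: components
#'   `sleepwake` ([binary_metrics()] plus the 2-class kappas and
#'   [confusion_table()]), `fourclass` ([per_stage_metrics()]),
#'   `measures_table` (from [cohort_measures()]), `measures`
#'   ([evaluate_measures()]), `exclusions`, `alignment`, `config`,
#'   `version`.
#' @export
run_evaluation <- function(cohort = NULL, config = list()) {
  cfg <- resolve_config(config)
  if (is.null(cohort)) {
    cohort <- read_cohort(dir = cfg$dir %||% NULL,
                          device_dir = cfg$device_dir %||% NULL,
                          reference_dir = cfg$reference_dir %||% NULL,
                          manifest = cfg$manifest %||% NULL)
  }
  stopifnot(inherits(cohort, "paired_cohort"))
  aligned <- align_cohort(cohort)

  ct2 <- confusion_table(aligned, scheme = "sleepwake")
  sleepwake <- list(
    metrics = binary_metrics(ct2, positive = "SLEEP", B = cfg$B,
                             seed = cfg$seed),
    kappa_pooled = cohens_kappa(ct2, "pooled", B = cfg$B, seed = cfg$seed),
    kappa_average = cohens_kappa(ct2, "average", B = cfg$B, seed = cfg$seed),
    confusion = ct2)
  fourclass <- per_stage_metrics(aligned, B = cfg$B, seed = cfg$seed)

  mt <- cohort_measures(aligned, onset_rule = cfg$onset_rule, k = cfg$onset_k,
                        terminal_wake = cfg$terminal_wake,
                        min_awakening_epochs = cfg$min_awakening_epochs)
  measures <- evaluate_measures(mt, B = cfg$B, seed = cfg$seed,
                                loa_form = cfg$loa_form)

  structure(list(sleepwake = sleepwake, fourclass = fourclass,
                 measures_table = mt, measures = measures,
                 n_participants = n_participants(aligned),
                 exclusions = attr(aligned, "excluded"),
                 alignment = attr(aligned, "alignment"),
                 config = cfg,
                 version = as.character(utils::packageVersion("sleepval"))),
            class = "sleep_evaluation")
}

#' @export
print.sleep_evaluation <- function(x, ...) {
  cat(sprintf("== sleep device evaluation (n = %d participants, B = %d, seed = %d) ==\n",
              x$n_participants, x$config$B, x$config$seed))
  if (length(x$exclusions)) {
    cat(sprintf("excluded %d participant(s): %s\n", length(x$exclusions),
                paste(names(x$exclusions), collapse = ", ")))
  }
  cat(sprintf("epochs analyzed: %d (%d masked)\n\n",
              x$sleepwake$confusion$n_epochs, x$sleepwake$confusion$n_masked))
  print(x$sleepwake$metrics)
  cat(sprintf("  kappa (pooled)  %s\n", format(x$sleepwake$kappa_pooled)))
  cat(sprintf("  kappa (average) %s\n\n", format(x$sleepwake$kappa_average)))
  print(x$fourclass)
  cat("\n")
  print(x$measures)
  invisible(x)
}

#' @export
summary.sleep_evaluation <- function(object, ...) print(object)

metric_ci_json <- function(m) {
  list(estimate = m$estimate, ci_low = m$ci_low, ci_high = m$ci_high,
       n_boot = m$n_boot, seed = m$seed, reason = m$reason)
}

#' Write evaluation reports to disk
#'
#' Emits `report.json` (nested metric/CI structure with confusion matrices,
#' resolved configuration, seeds and package version), CSV mirrors of the
#' three report tables (`sleep_wake.csv`, `per_stage.csv`, `measures.csv`),
#' the per-participant measures table, and `exclusions.txt` listing dropped
#' participants and alignment masking.
#'
#' @param x a [run_evaluation()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "sleep_evaluation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- list(
    schema_version = "1.0",
    package_version = x$version,
    config = x$config[setdiff(names(x$config), "covariate_spec")],
    n_participants = x$n_participants,
    sleep_wake = c(lapply(x$sleepwake$metrics, metric_ci_json),
                   list(kappa_pooled = metric_ci_json(x$sleepwake$kappa_pooled),
                        kappa_average = metric_ci_json(x$sleepwake$kappa_average),
                        confusion = unclass(x$sleepwake$confusion$counts))),
    four_class = lapply(x$fourclass$table, function(rw)
      lapply(rw, metric_ci_json)),
    four_class_confusion = unclass(x$fourclass$confusion$counts),
    exclusions = as.list(x$exclusions))
  jsonlite::write_json(rep, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  bm <- x$sleepwake$metrics
  utils::write.csv(data.frame(
    metric = names(bm),
    estimate = vapply(bm, function(m) m$estimate, 0),
    ci_low = vapply(bm, function(m) m$ci_low, 0),
    ci_high = vapply(bm, function(m) m$ci_high, 0)),
    file.path(dir, "sleep_wake.csv"), row.names = FALSE)

  ps <- x$fourclass$table
  rows <- do.call(rbind, lapply(names(ps), function(rw) {
    v <- unlist(lapply(names(ps[[rw]]), function(cl) {
      m <- ps[[rw]][[cl]]
      stats::setNames(c(m$estimate, m$ci_low, m$ci_high),
                      paste(cl, c("est", "lo", "hi"), sep = "_"))
    }))
    cbind(data.frame(stage = rw), as.data.frame(as.list(v)))
  }))
  utils::write.csv(rows, file.path(dir, "per_stage.csv"), row.names = FALSE)

  utils::write.csv(as.data.frame(x$measures), file.path(dir, "measures.csv"),
                   row.names = FALSE)
  utils::write.csv(x$measures_table, file.path(dir, "measures_by_participant.csv"),
                   row.names = FALSE)

  con <- file(file.path(dir, "exclusions.txt"), "w")
  on.exit(close(con))
  if (length(x$exclusions)) {
    writeLines(sprintf("%s\t%s", names(x$exclusions), x$exclusions), con)
  } else {
    writeLines("none", con)
  }
  for (id in names(x$alignment)) {
    a <- x$alignment[[id]]
    if (a$masked > 0 || a$dropped_device > 0 || a$dropped_reference > 0) {
      writeLines(sprintf("%s\tdropped %d/%d epochs, %d masked", id,
                         a$dropped_device, a$dropped_reference, a$masked), con)
    }
  }
  invisible(dir)
}

#' Per-subgroup evaluation
#'
#' Stratifies the cohort by one covariate and runs [run_evaluation()]
#' within each stratum.  Numeric covariates are binned with `breaks`
#' (passed to [cut()]; bins must be exhaustive over the observed values);
#' categorical covariates use their levels.  Strata with fewer than
#' `min_n` participants (default 10) are reported as not evaluated, never
#' silently dropped, and no formal between-group testing is performed.
#'
#' @param cohort a [paired_cohort()].
#' @param variable covariate name (a column of `cohort$covariates`).
#' @param breaks bin edges for a numeric covariate (`NULL` for categorical).
#' @param min_n minimum participants per evaluated stratum.
#' @param config see [run_evaluation()].
#' @return An object of class `"subgroup_evaluation"`: per-stratum list of
#'   either a `"sleep_evaluation"` or a not-evaluated marker with its `n`.
#' @export
subgroup_evaluation <- function(cohort, variable, breaks = NULL, min_n = 10L,
                                config = list()) {
  stopifnot(inherits(cohort, "paired_cohort"))
  cov <- cohort$covariates
  if (!variable %in% names(cov)) {
    stopf("unknown covariate '%s'; available: %s", variable,
          paste(setdiff(names(cov), "participant_id"), collapse = ", "))
  }
  v <- cov[[variable]]
  grp <- if (!is.null(breaks)) {
    if (any(v < min(breaks) | v > max(breaks))) {
      stopf("breaks do not cover the observed range of '%s'", variable)
    }
    cut(v, breaks = breaks, include.lowest = TRUE)
  } else factor(v)
  out <- list()
  for (lv in levels(grp)) {
    ids <- cov$participant_id[!is.na(grp) & grp == lv]
    if (length(ids) < min_n) {
      out[[lv]] <- structure(list(n = length(ids), min_n = min_n,
                                  evaluated = FALSE),
                             class = "subgroup_skipped")
    } else {
      out[[lv]] <- run_evaluation(subset_cohort(cohort, ids), config = config)
    }
  }
  structure(list(variable = variable, groups = out, min_n = min_n),
            class = "subgroup_evaluation")
}

#' @export
print.subgroup_evaluation <- function(x, ...) {
  cat(sprintf("subgroup evaluation by '%s' (min n = %d)\n", x$variable, x$min_n))
  for (lv in names(x$groups)) {
    g <- x$groups[[lv]]
    if (inherits(g, "subgroup_skipped")) {
      cat(sprintf("-- %s: not evaluated (n = %d < %d)\n", lv, g$n, g$min_n))
    } else {
      cat(sprintf("-- %s (n = %d):\n", lv, g$n_participants))
      m <- g$sleepwake$metrics
      cat(sprintf("   sensitivity %s  specificity %s\n",
                  format(m$sensitivity), format(m$specificity)))
    }
  }
  invisible(x)
}
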