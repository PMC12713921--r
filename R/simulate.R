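# Synthetic paired-hypnogram cohort generator with known ground truth.

# Overnight stage-transition structure (30-s epochs, states W/N1/N2/N3/R).
# Hand-tuned so that a default 41-participant, 480-min cohort lands near a
# typical healthy-adult laboratory night: TST ~ 385 min, WASO ~ 63 min,
# SOL ~ 25 min, light ~ 240, deep ~ 63, REM ~ 82 min.
default_transition_matrix <- function() {
  P <- rbind(
    W  = c(W = 0.9770, N1 = 0.0230, N2 = 0.0000, N3 = 0.0000, R = 0.0000),
    N1 = c(W = 0.0100, N1 = 0.8400, N2 = 0.1500, N3 = 0.0000, R = 0.0000),
    N2 = c(W = 0.0035, N1 = 0.0080, N2 = 0.9595, N3 = 0.0160, R = 0.0130),
    N3 = c(W = 0.0025, N1 = 0.0000, N2 = 0.0540, N3 = 0.9435, R = 0.0000),
    R  = c(W = 0.0050, N1 = 0.0100, N2 = 0.0230, N3 = 0.0000, R = 0.9620))
  P
}

# Device error structure over collapsed classes (rows = reference class,
# cols = device class).  Wake row gives specificity 0.70; each sleep row
# leaks 0.03 to WAKE, giving pooled sleep sensitivity 0.97; within-sleep
# confusions echo typical wearable per-stage sensitivities (light ~ 0.81,
# deep ~ 0.77, REM ~ 0.84).
default_confusion_matrix <- function() {
  C <- rbind(
    WAKE  = c(WAKE = 0.70, LIGHT = 0.24, DEEP = 0.02, REM = 0.04),
    LIGHT = c(WAKE = 0.03, LIGHT = 0.81, DEEP = 0.08, REM = 0.08),
    DEEP  = c(WAKE = 0.03, LIGHT = 0.19, DEEP = 0.77, REM = 0.01),
    REM   = c(WAKE = 0.03, LIGHT = 0.12, DEEP = 0.01, REM = 0.84))
  C
}

default_covariate_spec <- function() {
  list(
    age = function(n) round(stats::runif(n, 18, 78)),
    sex = function(n) sample(c("male", "female"), n, replace = TRUE,
                             prob = c(18, 23) / 41),
    bmi = function(n) round(pmin(pmax(stats::rnorm(n, 27, 4.5), 18), 45), 1),
    skin_tone = function(n) sample(paste0("type_", 1:6), n, replace = TRUE),
    arm_hair_density = function(n) sample(c("low", "medium", "high"), n,
                                          replace = TRUE))
}

#' Simulation configuration for a paired-hypnogram cohort
#'
#' Defines the generative model: a first-order 5-state Markov chain
#' (W/N1/N2/N3/R, starting in W at lights-off) for the reference hypnogram,
#' an epoch-independent 4x4 confusion matrix P(device class | collapsed
#' reference class) for the device, and per-participant Dirichlet
#' perturbation of both matrices (each row of each matrix is redrawn as
#' Dirichlet(heterogeneity x row), so the base matrices are the population
#' means and smaller `heterogeneity` means more between-participant
#' spread).  Defaults emulate a 41-participant single-night laboratory
#' cohort of healthy adults on a 480-min in-bed window, with device errors
#' dominated by wake-to-sleep confusion (pooled sleep sensitivity 0.97,
#' wake specificity 0.70).
#'
#' @param n_participants cohort size (default 41).
#' @param tib_epochs epochs per night (default 960 = 8 h of 30-s epochs).
#' @param epoch_seconds epoch length in seconds (default 30).
#' @param transition_matrix 5x5 row-stochastic matrix over W/N1/N2/N3/R.
#' @param initial_state starting stage at lights-off (default `"W"`).
#' @param confusion_matrix 4x4 row-stochastic matrix over
#'   WAKE/LIGHT/DEEP/REM.
#' @param heterogeneity Dirichlet concentration for per-participant matrix
#'   perturbation; `Inf` disables heterogeneity.
#' @param covariate_spec named list of functions `n -> vector` generating
#'   participant covariates.
#' @param error_persistence probability that the device repeats its previous
#'   epoch's label instead of drawing fresh (temporal error clustering);
#'   default 0 keeps errors epoch-independent so ground-truth operating
#'   characteristics stay analytic.
#' @param subgroup_effect optional `function(covariate_row, confusion_matrix)`
#'   returning a modified confusion matrix, used to inject performance
#'   differences by subgroup.
#' @param seed RNG seed; fully determines the cohort.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 41L, tib_epochs = 960L,
                       epoch_seconds = 30,
                       transition_matrix = default_transition_matrix(),
                       initial_state = "W",
                       confusion_matrix = default_confusion_matrix(),
                       heterogeneity = 400,
                       covariate_spec = default_covariate_spec(),
                       error_persistence = 0,
                       subgroup_effect = NULL,
                       seed = 1L) {
  check_stochastic <- function(M, states, what) {
    if (!all(dim(M) == length(states)) ||
        !identical(rownames(M), states) || !identical(colnames(M), states)) {
      stopf("%s must be %dx%d with rows/cols %s", what, length(states),
            length(states), paste(states, collapse = "/"))
    }
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-12)) {
      stopf("%s rows must be nonnegative and sum to 1 within 1e-12", what)
    }
  }
  check_stochastic(transition_matrix, stage_schemes$reference, "transition_matrix")
  check_stochastic(confusion_matrix, stage_schemes$device, "confusion_matrix")
  stopifnot(n_participants >= 1, tib_epochs >= 1, epoch_seconds > 0,
            initial_state %in% stage_schemes$reference,
            error_persistence >= 0, error_persistence < 1,
            heterogeneity > 0)
  structure(list(n_participants = as.integer(n_participants),
                 tib_epochs = as.integer(tib_epochs),
                 epoch_seconds = epoch_seconds,
                 transition_matrix = transition_matrix,
                 initial_state = initial_state,
                 confusion_matrix = confusion_matrix,
                 heterogeneity = heterogeneity,
                 covariate_spec = covariate_spec,
                 error_persistence = error_persistence,
                 subgroup_effect = subgroup_effect,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d participants, %d x %gs epochs ",
                     "(%.0f min in bed), heterogeneity %s, seed %d\n"),
              x$n_participants, x$tib_epochs, x$epoch_seconds,
              x$tib_epochs * x$epoch_seconds / 60,
              format(x$heterogeneity), x$seed))
  invisible(x)
}

rdirichlet_row <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) return(alpha / sum(alpha))   # degenerate guard
  g / sum(g)
}

perturb_matrix <- function(M, conc) {
  if (!is.finite(conc)) return(M)
  out <- M
  for (i in seq_len(nrow(M))) out[i, ] <- rdirichlet_row(conc * M[i, ])
  out
}

# Per-participant matrices, deterministic in (cfg$seed, participant).
participant_params <- function(cfg, participant) {
  with_seed(mix_seed(cfg$seed, 3L * participant + 1L), {
    P <- perturb_matrix(cfg$transition_matrix, cfg$heterogeneity)
    C <- perturb_matrix(cfg$confusion_matrix, cfg$heterogeneity)
    list(transition = P, confusion = C)
  })
}

simulate_chain <- function(P, n, start) {
  states <- rownames(P)
  cum <- apply(P, 1, cumsum)       # column s = cumulative row s
  x <- integer(n)
  x[1] <- match(start, states)
  u <- stats::runif(n)
  for (t in seq_len(n - 1L)) {
    x[t + 1L] <- findInterval(u[t + 1L], cum[, x[t]]) + 1L
  }
  states[x]
}

#' Simulate a reference (polysomnography-like) hypnogram
#'
#' First-order Markov chain over the 5 reference stages, starting in the
#' configured initial stage at lights-off, using the participant's
#' Dirichlet-perturbed transition matrix.  Deterministic in
#' `(cfg$seed, participant)`.  A night that never sleeps is allowed but
#' flagged with a message.
#'
#' @param cfg a [sim_config()].
#' @param participant participant index (1-based).
#' @return A reference-scheme [hypnogram()].
#' @export
simulate_reference <- function(cfg, participant = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  pp <- participant_params(cfg, participant)
  lab <- with_seed(mix_seed(cfg$seed, 3L * participant + 2L),
                   simulate_chain(pp$transition, cfg$tib_epochs,
                                  cfg$initial_state))
  h <- hypnogram(lab, scheme = "reference", epoch_seconds = cfg$epoch_seconds,
                 participant_id = sprintf("p%02d", participant))
  if (all(lab == "W")) {
    message(sprintf("participant p%02d: all-wake night (TST = 0)", participant))
  }
  h
}

#' Simulate a device hypnogram from a reference night
#'
#' Collapses the reference to the 4-class scheme and draws each device
#' epoch from the confusion row of the reference class (epoch-independent
#' unless `error_persistence > 0`, in which case the device repeats its
#' previous label with that probability).  Deterministic in
#' `(cfg$seed, participant)`.
#'
#' @param reference a reference-scheme [hypnogram()].
#' @param cfg a [sim_config()].
#' @param participant participant index (used for the seed and the
#'   participant's confusion matrix).
#' @param confusion optional confusion matrix overriding the participant's
#'   drawn one (used internally for subgroup effects).
#' @return A device-scheme [hypnogram()].
#' @export
simulate_device <- function(reference, cfg, participant = 1L,
                            confusion = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(reference, "hypnogram"))
  C <- confusion %||% participant_params(cfg, participant)$confusion
  ref4 <- suppressWarnings(collapse_stages(reference))
  classes <- stage_schemes$device
  n <- n_epochs(ref4)
  lab <- with_seed(mix_seed(cfg$seed, 3L * participant + 3L), {
    out <- character(n)
    for (k in classes) {
      idx <- which(ref4$labels == k)
      if (length(idx)) {
        out[idx] <- sample(classes, length(idx), replace = TRUE, prob = C[k, ])
      }
    }
    if (cfg$error_persistence > 0 && n > 1) {
      hold <- stats::runif(n) < cfg$error_persistence
      for (t in 2:n) if (hold[t]) out[t] <- out[t - 1L]
    }
    out[ref4$missing] <- NA_character_
    out
  })
  hypnogram(lab, scheme = "device", epoch_seconds = ref4$epoch_seconds,
            lights_off_s = ref4$lights_off_s, lights_on_s = ref4$lights_on_s,
            participant_id = ref4$participant_id)
}

#' Simulate a full paired cohort with ground truth
#'
#' Generates `n_participants` paired reference/device nights plus
#' covariates.  The returned cohort carries a `"ground_truth"` attribute
#' recording every per-participant transition and confusion matrix and the
#' implied pooled operating characteristics (sleep sensitivity and wake
#' specificity, computed analytically from the confusion matrices weighted
#' by the realized reference stage occupancies), for parameter-recovery
#' studies.
#'
#' @param cfg a [sim_config()].
#' @return A [paired_cohort()] with attribute `"ground_truth"`.
#' @examples
#' cfg <- sim_config(n_participants = 3, tib_epochs = 120, seed = 42)
#' co <- simulate_cohort(cfg)
#' attr(co, "ground_truth")$pooled_sensitivity
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  covs <- with_seed(mix_seed(cfg$seed, 0L), {
    out <- data.frame(participant_id = sprintf("p%02d",
                                               seq_len(cfg$n_participants)),
                      stringsAsFactors = FALSE)
    for (nm in names(cfg$covariate_spec)) {
      out[[nm]] <- cfg$covariate_spec[[nm]](cfg$n_participants)
    }
    out
  })
  records <- list()
  gt_part <- list()
  num_sens <- den_sens <- num_spec <- den_spec <- 0
  for (i in seq_len(cfg$n_participants)) {
    pp <- participant_params(cfg, i)
    C <- pp$confusion
    if (!is.null(cfg$subgroup_effect)) {
      C <- cfg$subgroup_effect(covs[i, , drop = FALSE], C)
    }
    ref <- simulate_reference(cfg, i)
    dev <- simulate_device(ref, cfg, i, confusion = C)
    id <- ref$participant_id
    records[[id]] <- list(device = dev, reference = ref)
    occ <- table(factor(unname(collapse_map[ref$labels]),
                        levels = stage_schemes$device))
    sleep_cls <- c("LIGHT", "DEEP", "REM")
    num_sens <- num_sens + sum(occ[sleep_cls] * (1 - C[sleep_cls, "WAKE"]))
    den_sens <- den_sens + sum(occ[sleep_cls])
    num_spec <- num_spec + occ[["WAKE"]] * C["WAKE", "WAKE"]
    den_spec <- den_spec + occ[["WAKE"]]
    gt_part[[id]] <- list(transition = pp$transition, confusion = C)
  }
  cohort <- paired_cohort(records, covs)
  attr(cohort, "ground_truth") <- list(
    participants = gt_part,
    pooled_sensitivity = num_sens / den_sens,
    pooled_specificity = num_spec / den_spec,
    config_seed = cfg$seed)
  cohort
}
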