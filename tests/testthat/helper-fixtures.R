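# Small in-code fixtures shared across test files.

# device hypnogram from compact labels: "W"->WAKE, "L"->LIGHT, "D"->DEEP,
# "R"->REM
dev_hyp <- function(code, id = "p1", epoch_seconds = 30) {
  map <- c(W = "WAKE", L = "LIGHT", D = "DEEP", R = "REM")
  lab <- unname(map[strsplit(code, "")[[1]]])
  hypnogram(lab, scheme = "device", epoch_seconds = epoch_seconds,
            participant_id = id)
}

ref_hyp <- function(labels, id = "p1", epoch_seconds = 30) {
  hypnogram(labels, scheme = "reference", epoch_seconds = epoch_seconds,
            participant_id = id)
}

# cohort with given per-participant label vectors (device scheme both sides
# unless reference labels given)
toy_cohort <- function(dev_codes, ref_codes = dev_codes) {
  ids <- sprintf("p%d", seq_along(dev_codes))
  recs <- Map(function(d, r, id) {
    list(device = dev_hyp(d, id), reference = dev_hyp(r, id))
  }, dev_codes, ref_codes, ids)
  names(recs) <- ids
  paired_cohort(recs)
}

# small simulated cohort for pipeline tests (fast defaults)
small_sim_cohort <- function(seed = 7, n = 6, tib = 240, ...) {
  suppressMessages(
    simulate_cohort(sim_config(n_participants = n, tib_epochs = tib,
                               seed = seed, ...)))
}
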