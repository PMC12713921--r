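# Brute-force oracles, written independently of the package internals:
# every quantity is recomputed by direct enumeration over epochs/pairs.

oracle_rates <- function(ref, dev, positive = "SLEEP") {
  stopifnot(length(ref) == length(dev))
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(ref)) {
    if (is.na(ref[i]) || is.na(dev[i])) next
    r_pos <- ref[i] == positive
    d_pos <- dev[i] == positive
    if (r_pos && d_pos) tp <- tp + 1
    if (r_pos && !d_pos) fn <- fn + 1
    if (!r_pos && d_pos) fp <- fp + 1
    if (!r_pos && !d_pos) tn <- tn + 1
  }
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
}

oracle_kappa <- function(ref, dev, classes = sort(unique(c(ref, dev)))) {
  n <- 0
  agree <- 0
  for (i in seq_along(ref)) {
    if (is.na(ref[i]) || is.na(dev[i])) next
    n <- n + 1
    if (ref[i] == dev[i]) agree <- agree + 1
  }
  if (n == 0) return(NA_real_)
  po <- agree / n
  pe <- 0
  for (cl in classes) {
    pr <- sum(ref == cl, na.rm = TRUE) / n
    pd <- sum(dev == cl, na.rm = TRUE) / n
    pe <- pe + pr * pd
  }
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

oracle_weighted_kappa <- function(x, y, cats = seq(min(c(x, y)), max(c(x, y)))) {
  K <- length(cats)
  if (K < 2) return(NA_real_)
  n <- length(x)
  W <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    W[i, j] <- 1 - abs(i - j) / (K - 1)
  }
  po <- pe <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    pij <- sum(x == cats[i] & y == cats[j]) / n
    ri <- sum(x == cats[i]) / n
    cj <- sum(y == cats[j]) / n
    po <- po + W[i, j] * pij
    pe <- pe + W[i, j] * ri * cj
  }
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

oracle_loa_constant <- function(device, reference) {
  d <- device - reference
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  c(lower = m - qnorm(0.975) * s, upper = m + qnorm(0.975) * s)
}

# number of awakenings by explicit run enumeration over the wake indicator
# at-or-after the first sleep epoch
oracle_nawk <- function(is_wake) {
  onset <- which(!is_wake)[1]
  if (is.na(onset)) return(0L)
  count <- 0L
  in_run <- FALSE
  for (i in onset:length(is_wake)) {
    if (is_wake[i] && !in_run) {
      count <- count + 1L
      in_run <- TRUE
    }
    if (!is_wake[i]) in_run <- FALSE
  }
  count
}
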