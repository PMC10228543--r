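# Shared fixtures: hand-built profiles and independent oracles.

# Build a delta_profile directly from per-residue values (singlet peaks).
# `delta`/`error` are vectors indexed by position 1..36; NA = unobserved.
make_delta_profile <- function(delta, error, observable = "hnNOE",
                               salt_mM = 0, wt = "WT", mut = "R26Q") {
  n <- length(delta)
  obs <- which(!is.na(delta))
  rows <- data.frame(
    residue = seq_len(n), pairing = ifelse(is.na(delta), NA, "1-1"),
    delta = delta, error = error,
    error_sum = error * sqrt(2),       # equal halves convention for fixtures
    sigma_wt = error / sqrt(2), sigma_mut = error / sqrt(2),
    status = ifelse(is.na(delta), "missing", "ok"))
  structure(rows, class = c("delta_profile", "data.frame"),
            observable = observable, salt_mM = salt_mM,
            wt_construct = wt, mut_construct = mut)
}

# Build a residue_profile from a named value/error vector (positions 1..36).
make_profile <- function(value, error = rep(0.01, length(value)),
                         construct = "WT", salt_mM = 0,
                         observable = "hnNOE") {
  n <- length(value)
  rows <- data.frame(residue = seq_len(n), peak_id = 1L, value = value,
                     error = error,
                     status = ifelse(is.na(value), "not-observed", "ok"))
  structure(rows[order(rows$residue), ],
            class = c("residue_profile", "data.frame"),
            construct = construct, salt_mM = salt_mM, observable = observable)
}

# Exhaustive region-detection oracle: enumerate every candidate span and
# apply the run rule directly; keep maximal valid spans.
# q: logical vector over positions, NA = unobserved.
oracle_regions <- function(q) {
  n <- length(q)
  qual <- which(!is.na(q) & q)
  valid <- list()
  for (i in qual) for (j in qual[qual >= i]) {
    span <- i:j
    inside <- qual[qual >= i & qual <= j]
    if (length(inside) < 3L) next
    ok <- TRUE
    for (m in seq_len(length(inside) - 1L)) {
      if (inside[m + 1L] - inside[m] <= 1L) next
      gap <- (inside[m] + 1L):(inside[m + 1L] - 1L)
      if (sum(!is.na(q[gap]) & !q[gap]) > 1L) { ok <- FALSE; break }
    }
    if (ok) valid[[length(valid) + 1L]] <- c(i, j)
  }
  if (!length(valid))
    return(data.frame(start = integer(), end = integer()))
  v <- do.call(rbind, valid)
  maximal <- vapply(seq_len(nrow(v)), function(r) {
    !any(v[, 1] <= v[r, 1] & v[, 2] >= v[r, 2] &
         (v[, 1] != v[r, 1] | v[, 2] != v[r, 2]))
  }, logical(1))
  v <- v[maximal, , drop = FALSE]
  v <- v[order(v[, 1]), , drop = FALSE]
  data.frame(start = v[, 1], end = v[, 2])
}

# Simulated hnNOE profiles for the five-study constructs at one seed.
sim_noe_profiles <- function(seed, salt_mM = 0,
                             constructs = c("WT", "R2Q", "R8Q", "R17Q",
                                            "R26Q", "R2/8/17/26Q"),
                             noise_fraction = 0.02) {
  profs <- lapply(constructs, function(cn) {
    tr <- generate_truth(cn, salt_mM, seed = seed)
    tab <- simulate_noe_pair(tr, noise_fraction, seed = seed,
                             residues = observable_positions(cn, salt_mM),
                             doublets = doublet_residues(cn, salt_mM))
    noe_profile(tab)
  })
  names(profs) <- constructs
  profs
}

# log-linear closed-form fit (independent oracle for noiseless series)
loglinear_fit <- function(delay, intensity) {
  fit <- lm(log(intensity) ~ delay)
  list(i0 = exp(coef(fit)[[1]]), rate = -coef(fit)[[2]])
}
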