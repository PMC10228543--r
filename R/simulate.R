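# Simulation of noisy peak tables from anchor-model truth.
#
# Peak tables are long-format data.frames with one row per measured peak
# intensity (or per HSQC peak), the same layout the TSV files use:
# construct, salt_mM, experiment, residue, peak_id, delay_s, intensity,
# noise, dH_ppm, dN_ppm (empty where not applicable).

PEAK_TABLE_COLUMNS <- c("construct", "salt_mM", "experiment", "residue",
                        "peak_id", "delay_s", "intensity", "noise",
                        "dH_ppm", "dN_ppm")

#' Default relaxation delay schedules
#'
#' The R1 series uses total relaxation loop lengths of 0.033, 0.195,
#' 0.390 (x2), 0.813 (x2), 1.301 and 1.951 s; the R2 (CPMG) series uses
#' 0.0088, 0.031 (x2), 0.053, 0.079, 0.110 (x2) and 0.150 s. The wild-type
#' sample at 150 mM KCl was collected with a shorter R2 schedule, available
#' as `variant = "wt150"`. Duplicated delays are genuine repeat points.
#'
#' @param experiment `"R1"` or `"R2"`.
#' @param variant `"default"`, or `"wt150"` for the shorter R2 schedule.
#' @return Numeric vector of delays in seconds.
#' @export
delay_schedule <- function(experiment = c("R1", "R2"),
                           variant = c("default", "wt150")) {
  experiment <- match.arg(experiment)
  variant <- match.arg(variant)
  if (experiment == "R1")
    return(c(0.033, 0.195, 0.390, 0.390, 0.813, 0.813, 1.301, 1.951))
  if (variant == "wt150")
    return(c(0.0044, 0.018, 0.018, 0.040, 0.062, 0.084, 0.084, 0.110))
  c(0.0088, 0.031, 0.031, 0.053, 0.079, 0.110, 0.110, 0.150)
}

empty_peak_table <- function() {
  data.frame(construct = character(), salt_mM = numeric(),
             experiment = character(), residue = integer(),
             peak_id = integer(), delay_s = numeric(), intensity = numeric(),
             noise = numeric(), dH_ppm = numeric(), dN_ppm = numeric())
}

# peak layout: doublet residues carry two peaks splitting the reference
# intensity 55/45; all others a single peak
peak_layout <- function(truth, residues, doublets) {
  rows <- lapply(residues, function(r) {
    i0 <- truth$i0[truth$residue == r]
    if (r %in% doublets)
      data.frame(residue = r, peak_id = c(1L, 2L), i0 = i0 * c(0.55, 0.45))
    else
      data.frame(residue = r, peak_id = 1L, i0 = i0)
  })
  do.call(rbind, rows)
}

check_noise_fraction <- function(noise_fraction) {
  stop_if_not_scalar_number(noise_fraction, "noise_fraction")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  noise_fraction
}

#' Simulate a relaxation decay series
#'
#' Emits one row per (residue, peak, delay) with intensity
#' `I0 * exp(-R * t)` plus additive Gaussian noise of standard deviation
#' `noise_fraction * I0` (the per-spectrum noise figure, also written to
#' the `noise` column). Duplicated delays yield independent rows.
#'
#' @param truth a [generate_truth()] object.
#' @param experiment `"R1"` or `"R2"`; selects the true rate.
#' @param delays delay schedule in seconds (defaults to
#'   [delay_schedule()] for the experiment).
#' @param noise_fraction Gaussian noise scale as a fraction of the
#'   reference intensity; 0 gives noiseless data.
#' @param seed integer seed (streams are derived per construct, salt and
#'   experiment, so tables are reproducible row for row).
#' @param residues positions to emit (default: all residues in `truth`).
#' @param doublets positions emitted as two peaks.
#' @return A peak-table data.frame.
#' @export
simulate_relaxation_series <- function(truth, experiment = c("R1", "R2"),
                                       delays = NULL, noise_fraction = 0.02,
                                       seed = 1L, residues = truth$residue,
                                       doublets = integer()) {
  experiment <- match.arg(experiment)
  check_noise_fraction(noise_fraction)
  if (is.null(delays)) delays <- delay_schedule(experiment)
  if (any(delays <= 0)) stop("relaxation delays must be positive")
  construct <- attr(truth, "construct")
  salt <- attr(truth, "salt_mM")
  layout <- peak_layout(truth, residues, doublets)
  if (is.null(layout)) return(empty_peak_table())

  set.seed(derive_seed(seed, paste(construct, salt, experiment)))
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    r <- layout$residue[i]
    rate <- if (experiment == "R1") truth$r1[truth$residue == r]
            else truth$r2[truth$residue == r]
    i0 <- layout$i0[i]
    sigma <- noise_fraction * i0
    data.frame(construct = construct, salt_mM = salt, experiment = experiment,
               residue = r, peak_id = layout$peak_id[i], delay_s = delays,
               intensity = i0 * exp(-rate * delays) +
                 rnorm(length(delays), 0, sigma),
               noise = sigma, dH_ppm = NA_real_, dN_ppm = NA_real_)
  })
  do.call(rbind, rows)
}

#' Simulate a steady-state heteronuclear NOE pair
#'
#' Emits interleaved reference and saturated intensities per peak:
#' reference `I0 + noise`, saturated `hnNOE * I0 + noise`, both with the
#' same per-spectrum `noise` column. Negative true hnNOE passes through as
#' negative saturated intensity.
#'
#' @inheritParams simulate_relaxation_series
#' @return A peak-table data.frame with experiments `"hnNOE-ref"` and
#'   `"hnNOE-sat"`.
#' @export
simulate_noe_pair <- function(truth, noise_fraction = 0.02, seed = 1L,
                              residues = truth$residue, doublets = integer()) {
  check_noise_fraction(noise_fraction)
  construct <- attr(truth, "construct")
  salt <- attr(truth, "salt_mM")
  layout <- peak_layout(truth, residues, doublets)
  if (is.null(layout)) return(empty_peak_table())

  set.seed(derive_seed(seed, paste(construct, salt, "hnNOE")))
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    r <- layout$residue[i]
    noe <- truth$hnnoe[truth$residue == r]
    i0 <- layout$i0[i]
    sigma <- noise_fraction * i0
    data.frame(construct = construct, salt_mM = salt,
               experiment = c("hnNOE-ref", "hnNOE-sat"),
               residue = r, peak_id = layout$peak_id[i], delay_s = NA_real_,
               intensity = c(i0, noe * i0) + rnorm(2, 0, sigma),
               noise = sigma, dH_ppm = NA_real_, dN_ppm = NA_real_)
  })
  do.call(rbind, rows)
}

#' Simulate an amide chemical shift table
#'
#' Wild-type shifts are drawn once per seed from plausible amide ranges
#' (dH 7.8-8.7 ppm; dN 112-127 ppm, glycines 105-112 ppm). A mutant's
#' shifts are the same wild-type base plus a perturbation decaying from
#' each mutated site, scaled so non-mutated residues move at most
#' ~0.07 ppm (weighted) next to the site and under 0.04 ppm beyond five
#' residues, plus a small seeded ripple; the mutated residue itself moves
#' by `csp_site`. At 0 mM KCl the construct's doublet residues are emitted
#' as two peaks with a fixed small splitting; at 150 mM all peaks are
#' singlets.
#'
#' @inheritParams generate_truth
#' @return A peak-table data.frame with experiment `"HSQC"`.
#' @export
simulate_shift_table <- function(construct, salt_mM,
                                 params = anchor_params(), seed = 1L) {
  validate_anchor_params(params)
  salt_mM <- check_salt(salt_mM)
  muts <- mutated_positions(construct)
  n <- H3_TAIL_LENGTH
  wt_codes <- h3_tail()$residues

  # construct-independent wild-type base shifts
  set.seed(derive_seed(seed, "wt-shifts"))
  dH <- runif(n, 7.8, 8.7)
  dN <- ifelse(wt_codes == "G", runif(n, 105, 112), runif(n, 112, 127))

  if (length(muts)) {
    set.seed(derive_seed(seed, paste("csp", construct)))
    for (m in muts) {
      d <- abs(seq_len(n) - m)
      mag <- ifelse(d == 0, params$csp_site,
                    params$csp_neighbor * exp(-(d - 1) / params$csp_lambda))
      u <- runif(n, 0.3, 0.9)              # fraction of CSP carried by 1H
      sH <- sample(c(-1, 1), n, replace = TRUE)
      sN <- sample(c(-1, 1), n, replace = TRUE)
      dH <- dH + sH * mag * u
      dN <- dN + sN * mag * sqrt((1 - u^2) / 0.154)
    }
    jit <- runif(n, 0, params$csp_jitter)
    uj <- runif(n, 0.3, 0.9)
    dH <- dH + sample(c(-1, 1), n, TRUE) * jit * uj
    dN <- dN + sample(c(-1, 1), n, TRUE) * jit * sqrt((1 - uj^2) / 0.154)
  }

  residues <- observable_positions(construct, salt_mM, "hsqc")
  doublets <- intersect(doublet_residues(construct, salt_mM), residues)
  rows <- lapply(residues, function(r) {
    if (r %in% doublets) {
      data.frame(construct = construct, salt_mM = salt_mM,
                 experiment = "HSQC", residue = r, peak_id = c(1L, 2L),
                 delay_s = NA_real_, intensity = NA_real_, noise = NA_real_,
                 dH_ppm = dH[r] + c(0, params$doublet_split[["dH"]]),
                 dN_ppm = dN[r] + c(0, params$doublet_split[["dN"]]))
    } else {
      data.frame(construct = construct, salt_mM = salt_mM,
                 experiment = "HSQC", residue = r, peak_id = 1L,
                 delay_s = NA_real_, intensity = NA_real_, noise = NA_real_,
                 dH_ppm = dH[r], dN_ppm = dN[r])
    }
  })
  do.call(rbind, rows)
}

#' Simulate the full peak table for one sample
#'
#' Assembles R1, R2, hnNOE and HSQC rows for one (construct, salt)
#' sample, applying the observability rules (invisible residues and
#' per-construct omissions) and the construct's doublet set.
#'
#' @inheritParams generate_truth
#' @param noise_fraction noise scale; defaults to `params$noise_fraction`.
#' @param r2_variant delay-schedule variant for the R2 series (the
#'   wild-type 150 mM sample used a shorter schedule).
#' @param apply_omissions drop rows for omitted residues (default TRUE);
#'   with FALSE every non-proline residue is emitted.
#' @return A peak-table data.frame covering all four experiments.
#' @examples
#' tab <- simulate_peak_table("R26Q", 0, seed = 7)
#' table(tab$experiment)
#' @export
simulate_peak_table <- function(construct, salt_mM,
                                params = anchor_params(), seed = 1L,
                                noise_fraction = NULL,
                                r2_variant = c("default", "wt150"),
                                apply_omissions = TRUE) {
  r2_variant <- match.arg(r2_variant)
  nf <- noise_fraction %||% params$noise_fraction
  truth <- generate_truth(construct, salt_mM, params, seed)
  relax_res <- if (apply_omissions)
    observable_positions(construct, salt_mM, "relaxation")
  else setdiff(seq_len(H3_TAIL_LENGTH), invisible_positions())
  doub <- doublet_residues(construct, salt_mM)

  rbind(
    simulate_relaxation_series(truth, "R1", noise_fraction = nf, seed = seed,
                               residues = relax_res,
                               doublets = intersect(doub, relax_res)),
    simulate_relaxation_series(truth, "R2",
                               delays = delay_schedule("R2", r2_variant),
                               noise_fraction = nf, seed = seed,
                               residues = relax_res,
                               doublets = intersect(doub, relax_res)),
    simulate_noe_pair(truth, noise_fraction = nf, seed = seed,
                      residues = relax_res,
                      doublets = intersect(doub, relax_res)),
    simulate_shift_table(construct, salt_mM, params, seed))
}

# ---- TSV I/O ----------------------------------------------------------------

#' Read and write peak tables
#'
#' Peak tables are tab-separated with the fixed header `construct,
#' salt_mM, experiment, residue, peak_id, delay_s, intensity, noise,
#' dH_ppm, dN_ppm`; fields that do not apply are empty.
#'
#' @param x a peak-table data.frame.
#' @param path file path.
#' @return `read_peak_table()` returns the data.frame;
#'   `write_peak_table()` returns `path` invisibly.
#' @export
write_peak_table <- function(x, path) {
  stopifnot(identical(names(x), PEAK_TABLE_COLUMNS))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, PEAK_TABLE_COLUMNS))
    stop("'", path, "' is not a peak table: expected header ",
         paste(PEAK_TABLE_COLUMNS, collapse = ", "))
  x <- read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                  colClasses = c(construct = "character",
                                 salt_mM = "numeric",
                                 experiment = "character",
                                 residue = "integer", peak_id = "integer",
                                 delay_s = "numeric", intensity = "numeric",
                                 noise = "numeric", dH_ppm = "numeric",
                                 dN_ppm = "numeric"))
  if (!identical(names(x), PEAK_TABLE_COLUMNS))
    stop("'", path, "' is not a peak table: expected header ",
         paste(PEAK_TABLE_COLUMNS, collapse = ", "))
  x
}
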