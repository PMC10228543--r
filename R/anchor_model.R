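# Arginine anchor-point model: ground-truth per-residue dynamics.
#
# Each residue carries a microscopic DNA site-binding strength (basic
# residues bind tightest). A triangular smoothing window couples neighbours,
# neutralizing an arginine removes strength in an exponentially decaying
# kernel around the site (wider on the C-terminal side), and the three
# relaxation observables are affine functions of the smoothed strength.

#' Parameters of the arginine anchor-point model
#'
#' Defaults are calibrated so that wild-type truth at 0 mM KCl lands on the
#' baseline experimental averages for the nucleosomal H3 tail: mean hnNOE
#' 0.34 with the S28-K36 "hinge" near 0.16 and T3-K27 near 0.41, mean R1
#' 1.07 +/- 0.09 s^-1, mean R2 22 +/- 8 s^-1 (and per-residue mean R2/R1
#' near 21), and so that the quadruple arginine mutant loses about 0.10 in
#' mean hnNOE.
#'
#' @param site_strengths named numeric: microscopic site-binding strength
#'   per residue code, in `[0, 1]`. Codes not listed get `other`.
#' @param other strength for codes not in `site_strengths`.
#' @param half_window half-width (residues) of the triangular smoothing
#'   window coupling neighbouring residues.
#' @param lambda_N,lambda_C decay lengths (residues) of the
#'   mutation-perturbation kernel on the N- and C-terminal side of the
#'   mutated position; `lambda_C > lambda_N` encodes the C-terminal bias of
#'   neutralization effects.
#' @param f_salt multiplicative scaling of the smoothed strength at 150 mM
#'   KCl, in `(0, 1]`; added monovalent salt weakens all tail-DNA contacts.
#' @param amp0 base amplitude of the strength-reduction kernel per
#'   neutralized arginine.
#' @param amp_power,amp_window the kernel amplitude for a mutation at
#'   position m is `amp0 * (1 - mean raw strength over m+1..m+amp_window)
#'   ^ amp_power`: an anchor matters most where its C-terminal neighbourhood
#'   holds no other anchors (this is what makes R26, next to the hinge, the
#'   strongest anchor).
#' @param noe_coef,r1_coef,r2_coef affine maps `c(intercept, slope)` from
#'   smoothed strength to hnNOE, R1 (s^-1) and R2 (s^-1). The R1 slope is
#'   negative: releasing the tail speeds ps-ns motion, raising R1.
#' @param noise_fraction default measurement noise as a fraction of the
#'   reference intensity (single per-spectrum noise figure).
#' @param i0_mean,i0_sdlog reference peak intensities are lognormal around
#'   `i0_mean` with log-sd `i0_sdlog` (arbitrary units).
#' @param doublet_split fixed chemical-shift splitting `c(dH, dN)` in ppm
#'   between the two peaks of a doublet residue.
#' @param csp_neighbor,csp_lambda,csp_site,csp_jitter shift-perturbation
#'   shape: a mutation moves the mutated residue's own peak by `csp_site`
#'   ppm (weighted scale), its sequence neighbours by `csp_neighbor *
#'   exp(-(d-1)/csp_lambda)`, and adds up to `csp_jitter` of seeded ripple
#'   everywhere else.
#' @return A validated list of class `anchor_params`.
#' @examples
#' p <- anchor_params()
#' p$f_salt
#' @export
anchor_params <- function(site_strengths = c(R = 1.0, K = 0.7),
                          other = 0.1,
                          half_window = 2L,
                          lambda_N = 3,
                          lambda_C = 6,
                          f_salt = 0.65,
                          amp0 = 0.205,
                          amp_power = 4,
                          amp_window = 8L,
                          noe_coef = c(-0.1734, 1.6497),
                          r1_coef = c(1.2757, -0.6540),
                          r2_coef = c(3.7170, 58.1305),
                          noise_fraction = 0.02,
                          i0_mean = 100,
                          i0_sdlog = 0.1,
                          doublet_split = c(dH = 0.02, dN = 0.10),
                          csp_neighbor = 0.07,
                          csp_lambda = 3,
                          csp_site = 0.30,
                          csp_jitter = 0.005) {
  p <- list(site_strengths = site_strengths, other = other,
            half_window = as.integer(half_window),
            lambda_N = lambda_N, lambda_C = lambda_C, f_salt = f_salt,
            amp0 = amp0, amp_power = amp_power,
            amp_window = as.integer(amp_window),
            noe_coef = noe_coef, r1_coef = r1_coef, r2_coef = r2_coef,
            noise_fraction = noise_fraction,
            i0_mean = i0_mean, i0_sdlog = i0_sdlog,
            doublet_split = doublet_split,
            csp_neighbor = csp_neighbor, csp_lambda = csp_lambda,
            csp_site = csp_site, csp_jitter = csp_jitter)
  validate_anchor_params(p)
  structure(p, class = "anchor_params")
}

validate_anchor_params <- function(p) {
  if (any(p$site_strengths < 0 | p$site_strengths > 1) ||
      p$other < 0 || p$other > 1)
    stop("site strengths must lie in [0, 1]")
  if (p$lambda_C <= p$lambda_N)
    stop("lambda_C must exceed lambda_N (C-terminal bias)")
  if (p$f_salt <= 0 || p$f_salt > 1)
    stop("f_salt must lie in (0, 1]")
  if (p$half_window < 0L) stop("half_window must be >= 0")
  for (nm in c("noe_coef", "r1_coef", "r2_coef"))
    if (length(p[[nm]]) != 2L || !all(is.finite(p[[nm]])))
      stop(nm, " must be two finite affine coefficients c(intercept, slope)")
  invisible(p)
}

# raw per-residue site strengths for a residue-code vector
raw_strengths <- function(codes, params) {
  s <- rep(params$other, length(codes))
  for (code in names(params$site_strengths))
    s[codes == code] <- params$site_strengths[[code]]
  s
}

# triangular smoothing, truncated and renormalized at the tail ends
smooth_strengths <- function(s, half_window) {
  n <- length(s)
  vapply(seq_len(n), function(r) {
    idx <- max(1L, r - half_window):min(n, r + half_window)
    w <- half_window + 1L - abs(idx - r)
    sum(w * s[idx]) / sum(w)
  }, numeric(1))
}

# exponential reduction kernel centered at m, asymmetric decay lengths
perturbation_kernel <- function(n, m, params) {
  r <- seq_len(n)
  d <- abs(r - m)
  ifelse(r < m, exp(-d / params$lambda_N), exp(-d / params$lambda_C))
}

# amplitude of the kernel for a mutation at m (computed from the WT tail)
kernel_amplitude <- function(m, params) {
  s_wt <- raw_strengths(h3_tail()$residues, params)
  idx <- (m + 1L):min(length(s_wt), m + params$amp_window)
  params$amp0 * (1 - mean(s_wt[idx]))^params$amp_power
}

#' Generate ground-truth per-residue dynamics
#'
#' Computes the anchor-point model's true hnNOE, R1 and R2 for every tail
#' residue of a construct at a given KCl concentration, together with
#' seeded reference peak intensities. Mutant truth differs from wild-type
#' truth only through the additive strength-reduction kernels centered at
#' the mutated positions, so multi-mutant effects are additive by
#' construction.
#'
#' @param construct construct label, e.g. `"WT"` or `"R2/8/17/26Q"`.
#' @param salt_mM 0 or 150 (mM added KCl); at 150 the smoothed strength is
#'   scaled by `params$f_salt`.
#' @param params an [anchor_params()] object.
#' @param seed integer seed for the reference intensities.
#' @return A data.frame of class `synthetic_truth` with one row per
#'   residue 1-36: `residue`, `code` (mutated sequence), `strength`
#'   (smoothed, after reduction and salt scaling), `hnnoe`, `r1`, `r2`,
#'   `i0`; attributes `construct`, `salt_mM`, `seed`, `params`.
#' @examples
#' tr <- generate_truth("WT", 0, seed = 1)
#' mean(tr$hnnoe[3:36])
#' @export
generate_truth <- function(construct, salt_mM, params = anchor_params(),
                           seed = 1L) {
  validate_anchor_params(params)
  salt_mM <- check_salt(salt_mM)
  muts <- parse_construct(construct)
  seq_mut <- apply_mutations(h3_tail(), muts)
  n <- H3_TAIL_LENGTH

  S <- smooth_strengths(raw_strengths(h3_tail()$residues, params),
                        params$half_window)
  for (m in mutated_positions(construct))
    S <- S - kernel_amplitude(m, params) * perturbation_kernel(n, m, params)
  if (salt_mM > 0) S <- S * params$f_salt

  hnnoe <- params$noe_coef[1] + params$noe_coef[2] * S
  r1 <- params$r1_coef[1] + params$r1_coef[2] * S
  r2 <- params$r2_coef[1] + params$r2_coef[2] * S
  if (any(r1 <= 0) || any(r2 <= 0))
    stop("observable coefficients yield non-positive relaxation rates")
  if (any(hnnoe <= -0.2) || any(hnnoe > 1))
    stop("observable coefficients yield hnNOE outside (-0.2, 1]")

  set.seed(derive_seed(seed, "reference-intensity"))
  i0 <- params$i0_mean * exp(rnorm(n, 0, params$i0_sdlog))

  structure(
    data.frame(residue = seq_len(n), code = seq_mut$residues,
               strength = S, hnnoe = hnnoe, r1 = r1, r2 = r2, i0 = i0),
    class = c("synthetic_truth", "data.frame"),
    construct = construct, salt_mM = salt_mM, seed = seed, params = params)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic truth: ", attr(x, "construct"), " at ",
      attr(x, "salt_mM"), " mM KCl (seed ", attr(x, "seed"), ")\n", sep = "")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}
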