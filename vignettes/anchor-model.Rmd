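---
title: "Methods: the anchor-point model and the relaxation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the anchor-point model and the relaxation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailspin)
```

# Scope and model

`tailspin` analyzes residue-resolved ps-ns dynamics of the histone H3
N-terminal tail (residues 1-36) within the nucleosome core particle, as
measured by ^15^N spin relaxation: longitudinal (R1) and transverse (R2)
rates from single-exponential decay of peak heights, the steady-state
{^1^H}-^15^N heteronuclear NOE (hnNOE, the saturated/reference intensity
ratio), and the derived R2/R1 ratio. Lower hnNOE and R2/R1 indicate faster
backbone motion. The scientific question the comparison stages address is
how neutralizing the tail arginines (R2, R8, R17, R26; mutated to
glutamine, singly or all together) releases the tail from its dynamic
DNA-bound ensemble.

Because the pipeline must be testable without experimental downloads, the
package includes a generative model of the system — the *arginine
anchor-point model* — that produces ground-truth dynamics and noisy peak
tables with the structure of the real experiments. The model is a
caricature with the right qualitative anatomy, not a spectral-density
calculation:

1. **Site strengths.** Each residue has a microscopic DNA site-binding
   strength by residue type: arginine 1.0, lysine 0.7, all others 0.1.
   Arginine's guanidinium group makes the most favorable DNA contacts;
   lysine is weaker; uncharged residues contribute little.
2. **Neighbour coupling.** Strengths are smoothed with a triangular window
   of half-width 2 residues: a residue's motion is damped by anchors in
   its immediate neighbourhood, so uncharged stretches (the TGG repeats,
   the S28-K36 "hinge") end up mobile while residues flanking an arginine
   are slowed.
3. **Mutation kernels.** Neutralizing the arginine at position *m*
   subtracts an exponential kernel `A_m * exp(-d/lambda)` from the
   smoothed strength, with decay length 3 residues toward the N-terminus
   and 6 toward the C-terminus (the C-terminal bias observed for these
   perturbations). Kernels of multiple mutations add, so multi-mutant
   effects are additive *by construction* — the additivity test has an
   exact truth to recover.
4. **Amplitudes.** `A_m = amp0 * (1 - s̄_C(m))^4`, where `s̄_C(m)` is the
   mean raw strength over the eight residues C-terminal of *m*. An anchor
   matters most where its C-terminal neighbourhood holds no other anchors:
   R26, sitting directly N-terminal of the anchor-poor hinge, gets the
   largest amplitude, and R2, whose N-terminal side is invisible and whose
   C-terminal side is anchor-rich, the smallest. This is the model's
   mechanism for the observation that R26 neutralization has the broadest
   effect and R2 the narrowest.
5. **Salt.** At 150 mM KCl all strengths are scaled by `f_salt = 0.65`:
   monovalent salt screens the electrostatic tail-DNA contacts, uniformly
   raising mobility.
6. **Observables.** hnNOE, R1 and R2 are affine in the smoothed strength.
   The hnNOE and R2 slopes are positive, the R1 slope negative (faster
   ps-ns motion raises R1 in this regime).

## Calibration of the defaults

The affine coefficients and kernel amplitude were fixed once, against the
baseline averages measured for the wild-type tail at 0 mM KCl, and are not
meant to be refit per run:

* mean hnNOE over the observed tail 0.34, with the T3-K27 segment near
  0.41 and the S28-K36 hinge near 0.16 (these two pin the hnNOE
  intercept and slope);
* mean R1 = 1.07 s^-1 with an across-residue spread of about 0.09 s^-1,
  and mean R2 = 22 s^-1 with a spread of about 8 s^-1 (these pin the R1
  and R2 maps; the resulting per-residue mean R2/R1 is about 21);
* a drop of about 0.10 in mean hnNOE for the quadruple mutant (this pins
  `amp0`).

Two deliberate compromises follow from using a single latent strength with
affine maps. First, the model cannot simultaneously match the quadruple
mutant's reported mean R1 increase (about 17%) and the wild type's nearly
flat R1 profile; we chose the wild-type spreads as the anchors, so the
simulated quadruple mutant's R1 and R2/R1 shifts are directionally correct
but smaller than the experimental ones. Second, within-segment
heterogeneity of hnNOE is larger than in the real data (the strength
profile oscillates between anchors and troughs). Neither affects the
difference profiles, which are what the comparison stages consume.

What the generator deliberately does *not* model: overall-tumbling
contributions to R2/R1 near the particle core, exchange (µs-ms)
contributions to R2 at the 500 Hz CPMG field, lineshape overlap between
crowded peaks, and the physical origin of peak doublets — doublets are a
configured label set per construct at 0 mM KCl (merging to singlets at
150 mM), with a fixed small splitting (0.02 ppm ^1^H, 0.10 ppm ^15^N),
because no magnitudes are established for the underlying asymmetry.
Consequently, passing tests demonstrate that the *pipeline* recovers known
truths under realistic noise and missing-data structure; they are not
evidence about nucleosome biophysics beyond what was put into the model.

# Synthetic experiment design

Simulated acquisitions mirror the real schedules: R1 series at delays
0.033, 0.195, 0.390 (x2), 0.813 (x2), 1.301, 1.951 s; R2 series at
0.0088, 0.031 (x2), 0.053, 0.079, 0.110 (x2), 0.150 s (the wild-type
150 mM sample uses a shorter variant); interleaved saturated/reference
pairs for the hnNOE. Duplicated delays are emitted as independent rows.
Noise is additive Gaussian with standard deviation equal to a fixed
fraction (default 0.02) of the residue's reference intensity, matching the
practice of propagating a single per-spectrum noise figure; the same value
fills the table's `noise` column. Reference intensities are lognormal
(median 100, log-sd 0.1) to give residues realistic intensity variation.

Observability follows the experimental bookkeeping: A1, P16 and P30 are
never visible; R2 is excluded from relaxation analysis everywhere (and
invisible at 150 mM); L20 is excluded for WT, R2Q, R8Q and R26Q at 0 mM
and WT at 150 mM; K36 is excluded everywhere at 150 mM. The generator
drops those rows, so downstream stages always face realistic missing data,
and every missing residue in every profile carries an explicit reason.

# Estimation choices

**Exponential fits.** Unweighted least squares of `I0 * exp(-R t)` without
offset. Unweighted is deliberate: with one noise figure per spectrum,
weights would be uniform anyway. Start values come from log-linear
regression on the positive intensities; negative intensities participate
in the fit itself. Parameter errors use the Gauss-Newton covariance scaled
by residual variance with an `n - 2` denominator; whether to scale by the
residual variance or by the known spectral noise is genuinely open, so
both are available (`error_scaling = "residual"` default, `"noise"`
alternative). Fits that fail (or give a non-positive rate) flag the
residue `"not-fit"` rather than aborting the profile. A jackknife error
(leave-one-out refits) is provided as a robustness cross-check; on
simulated series at 2% noise it agrees with the covariance error within a
factor of two on average.

**hnNOE and R2/R1.** The hnNOE is the plain saturated/reference ratio with
first-order error propagation of the two spectral noise values, including
the limit form when the saturated intensity is zero. R2/R1 propagates the
two relative fit errors in quadrature.

**CSP.** `sqrt(dH^2 + 0.154 dN^2)` with the standard amide nitrogen
weighting (configurable). Doublet pairing: when the reference construct
shows a singlet and the mutant a doublet, both mutant peaks are compared
against the single reference peak and both values reported; the mirror
case (reference doublet, mutant singlet) is handled symmetrically, which
is our extension — only the first case has an established convention.
Doublet-doublet residues pair by peak id. Mutated positions are reported
but flagged, and excluded from envelope statements about non-mutated
residues.

**Difference profiles.** `delta = reference - mutant`, so positive hnNOE
or R2/R1 deltas mean the mutant is more mobile. Errors combine in
quadrature; the component errors are retained so the sum-of-halfwidths
overlap criterion can also be applied. The summed delta (the area between
the profiles) uses the per-residue mean over pairings, with missing
residues contributing nothing.

**Region detection.** A residue *qualifies* when `|delta| > k * error`
(strict, default `k = 1`) for at least one pairing. A region is a maximal
run of at least three qualifying residues in which single observed
non-qualifying residues may interrupt but two consecutive observed
non-qualifiers break the run; unobserved residues neither qualify nor
break runs and are counted in the inclusive span; endpoints must qualify.
"Non-overlapping error bars" is ambiguous between the quadrature
combination (statistical convention, our default) and the literal
non-overlap of plotted bars (`|delta| > sigma_ref + sigma_mut`,
`criterion = "halfwidth-sum"`); both are implemented. At `k = 1` a null
residue qualifies by chance about 32% (quadrature) or 16% (halfwidth-sum)
of the time, so single-replicate breadths are noisy; the breadth ordering
across mutants (R26Q broadest, R2Q narrowest, R8Q and R17Q alike) is a
property of the *expected* breadths and is tested as an average over 50
seeded replicates rather than per replicate.

**Additivity.** The per-residue discrepancy is
`sum(single-mutant deltas) - quadruple delta`, over the intersection of
residues observed in all five comparisons (constructs differ in their
omission lists, so the intersection is the only set on which the sum is
well defined). Because every delta shares the same wild-type reference,
the wild-type value enters the discrepancy three times; the default
combined error propagates that multiplicity
(`sqrt(9 sigma_WT^2 + sum sigma_mut^2)`), with the naive quadrature of the
five delta errors available for comparison. With correctly estimated
1-sigma errors, the expected fraction of residues inside one combined
error bar is 68%, not higher — a useful caution when reading "fraction
within error" summaries.

# Numerical and reproducibility choices

All randomness flows from a single integer seed through deterministic
per-experiment sub-seeds (seed plus a text tag, folded into 31 bits), so
identical configurations give byte-identical peak tables and reports; no
wall-clock seeding exists anywhere. Ranking ties are broken by construct
name and flagged. Spans and counts are 1-based and inclusive everywhere,
matching residue-label conventions (T22-V35 counts 14 residues, including
the invisible P30).

Monte-Carlo problem sizes used in the test-suite: 500 replicates for fit
calibration, 50 replicates for ranking and breadth stability, 1000 random
profiles for the region-detection oracle comparison, 10^5 draws for
brute-force error-propagation checks. These sizes give comfortably stable
pass/fail behaviour for the properties tested.

# Worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 1)
simulate_study(cfg, "study")
res <- analyze_study(cfg, "study")
read.csv(file.path("study", "ranking.csv"))
cat(readLines(file.path("study", "summary.txt")), sep = "\n")
```

# Known limitations

* The generator's observables are affine in one latent strength; real
  spin relaxation mixes spectral densities non-linearly, and R2/R1 near
  the core is dominated by overall tumbling, which is not modeled.
* CSP perturbation directions are random; trajectory analysis toward an
  unbound-tail reference is out of scope.
* Region detection at `k = 1` is liberal; for conservative breadth
  estimates use `criterion = "halfwidth-sum"` or a larger `k`.
* The additivity "fraction within error" saturates at its statistical
  ceiling (~68% at one combined sigma) even when additivity is exact.
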