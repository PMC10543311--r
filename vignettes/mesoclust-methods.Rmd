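---
title: "Models and methods behind mesoclust"
author: "mesoclust authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesoclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoclust)
```

# Scope

`mesoclust` implements the analysis layer of the assays used to quantify
mesoscale clustering of phase-separating proteins in sub-saturated
solutions: autocorrelation and DLS sizing, nanoparticle tracking,
single-molecule burst/lifetime/FRET analysis, FCS model fitting,
microfluidic confocal cluster counting, preferential-interaction analysis of
solvation trajectories, and saturation-concentration thermodynamics. It does
not acquire data, run molecular dynamics, or simulate instrument optics
beyond what the estimators need; the built-in generators produce records
with the *statistical* structure of the real inputs (Brownian suspensions,
Poisson photon streams, Poisson cluster transits, equilibrium solvation
configurations) so every estimator can be exercised round-trip.

Units at all interfaces: nm for sizes and radial grids, ns for lifetimes and
microtimes, kHz for count rates, ms for diffusion times, seconds for
macrotimes and lags, SI internally.

# Correlation engines

`correlateDirect()` is the exact estimator
g2(tau) = \<I(t) I(t+tau)\> / \<I\>^2 at every integer lag.
`correlateMultiTau()` is the standard quasi-logarithmic estimator: 16 points
per level, pairwise averaging (factor 2) between levels; photon streams are
binned (default 1 µs) at the finest level. Both default to *symmetric
normalization* (the product of head- and tail-segment means), which reduces
finite-trace tail bias; plain normalization is a flag. The two estimators
agree within 2% on smooth traces over the first tenth of the record — the
coarse levels of the multi-tau grid carry a triangular binning kernel, which
is negligible when the correlation time exceeds a few bins. Per-lag
uncertainties, when requested, come from splitting the record into
contiguous blocks and using the block-to-block scatter of the correlation;
these weights feed the FCS fit.

The correlation-curve container stores g2 (baseline 1) or g2 − 1
(baseline 0) explicitly, since instrument exports differ in convention.

# DLS

The field correlation of a monodisperse suspension decays as exp(−D q² tau),
so the fitted model is G(tau) = 1 + b exp(−2 D q² tau) with
q = (4 π n0/λ0) sin(θ/2); b absorbs the instrument coherence factor.
Defaults are a 632.8 nm laser at 173° in water (n0 = 1.330,
η = 0.8872 mPa·s at 298.15 K) — all configurable. Sizes come from
D = kB T/(6 π η R_h), reported as d_h = 2 R_h.

*Slow-mode detection* fits two exponentials and reports the amplitude share
of the slower one; the flag requires a share above 0.1 **and** a
diffusion-coefficient separation above 10×. Both thresholds are package
choices (the underlying criterion in practice is qualitative); components
closer than 2× collapse to the single fit. *Size distributions* invert
sqrt(G − 1) = Σ w_i exp(−D_i q² tau) on a log-spaced diameter grid by
nonnegative least squares with second-difference smoothing; the smoothing
weight defaults to an L-curve corner search because vendor regularization
settings are proprietary. The *derived count rate* is measured rate divided
by the transmitted laser fraction — only this defining ratio is implemented,
not any vendor attenuation bookkeeping.

# NTA

Linking is greedy nearest-neighbour, candidate links taken in order of
increasing displacement (ties by lowest track id), gaps bridged up to a
`memory` of missed frames, minimum track length 10. On synthetic suspensions
at realistic field densities this gives >99% correct links; identity
switches during close encounters are the known failure mode of greedy
linking and the reason a purity-style metric reads lower than the
link-correctness metric. Diffusion is the MSD slope over the first 5 lags
with a free intercept (localization noise); a quadratic term dominating the
linear one flags drift. The size gate is 20 nm–1 µm, the instrument's
measurement range. Concentrations are mean simultaneous track count over the
observation volume; because per-sample dilution factors are rarely recorded,
comparisons across buffers should be made as ratios, which cancel them.

# Burst analysis and smFRET

Burst selection bins the stream (1 ms default), estimates the background by
3 rounds of 3σ clipping, and takes maximal runs of bins above
mean + 2σ, merging runs separated by one sub-threshold bin; bursts need at
least 10 photons and at most 3000 (the cap exists because downstream
per-burst fits scale with photon count). A caution established while
validating the selector: with 1 ms bins, Poisson discreteness makes a
2σ threshold admit single-photon bins once the per-bin background mean drops
below ~1, and the false-burst rate is ~1/s at a 1 kHz summed background. The
false-positive property tested in the suite (<0.1 false bursts per 10 s)
therefore uses a dark-count-dominated background of 0.1 kHz summed over the
four channels; at brighter backgrounds the same rules require either smaller
bins or a higher threshold, which the configuration exposes.

Lifetimes are maximum-likelihood fits of a mono-exponential decay wrapped
into the observation window (identical to a truncated renormalized
exponential) plus a known uniform background fraction; the standard error is
the Fisher curvature at the MLE. For a mono-exponential model this MLE *is*
the fluorescence-weighted average lifetime. Polarization channels combine as
S_par + 2 g S_perp before any ratio is formed.

FRET bookkeeping assumes pulsed interleaved excitation with the donor window
in the first half of the excitation period. Corrections apply in the order
background → crosstalk (linear subtraction) → detection-efficiency factor;
defaults are ideal (0/1) because correction factors are instrument-specific
calibrations. The static FRET line is E = 1 − tau_f/tau0. The dynamic line
for two interconverting states uses the intensity-weighted lifetime
tau_f = (x tau1² + (1−x) tau2²)/(x tau1 + (1−x) tau2) against the
species-averaged efficiency; it always lies at or above the static line and
collapses to a point when the state lifetimes coincide. Dye-linker
corrections used in some MFD practice are out of scope.

# FCS

The model is two 3D-Gaussian diffusion components weighted R and |1 − |R||,
multiplied by a kinetic relaxation factor 1 − |A| + |A| exp(−tc/tA); R and A
enter through absolute values, and the optimizer works on unconstrained
parameters (log scales for times, occupancy and axial ratios), reporting
magnitudes. Axial ratios default to 5 and stay fixed unless freed.
Initialization (t_d1 from the curve half-decay, t_d2 = 10 t_d1, R = 0.5,
A = 0.1) is documented because the surface is multimodal. Component ordering
t_d2 ≥ t_d1 is enforced by swapping after the fit; diffusion times landing
on the lag-range bounds are flagged rather than silently accepted.

Two statistical facts shape how the package is meant to be used. First, a
finite simulation (or measurement) volume with a fixed number of molecules
suppresses long-lag correlation (a closed-system anticorrelation), which the
free offset G0 absorbs; apparent diffusion times are therefore calibrated,
not assumed — fit a monomer-only measurement first and fix t_d1 globally
across the titration, exactly what the fixed-parameter mask is for. Second,
two components separated by only 2× in diffusion time are amplitude-
degenerate at desk-scale acquisition: a free-R fit collapses onto a single
effective component. The round-trip benchmark therefore pins the known
composition (R) along with the calibrated t_d1 and recovers t_d2; with
10 s acquisitions this returns t_d2/t_d1 within [1.6, 2.4] of the true
two-fold ratio. `residualStructure()` runs a Wald–Wolfowitz runs test on
residual signs beyond t_d2 — long same-sign stretches there are the
signature of unmodelled slower components.

# MCS

Cluster transits are maximal runs above mean + 5σ per trace (σ again from
3-round sigma clipping, so the peaks do not inflate their own threshold; at
a 10 kHz baseline with 1 ms bins the false-peak rate is <0.1 per 4 s trace).
The mean count over the 200 scan locations is the equal-weight average of
the four channel-group means. The flux formula
F = n·h·d_step / (t·(π/4)·z·w) resolves the geometry dimensionally: the
elliptical confocal spot cross-section (π/4)·z·w samples that fraction of
the per-step channel cross-section h·d_step; with the default geometry
(t = 4 s, h = 28 µm, d_step = 5.64 µm, z = 3 µm, w = 0.4 µm, Q = 15 µL/h),
n = 2 gives F ≈ 83.8 s⁻¹ and c = F/(N_A Q) ≈ 3.3×10⁻¹⁴ M. The dilute-phase
concentration estimator takes the mode of the kernel-smoothed intensity
histogram (the dilute phase dominates the sampled volume) and errors out
when fewer than 80% of samples sit below twice the mode — a tail-dominated
histogram has no stable baseline to read.

# Preferential interaction coefficients

Γ_ion(r) = N_ion(r) − N_H2O(r) · N_ion,bulk/N_H2O,bulk with cumulative
counts in 0.02 nm bins of minimum-image distance from the mass-weighted
solute centre (orthorhombic boxes only; radii beyond half the box edge are
an error). The bulk shell defaults to 2.5–3.38 nm, scaled proportionally
with a warning when the box is not 7 nm. The normalization ratio is
evaluated **per frame** inside `gammaIon()`, so its sampling noise enters
the frame-to-frame scatter and the reported SEM covers it; `bulkRatio()`
separately reports the frame-averaged ratio. With a list of frame sets the
SEM is taken across replicate means (the multi-replicate trajectory layout);
a single frame set uses frame-to-frame scatter, which is valid for the
generator's frames because they are independent equilibrium draws — for
time-correlated MD frames, pass replicates. Γ_salt = ½(Γ_an + Γ_cat − |Z|)
and profile differences propagate SEMs in quadrature.

One statistical limitation is intrinsic: at small r, expected ion counts are
rare-event (water density is ~30× ion density at 500 mM), and whenever all
frames happen to contain zero ions inside a window where waters already
number ≳10, the normal-theory |Γ|/SEM statistic exceeds 3 regardless of how
many frames are available. SEM-based null tests are therefore meaningful
only on radii with adequate counting statistics; the test suite gates them
at a pooled ion count of 10 (the usual sparse-histogram validity rule).
Production MD sampling (hundreds of ns across replicates) is orders of
magnitude denser and does not sit in this regime.

Site–site g(r) normalizes pair-distance histograms by the ideal-gas shell
expectation N_A N_B 4π r² dr / V; its cumulative integral reproduces the
cumulative counts, which the tests assert.

# Spin-down thermodynamics

supernatant = min(total, c_sat): the breakpoint is found by a 1-D grid
search with local refinement (derivative-free, robust to the kink), with a
bootstrap CI over points. A series whose best fit is the identity line has
shown no saturation and errors out. Transfer free energies use
ΔΔG = RT ln(ratio) with T defaulting to 293.15 K; note that a 4-fold
abundance ratio gives 0.81 kcal/mol at this temperature.

# Synthetic generators: what they emulate, and what they do not

* **Brownian suspensions** — Gaussian increments with per-axis variance
  2 D dt, D from Stokes–Einstein per particle; heavy-tailed cluster sizes as
  a monomer + truncated-power-law mixture (exponent configurable; the real
  distributions are only known to be heavy-tailed). No hydrodynamic
  interactions.
* **Scattered intensity** — coherent field sums with amplitudes ∝ d³
  (Rayleigh); no Mie corrections, no detector afterpulsing.
* **Photon streams** — emitter diffusion integrated at 10 µs steps, Poisson
  emission within steps through a 3D-Gaussian focus, exponential microtimes
  wrapped into the PIE windows, uniform-microtime background, optional
  crosstalk. No blinking, bleaching, or detector dead time (dead time
  defaults to absent; acquisition bin widths are configuration, not
  physics).
* **Scan traces** — Poisson transit counts with the mean implied by the true
  concentration through the flux relations, lognormal peak amplitudes on a
  Poisson baseline.
* **Solvation boxes** — fixed species counts from the salt concentration and
  box volume (realized densities exact by construction), waters uniform,
  ion positions rejection-sampled from a radial weight w(r) that must be 1
  in and beyond the bulk shell (validated; violating it would bias the
  local-bulk normalization). Frames are independent draws, not dynamics —
  Γ estimation needs only equilibrium configurations. Charge neutrality adds
  |Z| counter-ions.

Passing round-trip tests on these generators shows the *estimators* are
correct and calibrated under the stated statistical models; it does not
certify behaviour under real-data pathologies the generators omit
(aggregating dyes, detector artifacts, flow inhomogeneity, correlated MD
frames).

# Problem sizes in the test suite

The suite runs monodisperse DLS round trips at 150 particles × 3×10⁴ steps,
FCS round trips on 8–10 s photon streams (~3×10⁵ photons), burst
false-positive sweeps over 100 seeded 10 s backgrounds, solvation boxes of
3000 waters × 20 frames, and 100-series c_sat sweeps. These sizes were
chosen so each stochastic check sits several standard errors inside its
acceptance band while the whole suite stays fast enough to run on every
change.
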