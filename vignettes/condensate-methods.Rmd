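---
title: "Models and methods behind condensateR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind condensateR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

condensateR quantifies the assembly state, molecular mobility and DNA
binding of nuclear transcription-factor condensates, with the
CO/NF-YB2/NF-YC9/*FT* system of *Arabidopsis* flowering control as the
motivating application. This vignette describes each model, its
assumptions, the tunable parameters, and the design decisions taken where
the methodology was genuinely open. It states no empirical results beyond
what the package's tests and `scripts/acceptance.R` themselves compute.

## Condensate assembly metrics

**Spatial clustering index (SCI).** For an intensity profile sampled along
a 3 µm-wide line across a nucleus, SCI is the mean of the top 5% of values
divided by the mean of the bottom 5%. A uniform signal gives 1; bright foci
raise the ratio. Tails have `max(1, floor(0.05 n))` values (ties broken by
stable sort order), so profiles need at least 20 samples. SCI is invariant
to multiplicative rescaling and decreases monotonically toward 1 under
additive offsets; a non-positive bottom-tail mean is rejected as a
degenerate background. Line profiles are extracted by bilinear
interpolation at pixel pitch, averaging across the line width
perpendicular to its axis (0-based coordinates, pixel centres at
integers).

**Signal variance and three-state classification.** The per-nucleus scalar
is `(SD/mean)^2` of pixel intensities, with the population SD
(divide-by-n) convention, as befits a fixed pixel population rather than a
sample. Nuclei classify as *diffuse* (variance < 0.21), *spherical
condensate* (0.21–0.45, a closed interval at both boundaries, matching the
printed middle bin) or *irreversible aggregate* (> 0.45).

By default the statistic is computed over a thresholded foreground that
stands in for interactive particle selection: Otsu's threshold is computed
on `log1p`-transformed intensities, connected components of fewer than 4
pixels are dropped, and the variance is taken over the *original*
intensities of the surviving region. The log transform is the load-bearing
choice. Otsu's criterion on raw intensities provably fails here: whenever a
background/nucleoplasm/foci image is heterogeneous enough for its
nucleus-level variance to reach the 0.21 bin boundary, the between-class
variance of the "isolate the brightest foci" split exceeds that of the
background/nucleus split, so a raw-intensity threshold returns only the
foci and compresses the statistic to ~0.1 regardless of focus amplitude —
no aggregate could ever score above 0.45. Fluorescence intensity
histograms are approximately log-normal, and on the log scale the dominant
bimodality is dark background versus signal, so the threshold selects the
nucleus footprint (the "particle"), which is the region the published
variance regime must refer to. Computing the variance over
the whole provided mask remains available as `method = "whole"`.

**Mixture fitting.** Distributions of per-nucleus variances are fitted
with a univariate Gaussian mixture (default k = 3) by
expectation–maximisation: 10 seeded restarts with means initialised from
random data points, convergence at a relative log-likelihood change below
1e-8, an SD floor of 1e-8 times the data scale against spike collapse,
and components reported in ascending mean order. The per-iteration
log-likelihood trace is retained (it must be non-decreasing, and the test
suite checks this), and crossing points of adjacent weighted component
densities are reported as data-driven class boundaries. Coincident
components are flagged as degenerate, since their weights are then not
identifiable. Mixtures are fitted on raw variances, not logs; a
histogram-peak variant was considered and rejected because binning adds a
tuning parameter without improving identifiability.

## FRAP analysis

Traces carry a bleached ROI and an equal-sized unbleached reference ROI.
Normalisation divides bleach by reference — cancelling acquisition
photobleaching exactly when it affects both ROIs equally — then applies
*full-scale* normalisation: prebleach mean to 1, first post-bleach frame
to 0. The alternative (preserving bleach depth) was rejected so that the
fitted plateau reads directly as a recovery-plateau/mobile-fraction proxy
comparable across traces.

Recovery is fitted as a one-phase decay `F(t') = plateau (1 − e^{−k t'})`
(offset fixed at 0; a free-offset variant would trade bias for variance on
short traces and is deliberately omitted) by bounded nonlinear least
squares: plateau in [0, 1.5], rate in (0, 10] 1/s, initial guesses from the
last-quartile mean and `ln 2 / t_halfmax`. At least 8 post-bleach frames
are required; flat traces yield plateau ≈ 0 with the rate flagged
unidentifiable. Mobility classes: plateau ≥ 0.4 → *liquid*, else
*slow-diffusive*. The 0.4 cutoff is a package design parameter (exposed as
`plateauCutoff`): the underlying FRAP observations distinguish strong recovery from
minimal molecular exchange only qualitatively, and any cutoff
separating recovery plateaus near 0.8 from those near 0.1 yields the same
calls; 0.4 sits midway with maximal margin. A plateau exactly at the
cutoff is liquid. Acquisition presets mirror the two protocols: 1 s frames
for 60 s (in vivo), 30 s frames for 10 min (in vitro).

## Bivalent-analyte SPR kinetics

The bivalent analyte model describes an analyte with two binding modules:

d[AB]/dt  = ka1·C·F − kd1·[AB] − ka2·[AB]·F + kd2·[AB2]
d[AB2]/dt = ka2·[AB]·F − kd2·[AB2],   F = Rmax − [AB] − w·[AB2]

with analyte concentration C during the 60 s association phase and 0
during the 300 s dissociation phase; response = [AB] + [AB2]. The doubly
bound species weight is w = 1 (each captured analyte contributes once
regardless of valence, the standard convention; configurable). `ka2` is in
surface-response units (1/(RU·s)), as conventional. Bulk-shift and drift
terms are omitted — double-referenced sensorgrams are assumed. Integration
uses a stiff-safe ODE solver in two phase segments.

Global fitting estimates all five parameters in log space over every curve
of a dilution series simultaneously, with seeded multi-start (log-uniform
over four decades per rate, or log-normal perturbations of a supplied
initial guess). The headline quantity is the first-order Kd = kd1/ka1.
Identifiability deserves a caveat: with 1% multiplicative noise the global
optimum of the noisy objective genuinely moves, because kd1 trades off
against the rebinding parameters; uniform weighting then recovers Kd only
to within roughly 5–20%. Inverse-response weighting (residuals scaled by
1/response, floored at 2% of the maximum) is the statistically appropriate
choice under multiplicative noise and tightens recovery; the pipeline uses
it whenever the noise model is multiplicative. Fewer than three
concentrations triggers an ill-conditioning warning. The preset rate
constants place the first-order Kd at 50 nM with slow dissociation (CO
homotypic) and 20 nM with faster dissociation (NF-YB2 homotypic), the
affinities reported for those interactions; the dilution series is a
two-fold, six-point series from 256 nM.

## Single-particle analysis

Spot detection is Laplacian-of-Gaussian: convolution with a
scale-normalised LoG kernel matched to the expected sigma (default 1.5 px),
local maxima above a quality threshold (default: median + 5 MAD of the
response), non-maximum suppression within 2 sigma, and sub-pixel
refinement by separable quadratic interpolation. The tracking tool used in the original imaging workflow is a GUI; LoG is the equivalent detector of choice
and its quality threshold is config-exposed because the original values
are unreported. Total intensity is the pixel sum in a disk of radius
3 sigma minus the annulus-median background times the disk area;
border-clipped disks are flagged and excluded from statistics by default.
Colocalization uses mutual-nearest-neighbour matching within a radius,
reporting matched fraction relative to the first channel — the source
shows overlays only, so a symmetric, parameter-light rule was chosen.

## Reduced oligomer-DNA binding simulation

The simulation reproduces the composition and contact conventions of the
study system at drastically reduced resolution: one bead per CO-NF-Y
binding unit and ~10 bp per DNA bead (the packaged 169-nt CORE-containing
promoter fragment maps to 17 beads). Complexes of oligomer state s = 1-5
are linear chains of unit beads joined by soft tethers; when the unit
total is not divisible by s the remainder enters as monomers. The full
composition is 60 units, 15 chains, 120 nm box; the desk-scale default
keeps the study's 4:1 unit:chain ratio and approximately its unit
concentration at 32 units, 8 chains and a 76 nm box, a size at which
bound-count statistics converge on one CPU.

Energies are in kT, lengths in nm, time in diffusive units (unit
mobility); the 10 fs / 0.01 ps^-1 / 300 K settings of the residue-resolution
model this simulator reduces are provenance, not literally integrated. The geometry encodes three
load-bearing physical choices, each of which proved necessary during
development:

* **Stiff DNA.** Chains carry a cosine bending potential
  (`kAngle = 20` kT/rad^2, persistence length `kAngle x bond length`
  ~ 68 nm, i.e. the 57-nm fragment behaves as a nearly straight double
  helix). Without it a freely jointed chain crumples and its four motif
  beads collapse into a single blob: site geometry, site exclusivity and
  any oligomer-state dependence are lost.
* **Clustered motifs, spacer-matched tethers.** The four motif beads sit
  at uniform 2-bead (~20 bp, 6.8 nm) spacing centred on the fragment - a
  tandem cis-element block - and the intra-complex tether rest length
  equals that spacing (the spacer-matching condition). With sites spread
  over the whole fragment (~14-17 nm apart) the local concentration of a
  tethered arm at the neighbouring site, which scales as `1/(4 pi d^2)`,
  barely exceeds the bulk concentration and multivalent enhancement
  vanishes at any well depth that still equilibrates.
* **Strict site exclusivity.** Units repel within 2.4 nm (twice the
  contact cutoff; `kRep = 60` kT/nm^2), so two units cannot occupy one
  motif well: one complex footprint per CORE. Units and non-motif DNA
  beads do not otherwise interact; because unit-unit interactions are
  translation invariant, unit positions stay uniformly distributed when
  the well depth is zero, making the binding-off control exactly
  comparable to the analytic random-contact expectation
  `units * 4 * (4/3) pi rc^3 / V`.

The unit-motif attraction is `U(r) = -eps (1 - (r/rc)^2)^2` within
rc = 1.2 nm, with `eps = 9` kT and semi-flexible tethers
(`kUnit = 3` kT/nm^2) as defaults - calibrated once, before any acceptance
run, into the regime where single-site occupancy is partial (~5% per
site), arms exchange many times per trajectory, and multivalent bridging
is strong enough that mean bound counts rise with oligomer state; tether
stiffness is the lever that sets bridging strength without deepening the
wells (which would slow exchange). Dynamics are overdamped Langevin,
`dx = F dt + sqrt(2 T dt) eta`, dt = 0.008, with periodic wrapping and
minimum-image distances everywhere. Gaussian noise comes from a
xoshiro256++/Box-Muller generator seeded from R's RNG stream, so
`set.seed()` fixes trajectories bit-for-bit. A Metropolis Monte-Carlo mode
(unit moves only, DNA frozen) provides an equilibrium cross-check; the
test suite verifies its occupancy of a single unit against the two-state
Boltzmann ratio computed by direct quadrature of the well.

A unit is *bound* to a chain when its minimum-image distance to any motif
bead of that chain is <= 1.2 nm (closed boundary). Bound counts are
tallied per chain over the second half of each trajectory (first half
discarded as equilibration); the standard error of the mean uses batch
means over frames to respect autocorrelation, and the binding-off control
samples frames four times more densely because its contacts are rare.
The oligomer-state scan runs states 1-5 at 3 seeds each (default 2
million steps, 16000 diffusive time units per run), keeping the DNA-chain
geometry identical across states for a given seed index so that state
comparisons are paired, and reports the Spearman correlation of state
versus mean bound count - the avidity statistic. Only the direction and ordering of this trend is meaningful;
absolute bound-count histograms at desk scale are not comparable
across resolutions, and the package does not attempt to reproduce them. The
multi-engaged states of the larger oligomers are the slowest-relaxing
degrees of freedom, and their residual seed-to-seed variability is the
main caveat when interpreting a single three-seed scan.

## Synthetic-data generators

Every generator is a pure function of its arguments including the seed
(RNG state is saved and restored around each call), and returns ground
truth alongside the data.

**Nuclei.** A diffuse nucleus is a smooth ellipse (≈22% × 18% of the image
side, small seeded eccentricity and rotation) of constant intensity with
7% Gaussian read noise; a spherical-condensate nucleus dims the
nucleoplasm to 0.9× and adds 7–8 Gaussian foci (σ ≈ 0.25 µm, amplitudes
3.1–3.4× the reference intensity, placed ≥ 3.5 σ apart so overlaps do not
inflate the variance); an aggregate nucleus has a 0.6× nucleoplasm with
1–3 large irregular blobs built from 5–9 overlapping flat-top discs of
log-uniform amplitude 4–7×. Amplitudes and areas were calibrated once
against the foreground-variance classifier so that each class lands in its
variance bin for at least 95% of seeds (the suite checks 200 seeds per
class); they are not tuned thereafter. Noise is additive Gaussian (a read-
noise proxy); Poisson shot noise is omitted because the variance statistic
only needs a controllable SD/mean, and absolute intensity units are
arbitrary: no absolute intensity scale or camera gain is modelled.
Populations draw labels multinomially from a 3-simplex of class weights;
presets carry the measured mixtures (CO alone 16/36/48%; triple
co-expression 40/60/0%, the remainder being diffuse signal).

**FRAP traces.** Prebleach frames at normalised 1; full bleach to 0; post-
bleach recovery `plateau (1 − e^{−rate t'})`; both ROIs multiplied by
`e^{−λt}` acquisition bleaching; additive Gaussian noise. Mixture presets:
slow-diffusive class plateau 0.1 (rate 0.05/s), liquid class plateau 0.8
(rate 0.1/s), with slow fractions 0.76 (CO alone) and 0.05 (triple
complex).

**Sensorgrams.** Two-fold dilution series simulated from the bivalent
model (60 s + 300 s phases) with additive and/or multiplicative Gaussian
noise; zero noise reproduces the forward model exactly.

**Particle fields.** Sub-pixel-positioned 2-D Gaussian spots of known
integrated intensity on a flat background; fields that cannot satisfy the
minimum spot separation are flagged crowded. Integrated image intensity
equals background plus the summed truth intensities to within 1%.

What passing on these synthetics does *not* show: robustness to uneven
illumination, shot-noise statistics, out-of-focus light, nucleus
segmentation error (masks are generated, not detected), reaction–diffusion
FRAP behaviour, mass-transport-limited SPR, or sequence-specific binding
energetics. The generators emulate the statistical structure each
estimator consumes, not the full physics of the instruments.

## Problem sizes and reproducibility

Round-trip experiments run at the study designs: n = 75 nuclei for
assembly classification, n = 50 traces for FRAP mobility, six-point
dilution series for SPR, and 5 states × 3 seeds for the binding scan at
desk scale. At those sizes the honest yardsticks are the multinomial and
binomial 95% confidence intervals of the designs themselves, and the test
suite asserts recovery at exactly those tolerances. Every experiment
report embeds its resolved configuration, seed and package version, and
re-running a report's configuration reproduces its summary statistics
exactly.
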