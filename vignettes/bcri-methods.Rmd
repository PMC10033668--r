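---
title: "Brightness-calibrated ratiometric imaging: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brightness-calibrated ratiometric imaging: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcri)
```

## The problem

Confocal images of fluorescently labeled membrane receptors report photon
counts, not molecule numbers. Comparing labeling reactions across cells —
for example, the yield of a bioorthogonal click reaction on a receptor
carrying a non-canonical amino acid — requires the fraction of receptors
that carry the dye, which pixel intensities alone cannot give: each
fluorophore has its own brightness, maturation efficiency and excitation
response.

Brightness-calibrated ratiometric imaging (BCRI) closes this gap. The
molecular brightness of each label (counts per particle, CPP, in kHz) is
measured by fluorescence correlation spectroscopy (FCS) in solution under
the same optical settings used for imaging. Membrane pixel counts are then
converted to absolute particle numbers, and per-cell ratios between
channels become label stoichiometries: the click efficiency
CE = N_click/N_ref and the ligand occupancy N_ligand/N_ref, with the
eGFP-tagged receptor pool as reference.

## The calibration chain

1. **Observation volume.** A free dye with a literature diffusion
   coefficient gives the beam waist via `w0 = sqrt(4 D tau_D)`
   (`beam_waist_from_standard()`); the axial elongation z0 = AR·w0 with
   AR fixed to 6 completes the 3D Gaussian volume
   V_eff = pi^(3/2) w0² z0 and its equatorial cross-section
   A_eff = pi w0 z0 (`effective_volume()`). Reference coefficients
   (400, 370, 426 µm²/s at 25 °C for the three standards) are adjusted to
   the focus temperature (28 °C under laser heating) by Stokes–Einstein
   scaling `D(T₂) = D(T₁)·(T₂/T₁)·(η₁/η₂)` with a built-in water-viscosity
   correlation (Vogel–Fulcher–Tammann form, accurate to ~1% over
   0–100 °C). The literature source for the temperature adjustment does
   not print a formula; Stokes–Einstein scaling is the standard FCS
   practice and reproduces the quoted 25→28 °C shift.
2. **Excitation power density.** `P0 = 2 P_tot/(pi w0²)`
   (`power_density()`); repeated power measurements are tracked by an
   ordinary least-squares line in time (`laser_ageing_trend()`) because
   laser output decays slowly over months. Unweighted least squares is
   used throughout these instrument trends — nothing in the data
   motivates a weighting scheme.
3. **Molecular brightness.** Solution FCS curves are fitted with the
   single-species 3D model (`model_solution_acf()`); CPP = F/N. Because
   CPP is linear in excitation power over the working range,
   `brightness_vs_power()` interpolates the brightness at the power
   density of each image and warns on extrapolation.

## Correlation models

Membrane autocorrelation curves recorded in the presence of freely
diffusing ligand are described by a two-component model with triplet
blinking: a 3D term for the solution species, a 2D term for the membrane
species, and the exponential triplet factor. Fit bounds follow standard
practice for this instrument class: triplet time 1–100 µs, 3D diffusion
time 100 µs–3 ms, 2D diffusion time 3–300 ms, AR fixed to 6.

A note on the functional form: multiplying a 3D component that carries a
factor f_3D with a 2D component that carries (1 − f_3D) yields a zero-lag
amplitude f_3D(1 − f_3D)/N, which contradicts the interpretation of N as
the total particle number and breaks CPP = F/N. `model_membrane_acf()`
therefore combines the two diffusing components **additively**,
G = (1/N)·G_T·(G_3D + G_2D), which satisfies G(0) = 1/N; the product form
remains available behind `combine = "product"` for comparison but is
never used in fitting.

Fitting (`fit_acf()`) is bounded Levenberg–Marquardt least squares with
scale parameters in log space, deterministic bound-midpoint starts, and
deterministic jittered restarts if convergence is poor. Unweighted
residuals are the default; multi-run SD weights can be supplied. On
noiseless model curves all six free membrane-model parameters are
recovered to better than 1e-6 relative error from midpoint starts — the
basis of the generator-as-oracle tests.

Run curation (`curate_runs()`) discards runs whose fitted linear
intensity drift exceeds 10% of the mean or that contain bins more than
5 SD above the mean. Both thresholds are explicit configuration values;
the underlying experimental rule is qualitative ("slow drifts or
spikes"), so the defaults were chosen once to reject the artifacts the
rule targets while keeping Poisson-limited traces, and are not tuned.
Datasets with fewer than two surviving runs per channel are refused.

For dual-color cross-correlation (`fccs_relative_amplitude()`),
amplitudes are taken from 2D-model fits; autocorrelation amplitudes are
corrected for uncorrelated background by (F/(F−B))², the cross amplitude
by the product of both channel factors, and spectral cross-talk (1%
green→red by default) is removed by subtracting the bleed-through
covariance:
G_x = (G_x' F_g F_r − κ G_g F_g²)/((F_r − κ F_g) F_g).
The published method chain cites these corrections without restating the
formulas; the forms above are exact for the measured-covariance model and
are validated against the particle simulator, where background and
bleed-through are injected and must cancel. Which autocorrelation serves
as denominator is configurable; for "fraction of the reference pool
carrying the second label" the red (second-label) autocorrelation is the
appropriate denominator, and the ratio is additionally normalized to a
fully double-labeled control in the recovery studies.

## Image quantification

Segmentation applies Otsu's threshold to the reference (eGFP) channel
after light Gaussian smoothing (sigma = 1 px, configurable; the original
segmentation script's preprocessing is not public, so the default is the
mildest stabilizer that makes the threshold robust on shot-noise-limited
images). Connected components use 8-connectivity and the largest
component becomes the membrane mask, which is shared across channels:
chromatic displacement on a calibrated instrument is sub-pixel, and
`register_channels()` confirms this by reporting the best integer shift
(ties resolve to no shift).

`pixels_to_particles()` implements the BCRI chain: mean masked counts /
dwell time → count rate F; F / CPP → particles; division by (1 − p_nf)
corrects non-fluorescent labels (p_nf = 0.20 for eGFP maturation, 0.32
for the partially labeled ligand conjugate). Receptor density is
N_ref/A_eff. Pixels whose instantaneous count rate exceeds 1 MHz are
counted as saturation flags and reported, never silently dropped.
Occupied-state click efficiencies measured at partial occupancy F_occ are
rescaled by `rescale_ce_occupied()`:
CE_occ = (CE′ − (1 − F_occ)·CE_free)/F_occ.

## Binding and kinetics statistics

`hill_fit_mc()` fits θ(c) = A/(1 + (c0/c)^n) + A0 with c0 in log space
and n fixed to 1 by default (1:1 binding; free n is opt-in), then
propagates both measurement uncertainties by refitting 10,000 resamples
in which every point is perturbed by its σ_c and σ_θ (both axes by
default — a flag restricts perturbation to one axis). Reported
parameters are Monte-Carlo means ± SDs. Kinetics use a rising double
exponential with multi-start bounded least squares and an
identifiability flag when the rate ratio falls below 3; the
concentration dependence of labeling yield uses a two-hyperbola
saturation CE(c) = B1·c/(K1+c) + B2·c/(K2+c). The published figure calls
this a "sublinear two-state saturation" without printing the form; the
two-hyperbola sum is the simplest two-state saturating function and is
implemented as the default with the fitter pluggable.

Occupancy histograms are decomposed into 1- or 2-component Gaussian
mixtures by EM (via mclust) with model choice by AICc — the bimodality
claim needs a selection rule, and the small-sample correction matters at
typical cell counts. Welch's t-test and the Monte-Carlo Pearson
correlation (plain r/p plus mean ± SD over 10,000 noise-injected
resamples) wrap the standard estimators with explicit seeds.

## Trajectory post-processing

Coordinate ensembles (multi-model PDB) support: average structures after
rigid-body superposition onto the first frame (with optional 10-block
sub-trajectory averages); B-factors B = (8π²/3)·MSF of peptide-bond
atoms (N, CA, C, O — renamed N, C2, C3, O3 in the BCN pseudo-residue)
about the ensemble average; the catchbox census of a
13.5 × 4.5 × 3.5 Å cuboid tied to the C14→C15 triple-bond axis; ring
orientation as spherical angles of the normal
n = (C15−C11) × (C14−C18); and domain-wise superposition RMSD profiles.

Design choices that the source description leaves open:

* **Catchbox frame.** Only the local x-axis (along the bond) is fixed by
  construction. The y-axis is taken as the component of the ring-centroid
  → bond-midpoint vector orthogonal to x, and z = x × y — deterministic
  and chemically meaningful (y points out of the ring). Membership tests
  are validated against a brute-force six-half-space oracle on 10⁴
  random points.
* **Angle reference frame.** Ring angles are computed after superposing
  frames onto the ensemble average, so they describe rotor motion in a
  molecular frame rather than laboratory tumbling; a flag disables the
  superposition.
* **KDE.** The 2D kernel density over (azimuth, polar) uses a single
  isotropic Gaussian bandwidth chosen by leave-one-out cross-validated
  grid search over 100 log-spaced values in [0.1, 10]°, with eight
  log-spaced contour levels and a 10⁻⁶·⁵ display floor. Angles are
  treated as Euclidean coordinates (no periodic wrap), matching the
  estimator used for the published maps; a wrapped variant would only
  matter for densities near ±180°. The evaluation grid extends four
  bandwidths beyond the data so the density integrates to 1.
* **Superposition.** `superpose_and_rmsd()` pairs Cα atoms by global
  sequence alignment (BLOSUM62) and superposes with iterative outlier
  rejection (5 cycles, 2.0 × RMSD cutoff), mirroring the
  molecular-graphics `align` procedure; `cycles = 0` gives plain Kabsch.
  Anchor RMSDs (RMSD_0..3 for ±0..3 neighbors) are computed without
  re-fitting. Domain conventions follow the receptor architecture:
  D1 = residues 2–96, D2 = 98–196 (mature numbering; construct numbering
  is +6 and `convert_numbering()` converts).
* **B-factor estimator.** Superposing each frame onto the average with
  all atoms absorbs the rigid-body projection of the noise, lowering MSF
  by a fraction ≈ 6/(3·N_atoms). Tests of the 8π²σ² law include this
  term in their tolerance rather than hiding it.

Solvation-free-energy tables are consumed, not computed
(`read_sfe_table()`): per-site values more than 3 SD from the site mean
are disregarded as failed continuum-solvation runs, and the remaining
rows aggregate to site means ± SEM. `ce_structure_correlation()` then
correlates per-site CE (or |ΔCE|) with RMSD_0 or ΔG_solv through the
Monte-Carlo Pearson machinery, and `differential_ce()` supplies the
secondary-axis scaling that equates the average spread (SD across sites)
of the two quantities.

## What the simulators emulate — and what they do not

`simulate_fluctuation_traces()` propagates Brownian particles (2D
membrane and/or 3D solution species) through a 3D Gaussian detection
profile with periodic boundaries in a box ≥10 w0 (avoiding depletion)
and a time step capped at w0²/(100 D)·25; photon counts are Poisson per
bin, with optional uncorrelated background, green→red bleed-through, and
two-state triplet blinking. The point-spread function in
`simulate_cell_image()` is an isotropic Gaussian (0.55 px), annuli stand
in for equatorial membrane cross-sections, and expected membrane counts
follow density × A_eff × labeled fraction × CPP × dwell time.
`simulate_titration()` draws each occupancy point as the mean of
`n_cells` per-cell values (per-cell SD 0.05) and each concentration as
the mean of six FCS runs (10% per-run CV), while reporting the per-cell
SD and per-run CV as the point uncertainties — the convention of error
bars that show population spread. This is why the Monte-Carlo parameter
SDs, which are driven by the reported uncertainties, conservatively
cover the true dissociation constant in well over 90% of repetitions.

Not emulated: detector afterpulsing and dead time, refractive-index
mismatch, bleaching, 3D cell geometry, intracellular compartments, and
raw photon-stream correlation. Closed-loop tests therefore demonstrate
the correctness of the estimators under the stated noise model, not
robustness to every instrument artifact.

## Problem sizes and numerical conventions

Units are µm, seconds, kHz and mol/L internally, with converters at the
I/O boundary. All stochastic routines take explicit seeds and are
bit-reproducible. The recovery studies shipped with the package use
problem sizes chosen to give decisive statistics at desk scale: 100
random parameter draws for the noiseless refit oracle; 50 seeded
titration repetitions at 2,000 Monte-Carlo resamples (the full fits use
10,000); 30 simulated cells spanning densities 50–2000 µm⁻²; five seed
pairs of 100-particle, 100 s dual-color traces for the co-diffusion
readout; 2,000-frame jitter ensembles for the fluctuation law. Degenerate
inputs fail loudly: constant images have no Otsu threshold, empty masks
and non-positive calibration inputs are errors, collinear ring vectors
are flagged and excluded, and fits report convergence and at-bound flags
instead of failing silently.

## Known limitations

* The cross-talk correction assumes a single dominant bleed-through
  direction (green into red), appropriate for spectrally ordered dye
  pairs.
* The Gaussian-PSF image model ignores out-of-focus light; BCRI ratios
  are robust to this (both channels share the mask), absolute densities
  less so.
* Sequence-alignment pairing assumes the two structures differ by point
  substitutions, not indels, within the aligned domain.
* The KDE treats angles as Euclidean; maps with substantial density at
  the azimuth seam should use a wrapped kernel.
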