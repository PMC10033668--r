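# bcri — brightness-calibrated ratiometric imaging

Quantifying a labeling reaction on a receptor at the surface of a living
cell means answering a stoichiometric question with a microscope: *what
fraction of the receptors actually carries the dye?* Pixel intensities
cannot answer it — every fluorophore has its own brightness, maturation
efficiency and power response. `bcri` implements the full
brightness-calibrated ratiometric imaging (BCRI) workflow that converts
confocal photon-count images into absolute molecule numbers and label
ratios, together with the fluorescence (cross-)correlation spectroscopy
(FCS/FCCS) models behind the calibration, the binding and kinetics
statistics applied downstream, and the molecular-dynamics trajectory
analyses that connect labeling yield to local protein structure.

The package is written for quantitative fluorescence microscopists and
computational biophysicists working on site-specific (click) labeling of
membrane receptors, such as interleukin-4 receptor alpha carrying the
non-canonical amino acid BCNK.

## The core quantities

* **Molecular brightness**: CPP = F/N (kHz per particle), from FCS fits of
  G(τ) = (1/N)(1 + τ/τ_D)⁻¹(1 + τ/(AR²τ_D))⁻¹ᐟ² in solution.
* **Observation volume**: w0 = √(4 D τ_D) from a standard dye,
  V_eff = π³ᐟ² w0² z0, membrane cross-section A_eff = π w0 z0.
* **Pixel → particles**: N = (mean counts / dwell time) / CPP / (1 − p_nf),
  with p_nf the non-fluorescent label fraction (0.20 for eGFP, 0.32 for
  the partially labeled ligand conjugate).
* **Click efficiency / occupancy**: CE = N_click/N_ref,
  occupancy = N_ligand/N_ref, density = N_ref/A_eff.
* **Membrane FCS model**: G = (1/N)·G_T·(G_3D + G_2D) with triplet factor
  G_T and 3D/2D diffusing fractions; bounds τ_T ∈ [1, 100] µs,
  τ_3D ∈ [0.1, 3] ms, τ_2D ∈ [3, 300] ms, AR = 6.
* **Binding**: Hill law θ = A/(1 + (c0/c)ⁿ) + A0 fitted by a
  10,000-resample Monte-Carlo procedure that perturbs both axes with the
  measured uncertainties.
* **Structure**: catchbox census around the BCNK triple bond, ring-normal
  orientation maps (LOO-CV kernel density), B = (8π²/3)·MSF, and
  domain-wise Cα superposition with anchor RMSD₀..₃ profiles.

## Worked example

Calibrate the detection volume from a standard dye, quantify a simulated
three-channel cell, and fit a titration:

```r
library(bcri)

dye   <- standard_dye("ATTO655-COOH", D_ref = 426, T_ref = 25)   # um^2/s
w0    <- beam_waist_from_standard(dye, tau_D_st = 2.6e-5, T_meas = 28)
calib <- effective_volume(w0, AR = 6, laser_line = 633)
calib
#> Focal volume calibration (633 nm)
#>   w0 = 0.2188 um, z0 = 1.3126 um (AR = 6.00)
#>   V_eff = 0.3498 um^3 (= 0.3498 fL), A_eff = 0.9021 um^2

cpp  <- c(reference = 4, click = 10, ligand = 12)     # kHz, from FCS
p_nf <- c(reference = 0.20, ligand = 0.32)
sim  <- simulate_cell_image(density = 400, ce = 0.19, occupancy = 0.5,
                            calib = calib, cpp = cpp, p_nf = p_nf, seed = 5)
q <- quantify_cell(sim$channels, list(reference = calib),
                   cpp = cpp, p_nf = p_nf, cell_id = "cell_1")
sprintf("CE = %.3f, occupancy = %.3f, density = %.0f /um^2",
        q$CE, q$occupancy, q$density)
#> "CE = 0.189, occupancy = 0.497, density = 393 /um^2"
```

The cell was simulated with a true click efficiency of 0.19, occupancy
0.5 and 400 receptors/µm²; the pipeline recovers 0.189, 0.497 and
393 µm⁻² from Poisson-limited photon counts — the ratios are accurate
because both channels share the membrane mask and each is divided by its
own calibrated brightness.

```r
grid <- 10^seq(log10(1e-9), log10(1e-6), length.out = 8)   # mol/L
tit  <- simulate_titration(grid, c0 = 34e-9, seed = 11)
hill_fit_mc(tit, n_resamples = 10000, seed = 2)
#> Hill fit (Monte Carlo, 10000 resamples, seed 2)
#>   A   = 1.018 +/- 0.051
#>   A0  = -0.01923 +/- 0.043
#>   c0  = 3.18e-08 +/- 7.8e-09
#>   n   = 1 +/- 0
```

The dissociation constant (31.8 ± 7.8 nM) covers the simulated ground
truth of 34 nM within its Monte-Carlo SD; the SD is deliberately
conservative because the reported point uncertainties are per-cell and
per-run spreads, not standard errors of the mean (see the methods
vignette).

A thin command-line front end over the same functions ships in
`inst/cli/bcri.R` with subcommands `calibrate`, `fit-fcs`, `quantify`,
`titrate`, `kinetics`, `mixture`, `structure` and `simulate`.

## Package layout

* `R/calibration.R` — focal volume, power density, DOL, brightness lines
* `R/correlation.R` — ACF/CCF models, bounded fits, run curation, FCCS
  corrections
* `R/imaging.R` — segmentation, registration, pixel→particle conversion
* `R/binding.R` — Monte-Carlo Hill fit, kinetics, mixtures, Welch,
  Monte-Carlo Pearson, differential CE
* `R/structure.R` — trajectory averages, B-factors, catchbox, ring
  orientation, domain RMSD, SFE tables
* `R/synthetic.R` — seeded generators with ground truth for every
  analysis path
* `R/io.R` — TSV/CSV/YAML/TIFF round trips
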