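Package: bcri
Title: Brightness-Calibrated Ratiometric Imaging and Fluctuation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts confocal photon-count images into absolute molecular
    concentrations and label ratios using molecular brightness measured by
    fluorescence correlation spectroscopy (FCS). Implements focal-volume and
    excitation-power calibration, auto- and cross-correlation model fitting
    with run curation and amplitude corrections, membrane segmentation and
    pixel-to-particle conversion (click efficiency, receptor occupancy,
    surface density), Monte-Carlo Hill fits and labeling-kinetics statistics,
    and post-processing of molecular-dynamics coordinate ensembles (catchbox
    sampling, ring-orientation maps, B-factors, domain-wise backbone RMSD).
    Includes seeded simulators for fluctuation traces, multi-channel cell
    images, titrations, and jittered trajectories that provide ground truth
    for every analysis path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    bio3d,
    Biostrings,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
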