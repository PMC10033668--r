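# ---- synthetic data generators with known ground truth --------------------
# Every generator is deterministic given (config, seed) and records the
# truth it was built from, so each analysis path has a closed-loop oracle.

#' Configuration for a fluctuation-trace simulation
#'
#' Brownian particles (2D membrane and/or 3D solution species) diffuse
#' through a 3D Gaussian observation volume; photon counts per time bin
#' are Poisson draws around the sum of per-particle detection rates.
#'
#' @param species data.frame with one row per species: `n` (particle
#'   count), `D` (um^2/s), `dim` (2 or 3), `cpp_g`, `cpp_r` (brightness
#'   in each channel, kHz; 0 = unlabeled in that channel).
#' @param w0 beam waist (um). @param AR axis ratio (z0 = AR w0).
#' @param duration trace length (s). @param dt bin width (s).
#' @param box_factor lateral box size in units of w0 (periodic boundaries;
#'   default 10).
#' @param background_kHz named background count rates `c(green=, red=)`.
#' @param crosstalk_gr fraction of green signal bleeding into red
#'   (default 0).
#' @param triplet optional list(f_T, tau_T) two-state blinking applied to
#'   all species; requires dt <= tau_T / 5.
#' @param seed RNG seed (mandatory).
#' @return list of class `fcs_sim_config`.
#' @export
fcs_sim_config <- function(species, w0 = 0.25, AR = 6, duration = 60,
                           dt = 1e-3, box_factor = 10,
                           background_kHz = c(green = 0, red = 0),
                           crosstalk_gr = 0, triplet = NULL, seed) {
  stopifnot(is.data.frame(species),
            all(c("n", "D", "dim", "cpp_g", "cpp_r") %in% names(species)),
            all(species$n >= 0), all(species$D > 0),
            all(species$dim %in% c(2, 3)),
            w0 > 0, AR > 0, duration > 0, dt > 0, box_factor >= 4)
  if (missing(seed)) stop("fcs_sim_config: seed is mandatory")
  # time step must resolve the focal transit (box >= 10 w0 avoids depletion)
  tau_min <- w0^2 / (4 * max(species$D))
  if (dt > w0^2 / (100 * max(species$D)) * 25) {
    stop(sprintf("fcs_sim_config: dt = %g s too coarse for D = %g um^2/s (transit %g s)",
                 dt, max(species$D), tau_min))
  }
  if (!is.null(triplet)) {
    stopifnot(triplet$f_T >= 0, triplet$f_T < 1, triplet$tau_T > 0)
    if (dt > triplet$tau_T / 5) {
      stop("fcs_sim_config: dt too coarse to resolve triplet blinking")
    }
  }
  structure(list(species = species, w0 = w0, AR = AR, duration = duration,
                 dt = dt, box_factor = box_factor,
                 background_kHz = background_kHz,
                 crosstalk_gr = crosstalk_gr, triplet = triplet, seed = seed),
            class = "fcs_sim_config")
}

#' Simulate dual-channel fluctuation traces
#'
#' @param cfg an [fcs_sim_config()].
#' @return list with `green`, `red` (integer photon counts per bin), `dt`,
#'   `duration`, and `truth` (effective particle numbers per channel and
#'   per species in the Gaussian observation volume, expected count
#'   rates).
#' @export
simulate_fluctuation_traces <- function(cfg) {
  stopifnot(inherits(cfg, "fcs_sim_config"))
  set.seed(cfg$seed)
  n_bins <- floor(cfg$duration / cfg$dt)
  L <- cfg$box_factor * cfg$w0
  z0 <- cfg$AR * cfg$w0
  Lz <- cfg$box_factor * z0
  rate_g <- rep(0, n_bins)    # expected kHz per bin
  rate_r <- rep(0, n_bins)
  truth <- list(N_g = 0, N_r = 0, N_gr = 0, species = cfg$species)
  for (s in seq_len(nrow(cfg$species))) {
    sp <- cfg$species[s, ]
    if (sp$n == 0) next
    ndim <- sp$dim
    sd_step <- sqrt(2 * sp$D * cfg$dt)
    pos <- matrix(stats::runif(sp$n * 2, -L / 2, L / 2), ncol = 2)
    z <- if (ndim == 3) stats::runif(sp$n, -Lz / 2, Lz / 2) else rep(0, sp$n)
    # effective particle number in the Gaussian volume
    n_eff_lat <- sp$n * pi * cfg$w0^2 / L^2
    n_eff <- if (ndim == 3) n_eff_lat * sqrt(pi) * z0 / Lz else n_eff_lat
    if (sp$cpp_g > 0) truth$N_g <- truth$N_g + n_eff
    if (sp$cpp_r > 0) truth$N_r <- truth$N_r + n_eff
    if (sp$cpp_g > 0 && sp$cpp_r > 0) truth$N_gr <- truth$N_gr + n_eff
    if (!is.null(cfg$triplet)) {
      p_dark <- cfg$triplet$f_T
      k_off <- p_dark / cfg$triplet$tau_T * cfg$dt        # bright -> dark
      k_on <- (1 - p_dark) / cfg$triplet$tau_T * cfg$dt   # dark -> bright
      bright <- stats::runif(sp$n) > p_dark
    }
    chunk <- 2000L
    done <- 0L
    while (done < n_bins) {
      m <- min(chunk, n_bins - done)
      # brownian increments, cumulated inside the chunk
      mde <- matrix(0, sp$n, m)
      dx <- matrix(stats::rnorm(sp$n * m, 0, sd_step), sp$n, m)
      dy <- matrix(stats::rnorm(sp$n * m, 0, sd_step), sp$n, m)
      x <- pos[, 1] + t(apply(dx, 1, cumsum))
      y <- pos[, 2] + t(apply(dy, 1, cumsum))
      x <- ((x + L / 2) %% L) - L / 2
      y <- ((y + L / 2) %% L) - L / 2
      if (ndim == 3) {
        dz <- matrix(stats::rnorm(sp$n * m, 0, sd_step), sp$n, m)
        zz <- z + t(apply(dz, 1, cumsum))
        zz <- ((zz + Lz / 2) %% Lz) - Lz / 2
        mde <- exp(-2 * (x^2 + y^2) / cfg$w0^2 - 2 * zz^2 / z0^2)
        z <- zz[, m]
      } else {
        mde <- exp(-2 * (x^2 + y^2) / cfg$w0^2)
      }
      if (!is.null(cfg$triplet)) {
        for (j in seq_len(m)) {
          u <- stats::runif(sp$n)
          bright <- ifelse(bright, u > k_off, u < k_on)
          mde[, j] <- mde[, j] * bright
        }
      }
      contrib <- colSums(mde)
      idx <- (done + 1):(done + m)
      if (sp$cpp_g > 0) rate_g[idx] <- rate_g[idx] + sp$cpp_g * contrib
      if (sp$cpp_r > 0) rate_r[idx] <- rate_r[idx] + sp$cpp_r * contrib
      pos <- cbind(x[, m], y[, m])
      done <- done + m
    }
  }
  bg <- cfg$background_kHz
  bg_g <- if ("green" %in% names(bg)) bg[["green"]] else 0
  bg_r <- if ("red" %in% names(bg)) bg[["red"]] else 0
  rate_r_det <- rate_r + cfg$crosstalk_gr * rate_g   # spectral bleed-through
  counts_g <- stats::rpois(n_bins, (rate_g + bg_g) * 1000 * cfg$dt)
  counts_r <- stats::rpois(n_bins, (rate_r_det + bg_r) * 1000 * cfg$dt)
  truth$F_g_kHz <- mean(rate_g) + bg_g
  truth$F_r_kHz <- mean(rate_r_det) + bg_r
  list(green = counts_g, red = counts_r, dt = cfg$dt,
       duration = n_bins * cfg$dt, truth = truth, config = cfg)
}

#' Correlate intensity traces on a quasi-logarithmic lag grid
#'
#' Normalized fluctuation correlation
#' G(tau) = <dF_a(t) dF_b(t + tau)> / (<F_a><F_b>) computed by FFT and
#' averaged within logarithmically spaced lag bins (a multi-tau-style
#' grid). `a == b` gives the autocorrelation.
#'
#' @param a,b integer count traces (same length); `b` defaults to `a`.
#' @param dt bin width (s).
#' @param max_lag maximal lag (s); default duration/10.
#' @param points_per_decade lag-grid density (default 12).
#' @param channel,run_id metadata for the returned curve.
#' @return a [correlation_curve()]; `mean_intensity` is set from the
#'   trace (kHz).
#' @export
correlate <- function(a, b = a, dt, max_lag = NULL, points_per_decade = 12,
                      channel = "green", run_id = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 4)
  n <- length(a)
  if (is.null(max_lag)) max_lag <- n * dt / 10
  max_k <- min(n - 2, floor(max_lag / dt))
  if (max_k < 2) stop("correlate: trace too short for the requested lags")
  da <- a - mean(a)
  db <- b - mean(b)
  # linear cross-covariance via zero-padded FFT
  nfft <- stats::nextn(2 * n, 2)
  fa <- stats::fft(c(da, rep(0, nfft - n)))
  fb <- stats::fft(c(db, rep(0, nfft - n)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / nfft
  k <- 1:max_k
  cov_k <- cc[k + 1] / (n - k)
  G_all <- cov_k / (mean(a) * mean(b))
  # quasi-logarithmic binning of integer lags
  edges <- unique(round(10^seq(0, log10(max_k), by = 1 / points_per_decade)))
  lag_bin <- findInterval(k, edges)
  lags <- tapply(k * dt, lag_bin, mean)
  G <- tapply(G_all, lag_bin, mean)
  correlation_curve(as.numeric(lags), as.numeric(G), channel = channel,
                    mean_intensity = mean(a) / dt / 1000,
                    duration = n * dt, run_id = run_id)
}

#' Simulate a dual-color membrane FCCS experiment
#'
#' All particles carry the green (reference) label; a fraction
#' `double_fraction` additionally carries the red label and co-diffuses.
#' Traces are simulated, correlated, and reduced to the corrected
#' relative cross-correlation amplitude with [fccs_relative_amplitude()]
#' using the red autocorrelation as denominator, so that the ideal
#' readout equals the double-labeled fraction.
#'
#' @param double_fraction fraction of particles labeled in both channels.
#' @param n_particles total particles (default 100).
#' @param n_red_independent additional red-only particles that do not
#'   co-diffuse with the green pool (default 0; use to emulate a
#'   non-interacting membrane marker).
#' @param seed RNG seed.
#' @param duration trace length (s, default 100).
#' @param dt bin width (s, default 1e-3).
#' @param D membrane diffusion coefficient (um^2/s, default 0.5).
#' @param w0 beam waist (um, default 0.25).
#' @param cpp_g,cpp_r per-channel brightness (kHz).
#' @param background_kHz,crosstalk_gr forwarded to the simulator and then
#'   corrected for in the analysis.
#' @return list with `rel_cc` (corrected ratio), `fccs` (full
#'   [fccs_relative_amplitude()] result), `truth`.
#' @export
simulate_fccs_experiment <- function(double_fraction, n_particles = 100,
                                     n_red_independent = 0,
                                     seed = 1, duration = 100, dt = 1e-3,
                                     D = 0.5, w0 = 0.25, cpp_g = 30,
                                     cpp_r = 30,
                                     background_kHz = c(green = 0, red = 0),
                                     crosstalk_gr = 0) {
  stopifnot(double_fraction >= 0, double_fraction <= 1)
  n_double <- round(double_fraction * n_particles)
  species <- data.frame(
    n = c(n_double, n_particles - n_double, n_red_independent),
    D = D, dim = 2,
    cpp_g = c(cpp_g, cpp_g, 0),
    cpp_r = c(cpp_r, 0, cpp_r)
  )
  cfg <- fcs_sim_config(species = species, w0 = w0, duration = duration,
                        dt = dt, background_kHz = background_kHz,
                        crosstalk_gr = crosstalk_gr, seed = seed)
  tr <- simulate_fluctuation_traces(cfg)
  max_lag <- min(tr$duration / 10, 100 * w0^2 / (4 * D))
  g <- correlate(tr$green, dt = dt, max_lag = max_lag, channel = "green")
  r <- correlate(tr$red, dt = dt, max_lag = max_lag, channel = "red")
  x <- correlate(tr$green, tr$red, dt = dt, max_lag = max_lag,
                 channel = "cross")
  res <- fccs_relative_amplitude(
    g, r, x, background = background_kHz, crosstalk_gr = crosstalk_gr,
    denominator = "red")
  list(rel_cc = res$rel_cc, fccs = res, truth = tr$truth)
}

#' Simulate a three-channel confocal cell image
#'
#' An annulus-shaped plasma-membrane cross-section carries receptors at
#' surface density `density`; expected photon counts per membrane pixel
#' are (density x A_eff x labeled fraction x CPP x dwell time), blurred
#' with an isotropic Gaussian point-spread function and Poisson-sampled.
#' Channels: `reference` (all receptors, 1 - p_nf fluorescent), `click`
#' (fraction CE), `ligand` (fraction occupancy, 1 - p_nf fluorescent).
#'
#' @param density receptor surface density (um^-2).
#' @param ce true click efficiency.
#' @param occupancy true IL-4 occupancy.
#' @param calib an [effective_volume()] calibration (supplies A_eff).
#' @param cpp named brightness per channel (kHz),
#'   e.g. `c(reference = 4, click = 10, ligand = 12)`.
#' @param p_nf named non-fluorescent fractions (default
#'   `c(reference = 0.20, ligand = 0.32)`).
#' @param size image edge (px, default 128). @param pixel_size um/px.
#' @param radii annulus inner/outer radii (px, default `c(30, 46)`).
#' @param dwell_time pixel dwell (s, default 25e-6).
#' @param psf_sigma PSF sigma in pixels (default 0.55).
#' @param background mean dark counts per pixel (default 0.05).
#' @param seed RNG seed.
#' @return list with `channels` (named list of [channel_image()]),
#'   `truth` (the inputs incl. expected membrane counts), `annulus`
#'   (logical ground-truth mask).
#' @export
simulate_cell_image <- function(density, ce, occupancy = 0, calib,
                                cpp = c(reference = 4, click = 10, ligand = 12),
                                p_nf = c(reference = 0.20, ligand = 0.32),
                                size = 128, pixel_size = 0.1,
                                radii = c(30, 46), dwell_time = 25e-6,
                                psf_sigma = 0.55, background = 0.05, seed = 1) {
  stopifnot(inherits(calib, "focal_volume_calibration"),
            density > 0, ce >= 0, occupancy >= 0,
            radii[1] < radii[2], radii[2] < size / 2)
  set.seed(seed)
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`))
  annulus <- d >= radii[1] & d <= radii[2]
  get_pnf <- function(ch) if (ch %in% names(p_nf)) unname(p_nf[ch]) else 0
  frac <- c(reference = (1 - get_pnf("reference")),
            click = ce,
            ligand = occupancy * (1 - get_pnf("ligand")))
  N_vol <- density * calib$A_eff        # particles in the focal cross-section
  channels <- list()
  for (ch in names(frac)) {
    rate_kHz <- N_vol * frac[[ch]] * unname(cpp[ch])
    expected <- matrix(background, size, size)
    expected[annulus] <- expected[annulus] + rate_kHz * 1000 * dwell_time
    if (psf_sigma > 0) {
      sm <- max(expected)
      expected <- EBImage::gblur(expected / sm, sigma = psf_sigma) * sm
      expected[expected < 0] <- 0
    }
    counts <- matrix(stats::rpois(size^2, expected), size, size)
    channels[[ch]] <- channel_image(counts, dwell_time = dwell_time,
                                    pixel_size = pixel_size, channel = ch)
  }
  list(channels = channels,
       truth = list(density = density, ce = ce, occupancy = occupancy,
                    cpp = cpp, p_nf = p_nf, N_vol = N_vol),
       annulus = annulus)
}

#' Simulate a titration dataset around a Hill-law ground truth
#'
#' Each point's occupancy is the mean of `n_cells` per-cell draws with
#' per-cell SD `sigma_theta_cell`; each concentration is the mean of
#' `n_runs` supernatant FCS measurements with per-run coefficient of
#' variation `cv_c`. The reported point uncertainties are the per-cell SD
#' and per-run CV (matching error bars that show the spread across cells,
#' not the error of the mean), which makes downstream Monte-Carlo errors
#' deliberately conservative.
#'
#' @param c_grid true free-ligand concentrations (mol/L).
#' @param A,A0,c0,n Hill-law ground truth.
#' @param sigma_theta_cell per-cell occupancy SD (default 0.05).
#' @param cv_c per-run relative concentration error (default 0.10).
#' @param n_cells cells per point (default 30).
#' @param n_runs FCS runs per concentration (default 6).
#' @param seed RNG seed.
#' @return a [titration_dataset()]; the truth is attached as attribute
#'   `truth`.
#' @export
simulate_titration <- function(c_grid, A = 1, A0 = 0, c0, n = 1,
                               sigma_theta_cell = 0.05, cv_c = 0.10,
                               n_cells = 30, n_runs = 6, seed = 1) {
  stopifnot(all(c_grid > 0), c0 > 0)
  set.seed(seed)
  theta_true <- hill_model(c_grid, A, A0, c0, n)
  theta <- vapply(theta_true, function(th) {
    mean(stats::rnorm(n_cells, th, sigma_theta_cell))
  }, numeric(1))
  c_meas <- vapply(c_grid, function(cc) {
    mean(cc * (1 + stats::rnorm(n_runs, 0, cv_c)))
  }, numeric(1))
  c_meas <- pmax(c_meas, min(c_grid) * 1e-3)
  out <- titration_dataset(c = c_meas, theta = theta,
                           sigma_c = cv_c * c_meas,
                           sigma_theta = sigma_theta_cell,
                           n_cells = n_cells)
  attr(out, "truth") <- list(A = A, A0 = A0, c0 = c0, n = n)
  out
}

#' Simulate a jittered coordinate ensemble
#'
#' Frames are the reference coordinates plus zero-mean isotropic Gaussian
#' displacements with per-atom sigma; optional rigid-body tumbling
#' (random rotation + translation per frame) tests the superposition
#' invariance of downstream analyses.
#'
#' @param atoms atom table as for [trajectory_ensemble()].
#' @param ref_coords `n_atoms x 3` reference coordinates (A).
#' @param sigma per-atom jitter SD (A), scalar or vector.
#' @param n_frames number of frames.
#' @param tumbling apply a random rigid transform per frame (default
#'   FALSE).
#' @param seed RNG seed.
#' @return a [trajectory_ensemble()] with attribute `truth_sigma`.
#' @export
simulate_trajectory <- function(atoms, ref_coords, sigma = 0.5,
                                n_frames = 100, tumbling = FALSE, seed = 1) {
  stopifnot(is.matrix(ref_coords), ncol(ref_coords) == 3)
  set.seed(seed)
  n <- nrow(ref_coords)
  sigma <- rep_len(sigma, n)
  coords <- array(NA_real_, c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    fr <- ref_coords + matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
    if (tumbling) {
      M <- matrix(stats::rnorm(9), 3, 3)
      qr_d <- qr(M)
      R <- qr.Q(qr_d)
      if (det(R) < 0) R[, 1] <- -R[, 1]
      fr <- fr %*% R + matrix(stats::rnorm(3, 0, 5), n, 3, byrow = TRUE)
    }
    coords[, , f] <- fr
  }
  out <- trajectory_ensemble(atoms, coords)
  attr(out, "truth_sigma") <- sigma
  out
}

#' Synthetic mini-protein with a BCN residue
#'
#' Builds a deterministic helical C-alpha/backbone trace of `n_res`
#' residues with full peptide-bond atoms and replaces one residue by a
#' BCN pseudo-residue carrying the renamed backbone (N, C2, C3, O3) and
#' the four ring atoms C11, C14, C15, C18 arranged as a planar ring with
#' the C14-C15 triple bond. Intended as a ground-truth substrate for the
#' catchbox, ring-orientation and B-factor analyses; it is a synthetic
#' construct, not a crystal structure.
#'
#' @param n_res number of residues (default 24).
#' @param bcn_resno residue number converted to BCN (default 12).
#' @return list with `atoms` (data.frame) and `coords` (matrix), ready
#'   for [trajectory_ensemble()] / [simulate_trajectory()].
#' @export
synthetic_bcn_structure <- function(n_res = 24, bcn_resno = 12) {
  atoms <- list()
  coords <- list()
  aa_cycle <- c("ALA", "GLY", "SER", "LEU", "LYS", "GLU", "THR", "VAL")
  for (r in seq_len(n_res)) {
    # ideal-ish alpha helix: rise 1.5 A, 100 deg/residue, radius 2.3 A
    ang <- (r - 1) * 100 * pi / 180
    ca <- c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (r - 1))
    is_bcn <- r == bcn_resno
    resname <- if (is_bcn) "BCN" else aa_cycle[(r - 1) %% length(aa_cycle) + 1]
    bb_names <- if (is_bcn) c("N", "C2", "C3", "O3") else c("N", "CA", "C", "O")
    offs <- rbind(c(-1.2, 0.3, -0.5), c(0, 0, 0), c(1.3, 0.2, 0.4),
                  c(1.8, 1.2, 0.6))
    for (j in seq_along(bb_names)) {
      atoms[[length(atoms) + 1]] <- data.frame(
        name = bb_names[j], resname = resname, resno = r, chain = "A")
      coords[[length(coords) + 1]] <- ca + offs[j, ]
    }
    if (is_bcn) {
      # planar ring ~6 A out along the local radial direction
      dir <- c(cos(ang), sin(ang), 0)
      side <- c(-sin(ang), cos(ang), 0)
      base <- ca + 6 * dir
      ring <- list(
        C11 = base - 1.2 * side - 0.8 * dir,
        C14 = base - 0.6 * side + 0.7 * dir,
        C15 = base + 0.6 * side + 0.7 * dir,
        C18 = base + 1.2 * side - 0.8 * dir
      )
      for (nm in names(ring)) {
        atoms[[length(atoms) + 1]] <- data.frame(
          name = nm, resname = "BCN", resno = r, chain = "A")
        coords[[length(coords) + 1]] <- ring[[nm]]
      }
    }
  }
  list(atoms = do.call(rbind, atoms),
       coords = do.call(rbind, coords))
}
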