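# ---- confocal image quantification ----------------------------------------

#' Photon-counting channel image
#'
#' One confocal channel recorded in photon-counting mode (16-bit counts)
#' with the acquisition metadata the pixel-to-particle conversion needs.
#'
#' @param pixels 2D matrix of non-negative integer photon counts.
#' @param dwell_time pixel dwell time (s).
#' @param pixel_size pixel edge length (um).
#' @param channel channel identifier, e.g. "egfp".
#' @param laser_line excitation wavelength (nm), optional.
#' @param P_tot total excitation power (uW), optional.
#' @return object of class `channel_image`.
#' @export
channel_image <- function(pixels, dwell_time, pixel_size = NA_real_,
                          channel = "egfp", laser_line = NA_real_,
                          P_tot = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(pixels < 0) || any(pixels != round(pixels))) {
    stop("channel_image: pixels must be non-negative integer counts")
  }
  if (!is.numeric(dwell_time) || dwell_time <= 0) {
    stop("channel_image: dwell_time must be positive (s)")
  }
  structure(list(pixels = pixels, dwell_time = dwell_time,
                 pixel_size = pixel_size, channel = channel,
                 laser_line = laser_line, P_tot = P_tot),
            class = "channel_image")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally via union-find on the (small) label graph.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' Segment the plasma membrane by Otsu thresholding
#'
#' Applies Otsu's threshold to the chosen channel (by convention the
#' reference/eGFP channel), labels connected foreground components
#' (8-connectivity), and returns the largest component as the membrane
#' mask. Optional Gaussian smoothing before thresholding stabilizes the
#' threshold on shot-noise-limited images; the mask is taken from the
#' unsmoothed thresholded image restricted to the selected component.
#'
#' @param img a [channel_image()] (or plain count matrix).
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (default 1;
#'   0 disables).
#' @return object of class `membrane_mask` with fields `mask` (logical
#'   matrix), `component_area` (pixels), `threshold`, `source_channel`.
#' @export
segment_membrane <- function(img, smooth_sigma = 1) {
  px <- if (inherits(img, "channel_image")) img$pixels else img
  stopifnot(is.matrix(px))
  if (length(px) == 0) stop("segment_membrane: empty image")
  rng <- range(px)
  if (rng[1] == rng[2]) stop("segment_membrane: constant image, no threshold")
  work <- px
  if (smooth_sigma > 0) {
    work <- EBImage::gblur(px / max(px), sigma = smooth_sigma) * max(px)
  }
  norm <- (work - min(work)) / (max(work) - min(work))
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  if (!any(fg)) stop("segment_membrane: empty foreground after thresholding")
  lab <- .label8(fg)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  mask <- lab == biggest
  structure(list(
    mask = mask,
    component_area = sum(mask),
    threshold = thr * (max(work) - min(work)) + min(work),
    source_channel = if (inherits(img, "channel_image")) img$channel else NA_character_
  ), class = "membrane_mask")
}

#' Integer-pixel channel registration by mask overlap
#'
#' Finds the integer shift of a second channel's mask (or thresholded
#' image) that maximizes overlap with the reference mask within
#' `max_shift` pixels. Lateral chromatic displacement on the calibrated
#' instrument is sub-pixel, so the shift is applied only if it improves
#' the overlap by more than `tie_tol`; ties resolve to no shift.
#'
#' @param ref_mask logical matrix (reference channel mask).
#' @param mask logical matrix to register.
#' @param max_shift maximal |shift| per axis in pixels (default 2).
#' @param tie_tol minimal overlap-fraction gain to accept a shift
#'   (default 1e-3).
#' @return list with `shift` (dx, dy), `overlap` (fraction of reference
#'   mask covered at the chosen shift).
#' @export
register_channels <- function(ref_mask, mask, max_shift = 2, tie_tol = 1e-3) {
  if (inherits(ref_mask, "membrane_mask")) ref_mask <- ref_mask$mask
  if (inherits(mask, "membrane_mask")) mask <- mask$mask
  stopifnot(is.matrix(ref_mask), is.matrix(mask),
            all(dim(ref_mask) == dim(mask)))
  nr <- nrow(ref_mask); nc <- ncol(ref_mask)
  shift_mat <- function(m, dx, dy) {
    out <- matrix(FALSE, nr, nc)
    xs <- seq_len(nr) - dx
    ys <- seq_len(nc) - dy
    ok_x <- xs >= 1 & xs <= nr
    ok_y <- ys >= 1 & ys <= nc
    out[ok_x, ok_y] <- m[xs[ok_x], ys[ok_y]]
    out
  }
  denom <- max(sum(ref_mask), 1)
  best <- c(0, 0)
  base <- sum(ref_mask & mask) / denom
  best_ov <- base
  for (dx in -max_shift:max_shift) {
    for (dy in -max_shift:max_shift) {
      if (dx == 0 && dy == 0) next
      ov <- sum(ref_mask & shift_mat(mask, dx, dy)) / denom
      if (ov > best_ov + tie_tol) {
        best_ov <- ov
        best <- c(dx, dy)
      }
    }
  }
  list(shift = best, overlap = best_ov, overlap_unshifted = base)
}

#' Convert masked pixel counts to a corrected particle number
#'
#' The mean photon count inside the membrane mask is divided by the pixel
#' dwell time to give a count rate F, by the molecular brightness `cpp` to
#' give the mean particle number in the observation volume, and rescaled
#' by 1/(1 - p_nf) for the fraction of non-fluorescent labels (immature
#' fluorescent protein, unlabeled ligand).
#'
#' @param img a [channel_image()].
#' @param mask a [membrane_mask()] (or logical matrix).
#' @param cpp molecular brightness (kHz) at the image's excitation power.
#' @param p_nf non-fluorescent fraction in `[0, 1)` (default 0).
#' @return list with `N` (corrected particle number), `N_raw`, `F_kHz`,
#'   `mean_counts`, and `saturated` (count of pixels whose instantaneous
#'   rate exceeds 1 MHz).
#' @export
pixels_to_particles <- function(img, mask, cpp, p_nf = 0) {
  stopifnot(inherits(img, "channel_image"))
  if (inherits(mask, "membrane_mask")) mask <- mask$mask
  stopifnot(is.matrix(mask), all(dim(mask) == dim(img$pixels)))
  if (!any(mask)) stop("pixels_to_particles: empty mask")
  if (!is.numeric(cpp) || cpp <= 0) stop("pixels_to_particles: cpp must be positive (kHz)")
  if (p_nf < 0 || p_nf >= 1) stop("pixels_to_particles: p_nf must be in [0, 1)")
  mc <- mean(img$pixels[mask])
  F_kHz <- mc / img$dwell_time / 1000      # counts per dwell -> kHz
  N_raw <- F_kHz / cpp
  rate_MHz <- img$pixels / img$dwell_time / 1e6
  list(
    N = N_raw / (1 - p_nf),
    N_raw = N_raw,
    F_kHz = F_kHz,
    mean_counts = mc,
    saturated = sum(rate_MHz[mask] > 1)
  )
}

#' Quantify one cell: click efficiency, occupancy, surface density
#'
#' Segments the membrane on the reference channel, applies the shared mask
#' to every channel (after optional integer registration), converts pixel
#' counts to corrected particle numbers, and forms the ratios
#' CE = N_click/N_ref and occupancy = N_ligand/N_ref. The receptor surface
#' density is N_ref divided by the elliptical cross-section A_eff of the
#' reference laser line's observation volume.
#'
#' @param channels named list of [channel_image()]s; must contain
#'   `reference`, optionally `click` and `ligand`.
#' @param calib named list of [effective_volume()] calibrations per channel
#'   (at least for `reference`).
#' @param cpp named numeric: molecular brightness (kHz) per channel.
#' @param p_nf named numeric: non-fluorescent fraction per channel
#'   (missing channels default to 0).
#' @param cell_id identifier stored in the result.
#' @param register logical: register click/ligand masks to the reference
#'   mask before applying it (default FALSE; displacement is sub-pixel on
#'   a calibrated instrument).
#' @return object of class `cell_quantification` with particle numbers,
#'   `CE`, `occupancy`, `density` (um^-2), saturation flags and the mask.
#' @export
quantify_cell <- function(channels, calib, cpp, p_nf = c(reference = 0),
                          cell_id = NA, register = FALSE) {
  stopifnot(is.list(channels), "reference" %in% names(channels))
  if (!("reference" %in% names(calib))) {
    stop("quantify_cell: missing calibration for the reference channel")
  }
  for (ch in names(channels)) {
    if (!(ch %in% names(cpp))) {
      stop(sprintf("quantify_cell: missing brightness (cpp) for channel '%s'", ch))
    }
  }
  mask <- segment_membrane(channels$reference)
  get_pnf <- function(ch) if (ch %in% names(p_nf)) unname(p_nf[ch]) else 0
  res <- list()
  flags <- character(0)
  for (ch in names(channels)) {
    m <- mask
    if (register && ch != "reference") {
      other <- tryCatch(segment_membrane(channels[[ch]]), error = function(e) NULL)
      if (!is.null(other)) {
        reg <- register_channels(mask$mask, other$mask)
        # shared reference mask is used regardless; the shift is reported
        if (any(reg$shift != 0)) {
          flags <- c(flags, sprintf("%s_shift_%d_%d", ch, reg$shift[1], reg$shift[2]))
        }
      }
    }
    res[[ch]] <- pixels_to_particles(channels[[ch]], m, unname(cpp[ch]),
                                     get_pnf(ch))
    if (res[[ch]]$saturated > 0) {
      flags <- c(flags, sprintf("%s_saturated_%d", ch, res[[ch]]$saturated))
    }
  }
  N_ref <- res$reference$N
  N_click <- if ("click" %in% names(res)) res$click$N else NA_real_
  N_ligand <- if ("ligand" %in% names(res)) res$ligand$N else NA_real_
  A_eff <- calib$reference$A_eff
  structure(list(
    cell_id = cell_id,
    N_ref = N_ref, N_click = N_click, N_ligand = N_ligand,
    CE = if (is.na(N_click)) NA_real_ else N_click / N_ref,
    occupancy = if (is.na(N_ligand)) NA_real_ else N_ligand / N_ref,
    density = N_ref / A_eff,
    flags = flags,
    mask = mask
  ), class = "cell_quantification")
}

#' Rescale occupied-state click efficiency for partial occupancy
#'
#' CE_occ = (CE_occ' - (1 - F_occ) CE_free) / F_occ removes the
#' contribution of unoccupied receptors from a click efficiency measured
#' at partial ligand occupancy F_occ.
#'
#' @param CE_occ_prime measured click efficiency in the occupied-state
#'   condition.
#' @param CE_free click efficiency of the free receptor.
#' @param F_occ fraction of receptors actually occupied, in (0, 1].
#' @return corrected occupied-state click efficiency.
#' @export
rescale_ce_occupied <- function(CE_occ_prime, CE_free, F_occ) {
  if (!is.numeric(F_occ) || any(F_occ <= 0) || any(F_occ > 1)) {
    stop("rescale_ce_occupied: F_occ must be in (0, 1]")
  }
  (CE_occ_prime - (1 - F_occ) * CE_free) / F_occ
}
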