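# ---- MD trajectory and structure post-processing --------------------------

#' Trajectory ensemble container
#'
#' Per-frame coordinates of a constant atom roster, as obtained from a
#' multi-model PDB of MD snapshots.
#'
#' @param atoms data.frame with columns `name` (atom name), `resname`,
#'   `resno`, and optionally `chain`.
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resname", "resno") %in% names(atoms)))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            dim(coords)[1] == nrow(atoms))
  if (!all(is.finite(coords))) stop("trajectory_ensemble: non-finite coordinates")
  if (!("chain" %in% names(atoms))) atoms$chain <- "A"
  structure(list(atoms = atoms, coords = coords,
                 n_frames = dim(coords)[3], n_atoms = nrow(atoms)),
            class = "trajectory_ensemble")
}

#' Read a (multi-model) PDB file into a trajectory ensemble
#'
#' Static structures give a 1-frame ensemble; multi-model files one frame
#' per MODEL record. Only the first alternate location is kept.
#'
#' @param path PDB file.
#' @param chain optional chain selection.
#' @return a [trajectory_ensemble()].
#' @export
read_trajectory_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel_idx <- which(pdb$atom$type == "ATOM" | pdb$atom$type == "HETATM")
  keep <- pdb$atom$alt %in% c(NA, "", "A")
  sel_idx <- intersect(sel_idx, which(keep))
  if (!is.null(chain)) sel_idx <- intersect(sel_idx, which(pdb$atom$chain %in% chain))
  if (!length(sel_idx)) stop("read_trajectory_pdb: no atoms selected")
  atoms <- data.frame(
    name = pdb$atom$elety[sel_idx],
    resname = pdb$atom$resid[sel_idx],
    resno = pdb$atom$resno[sel_idx],
    chain = pdb$atom$chain[sel_idx],
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, c(length(sel_idx), 3, n_frames))
  cols <- as.vector(t(outer(sel_idx - 1, 1:3, function(a, b) 3 * a + b)))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- matrix(xyz[f, cols], ncol = 3, byrow = TRUE)
  }
  trajectory_ensemble(atoms, coords)
}

# Kabsch superposition of mobile (n x 3) onto fixed (n x 3); returns the
# transformed mobile coordinates.
.kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(A %*% t(R), 2, cf, `+`)
}

# superpose every frame onto reference coordinates using fit atom subset
.superpose_frames <- function(coords, ref, fit_idx = seq_len(nrow(ref))) {
  out <- coords
  for (f in seq_len(dim(coords)[3])) {
    mob <- coords[, , f]
    cm <- colMeans(mob[fit_idx, , drop = FALSE])
    cf <- colMeans(ref[fit_idx, , drop = FALSE])
    A <- sweep(mob[fit_idx, , drop = FALSE], 2, cm)
    B <- sweep(ref[fit_idx, , drop = FALSE], 2, cf)
    sv <- svd(t(A) %*% B)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    out[, , f] <- sweep(sweep(mob, 2, cm) %*% t(R), 2, cf, `+`)
  }
  out
}

#' Average structure of a trajectory
#'
#' Superposes every frame onto the first by rigid-body least squares on
#' all atoms and returns the per-atom arithmetic mean. With `sub_ranges`,
#' one average per contiguous frame block is returned (10 equal blocks
#' when `sub_ranges = 10`), as used for sub-trajectory averages feeding
#' solvation-free-energy calculations.
#'
#' @param traj a [trajectory_ensemble()].
#' @param sub_ranges NULL (default), an integer number of equal blocks, or
#'   a list of frame-index vectors.
#' @param superpose superpose frames before averaging (default TRUE).
#' @return matrix `n_atoms x 3`, or a list of such matrices for
#'   sub-ranges.
#' @export
average_structure <- function(traj, sub_ranges = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (traj$n_frames < 1) stop("average_structure: empty trajectory")
  coords <- traj$coords
  if (superpose && traj$n_frames > 1) {
    coords <- .superpose_frames(coords, coords[, , 1])
  }
  avg_of <- function(frames) {
    apply(coords[, , frames, drop = FALSE], c(1, 2), mean)
  }
  if (is.null(sub_ranges)) return(avg_of(seq_len(traj$n_frames)))
  if (is.numeric(sub_ranges) && length(sub_ranges) == 1) {
    sub_ranges <- split(seq_len(traj$n_frames),
                        cut(seq_len(traj$n_frames), sub_ranges, labels = FALSE))
  }
  lapply(sub_ranges, avg_of)
}

# default peptide-bond atom names, with the BCN residue's renamed backbone
.backbone_atoms <- function(resname) {
  if (resname %in% c("BCN", "BCNK")) c("N", "C2", "C3", "O3") else c("N", "CA", "C", "O")
}

#' Per-residue B-factors from a trajectory
#'
#' Frames are superposed onto the trajectory average structure; for each
#' requested residue the mean-square fluctuation of its peptide-bond
#' atoms (N, CA, C, O; renamed N, C2, C3, O3 in the BCN residue) about
#' their average positions is converted to the crystallographic
#' B = (8 pi^2 / 3) MSF. The raw RMSF is reported alongside.
#'
#' @param traj a [trajectory_ensemble()].
#' @param residues residue numbers to evaluate (default: all).
#' @return data.frame with `resno`, `resname`, `B` (A^2), `rmsf` (A),
#'   `n_atoms`. Residues with no backbone atoms are skipped with a
#'   warning.
#' @export
bfactors <- function(traj, residues = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  if (is.null(residues)) residues <- unique(traj$atoms$resno)
  ref <- average_structure(traj)
  coords <- if (traj$n_frames > 1) .superpose_frames(traj$coords, ref) else traj$coords
  # fluctuation reference: average of the superposed frames
  avg <- apply(coords, c(1, 2), mean)
  rows <- list()
  for (r in residues) {
    in_res <- traj$atoms$resno == r
    if (!any(in_res)) {
      warning(sprintf("bfactors: residue %s absent; skipped", r))
      next
    }
    resname <- traj$atoms$resname[in_res][1]
    idx <- which(in_res & traj$atoms$name %in% .backbone_atoms(resname))
    if (!length(idx)) {
      warning(sprintf("bfactors: residue %s has no peptide-bond atoms; skipped", r))
      next
    }
    dev2 <- 0
    for (f in seq_len(traj$n_frames)) {
      dev2 <- dev2 + rowSums((coords[idx, , f, drop = FALSE][, , 1] -
                                avg[idx, , drop = FALSE])^2)
    }
    msf <- mean(dev2 / traj$n_frames)
    rows[[as.character(r)]] <- data.frame(
      resno = r, resname = resname,
      B = (8 * pi^2 / 3) * msf,
      rmsf = sqrt(msf),
      n_atoms = length(idx)
    )
  }
  if (!length(rows)) stop("bfactors: no residues evaluated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# local orthonormal frame of the BCN ring: x along C14->C15, y the
# component of (ring centroid -> bond midpoint) orthogonal to x, z = x cross y
.catchbox_frame <- function(ring_xyz) {
  c14 <- ring_xyz["C14", ]
  c15 <- ring_xyz["C15", ]
  ex <- c15 - c14
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9) stop("catchbox: degenerate C14-C15 bond")
  ex <- ex / nx
  center <- (c14 + c15) / 2
  centroid <- colMeans(ring_xyz)
  v <- center - centroid
  v <- v - sum(v * ex) * ex
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) {
    # centroid on the bond axis: pick any vector orthogonal to x
    v <- c(-ex[2], ex[1], 0)
    if (sum(v^2) < 1e-12) v <- c(0, -ex[3], ex[2])
    nv <- sqrt(sum(v^2))
  }
  ey <- v / nv
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  list(center = center, R = rbind(ex, ey, ez))
}

#' Catchbox census around the BCN triple bond
#'
#' For every frame, a cuboid box (default 13.5 x 4.5 x 3.5 A) is erected
#' around the midpoint of the C14-C15 triple bond of the BCN ring, with
#' the local x-axis along the bond. Every non-BCN atom is tested for
#' membership; per-atom hit counts and, per hit, the distance from the
#' BCN residue's anchor atom are accumulated. The census maps the steric
#' outreach of the strained alkyne.
#'
#' @param traj a [trajectory_ensemble()].
#' @param bcn_resno residue number of the BCN residue.
#' @param dims box edge lengths (A) along local x, y, z.
#' @param anchor_atom atom name used as distance anchor (default "C3",
#'   the renamed backbone carbon; falls back to "CA").
#' @return list with `counts` (data.frame: atom index, name, resname,
#'   resno, hits, frequency), `distances` (numeric, anchor distances of
#'   all hits), `n_frames`.
#' @export
catchbox_hits <- function(traj, bcn_resno, dims = c(13.5, 4.5, 3.5),
                          anchor_atom = "C3") {
  stopifnot(inherits(traj, "trajectory_ensemble"), length(dims) == 3)
  atoms <- traj$atoms
  bcn <- which(atoms$resno == bcn_resno)
  if (!length(bcn)) stop("catchbox_hits: BCN residue not found")
  ring_names <- c("C11", "C14", "C15", "C18")
  ring_idx <- bcn[match(ring_names, atoms$name[bcn])]
  if (any(is.na(ring_idx[c(2, 3)]))) {
    stop("catchbox_hits: ring atoms C14/C15 missing")
  }
  anchor_idx <- bcn[match(anchor_atom, atoms$name[bcn])]
  if (is.na(anchor_idx)) anchor_idx <- bcn[match("CA", atoms$name[bcn])]
  others <- setdiff(seq_len(traj$n_atoms), bcn)
  half <- dims / 2
  hits <- integer(traj$n_atoms)
  dists <- numeric(0)
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , f]
    ring_xyz <- xyz[bcn[match(c("C14", "C15"), atoms$name[bcn])], , drop = FALSE]
    # use all available ring atoms for the centroid
    have_ring <- bcn[atoms$name[bcn] %in% ring_names]
    ring_all <- xyz[have_ring, , drop = FALSE]
    rownames(ring_all) <- atoms$name[have_ring]
    fr <- .catchbox_frame(ring_all)
    local <- sweep(xyz[others, , drop = FALSE], 2, fr$center) %*% t(fr$R)
    inside <- abs(local[, 1]) <= half[1] &
      abs(local[, 2]) <= half[2] &
      abs(local[, 3]) <= half[3]
    hits[others[inside]] <- hits[others[inside]] + 1L
    if (any(inside) && !is.na(anchor_idx)) {
      d <- sqrt(rowSums(sweep(xyz[others[inside], , drop = FALSE], 2,
                              xyz[anchor_idx, ])^2))
      dists <- c(dists, d)
    }
  }
  hit_idx <- which(hits > 0)
  list(
    counts = data.frame(
      atom = hit_idx,
      name = atoms$name[hit_idx],
      resname = atoms$resname[hit_idx],
      resno = atoms$resno[hit_idx],
      hits = hits[hit_idx],
      frequency = hits[hit_idx] / traj$n_frames
    ),
    distances = dists,
    n_frames = traj$n_frames
  )
}

#' Test points against the catchbox of a single frame
#'
#' Exposes the frame construction and membership test for one snapshot;
#' used for validating the box geometry.
#'
#' @param ring_xyz matrix of ring-atom coordinates with rownames including
#'   C14 and C15 (C11/C18 improve the centroid).
#' @param points n x 3 matrix of query coordinates.
#' @param dims box edge lengths (A).
#' @return logical vector of membership.
#' @export
catchbox_contains <- function(ring_xyz, points, dims = c(13.5, 4.5, 3.5)) {
  fr <- .catchbox_frame(ring_xyz)
  local <- sweep(points, 2, fr$center) %*% t(fr$R)
  half <- dims / 2
  abs(local[, 1]) <= half[1] & abs(local[, 2]) <= half[2] &
    abs(local[, 3]) <= half[3]
}

#' Ring-normal orientation angles along a trajectory
#'
#' Per frame, the BCN ring normal n = normalize((C15 - C11) x (C14 - C18))
#' is expressed in spherical polar coordinates: polar = arccos(n_z),
#' azimuth = atan2(n_y, n_x), in degrees, after superposing all frames
#' onto the trajectory average (so the angles describe rotor motion in a
#' common molecular frame). Frames with near-collinear vectors are
#' flagged and excluded.
#'
#' @param traj a [trajectory_ensemble()].
#' @param bcn_resno residue number of the BCN residue.
#' @param superpose superpose frames onto the average first (default TRUE).
#' @return object of class `ring_orientation`: data.frame with `frame`,
#'   `polar`, `azimuth` (degrees); attribute `n_excluded`.
#' @export
ring_orientation <- function(traj, bcn_resno, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  atoms <- traj$atoms
  bcn <- which(atoms$resno == bcn_resno)
  need <- c("C11", "C14", "C15", "C18")
  idx <- bcn[match(need, atoms$name[bcn])]
  if (any(is.na(idx))) stop("ring_orientation: atoms C11/C14/C15/C18 missing")
  coords <- traj$coords
  if (superpose && traj$n_frames > 1) {
    coords <- .superpose_frames(coords, average_structure(traj))
  }
  polar <- azimuth <- rep(NA_real_, traj$n_frames)
  excluded <- 0L
  for (f in seq_len(traj$n_frames)) {
    xyz <- coords[idx, , f]
    v1 <- xyz[3, ] - xyz[1, ]       # C11 -> C15
    v2 <- xyz[2, ] - xyz[4, ]       # C18 -> C14
    n <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
    nn <- sqrt(sum(n^2))
    if (nn < 1e-9) {
      excluded <- excluded + 1L
      next
    }
    n <- n / nn
    polar[f] <- acos(max(min(n[3], 1), -1)) * 180 / pi
    azimuth[f] <- if (abs(n[3]) >= 1 - 1e-12) 0 else atan2(n[2], n[1]) * 180 / pi
  }
  ok <- !is.na(polar)
  out <- data.frame(frame = which(ok), polar = polar[ok], azimuth = azimuth[ok])
  attr(out, "n_excluded") <- excluded
  class(out) <- c("ring_orientation", "data.frame")
  out
}

# Gaussian KDE in 2D with a single isotropic bandwidth; log-likelihood of
# held-out points computed from pairwise squared distances.
.kde2_loo_loglik <- function(d2, h) {
  n <- nrow(d2)
  K <- exp(-d2 / (2 * h^2)) / (2 * pi * h^2)
  diag(K) <- 0
  dens <- rowSums(K) / (n - 1)
  sum(log(pmax(dens, 1e-300)))
}

#' Kernel density map of ring-orientation angles
#'
#' Gaussian kernel density estimate over (azimuth, polar) pairs treated as
#' Euclidean coordinates, with the bandwidth selected by leave-one-out
#' cross-validated grid search over 100 logarithmically spaced values
#' between 0.1 and 10 degrees. The density is evaluated on a regular grid
#' padded beyond the data range; eight logarithmically spaced contour
#' levels with a 10^-6.5 display floor are returned for plotting.
#'
#' @param orient a [ring_orientation()] result (or data.frame with
#'   `azimuth`, `polar`).
#' @param grid_n grid points per axis (default 101).
#' @param bandwidths candidate bandwidths (default 100 log-spaced in
#'   `[0.1, 10]`).
#' @param pad grid padding beyond the data range in bandwidths (default 4).
#' @return list with `azimuth`, `polar` (grid axes), `density` (matrix),
#'   `bandwidth`, `levels` (8 log-spaced contour levels), `floor`
#'   (10^-6.5), `integral` (numeric quadrature of the density over the
#'   grid).
#' @export
angle_density_map <- function(orient, grid_n = 101,
                              bandwidths = 10^seq(log10(0.1), log10(10),
                                                  length.out = 100),
                              pad = 4) {
  az <- orient$azimuth
  po <- orient$polar
  n <- length(az)
  if (n < 10) stop("angle_density_map: need >= 10 frames")
  pts <- cbind(az, po)
  d2 <- as.matrix(stats::dist(pts))^2
  ll <- vapply(bandwidths, function(h) .kde2_loo_loglik(d2, h), numeric(1))
  h <- bandwidths[which.max(ll)]
  gx <- seq(min(az) - pad * h, max(az) + pad * h, length.out = grid_n)
  gy <- seq(min(po) - pad * h, max(po) + pad * h, length.out = grid_n)
  gg <- expand.grid(x = gx, y = gy)
  dens <- matrix(0, grid_n, grid_n)
  # evaluate in chunks to keep memory flat
  chunk <- 2000L
  vals <- numeric(nrow(gg))
  for (s in seq(1, nrow(gg), by = chunk)) {
    e <- min(s + chunk - 1, nrow(gg))
    dx <- outer(gg$x[s:e], az, `-`)
    dy <- outer(gg$y[s:e], po, `-`)
    vals[s:e] <- rowMeans(exp(-(dx^2 + dy^2) / (2 * h^2))) / (2 * pi * h^2)
  }
  dens <- matrix(vals, grid_n, grid_n)
  integral <- sum(dens) * diff(gx[1:2]) * diff(gy[1:2])
  lev_max <- max(dens)
  floor_lev <- 10^-6.5
  levels <- 10^seq(log10(floor_lev), log10(max(lev_max, floor_lev * 10)),
                   length.out = 8)
  list(azimuth = gx, polar = gy, density = dens, bandwidth = h,
       levels = levels, floor = floor_lev, integral = integral)
}

# one-letter sequence from CA records of a structure data.frame + coords
.ca_table <- function(traj, frame = 1) {
  atoms <- traj$atoms
  idx <- which(atoms$name == "CA")
  data.frame(
    idx = idx,
    resno = atoms$resno[idx],
    aa = vapply(atoms$resname[idx], function(r) {
      a <- bio3d::aa321(r)
      if (is.na(a) || a == "X") "X" else a
    }, character(1)),
    x = traj$coords[idx, 1, frame],
    y = traj$coords[idx, 2, frame],
    z = traj$coords[idx, 3, frame]
  )
}

#' Domain-wise superposition and anchor RMSD profile
#'
#' Pairs the C-alpha atoms of a residue range in two structures by global
#' sequence alignment (BLOSUM62), superposes them by least squares with
#' iterative outlier rejection (default 5 cycles, rejecting pairs whose
#' deviation exceeds `cutoff` times the current RMSD, as in the standard
#' molecular-graphics `align` procedure), and then reports, per anchor
#' residue, the RMSD of the anchor C-alpha alone (RMSD_0) and including
#' +/-1, 2, 3 sequence neighbors (RMSD_1..3) without re-fitting.
#'
#' @param mobile,reference [trajectory_ensemble()]s (first frame used).
#' @param region integer range of (mature) residue numbers to align, e.g.
#'   `2:96` for domain D1, `98:196` for D2, `2:196` for a global fit.
#' @param anchors residue numbers at which to evaluate the RMSD profile.
#' @param cycles outlier-rejection cycles (default 5; 0 = plain Kabsch).
#' @param cutoff rejection multiple of the RMSD (default 2).
#' @return object of class `rmsd_profile`: data.frame with `anchor`,
#'   `rmsd0..rmsd3` (A); attributes `n_pairs`, `fit_rmsd`, `region`.
#' @export
superpose_and_rmsd <- function(mobile, reference, region, anchors,
                               cycles = 5, cutoff = 2) {
  stopifnot(inherits(mobile, "trajectory_ensemble"),
            inherits(reference, "trajectory_ensemble"))
  ca_m <- .ca_table(mobile)
  ca_r <- .ca_table(reference)
  ca_m <- ca_m[ca_m$resno %in% region, ]
  ca_r <- ca_r[ca_r$resno %in% region, ]
  if (nrow(ca_m) < 10 || nrow(ca_r) < 10) {
    stop("superpose_and_rmsd: region absent or too short")
  }
  sq_m <- paste(ca_m$aa, collapse = "")
  sq_r <- paste(ca_r$aa, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sq_m), Biostrings::AAString(sq_r),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pm <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  i_m <- i_r <- 0L
  pairs <- list()
  for (k in seq_along(pm)) {
    if (pm[k] != "-") i_m <- i_m + 1L
    if (ps[k] != "-") i_r <- i_r + 1L
    if (pm[k] != "-" && ps[k] != "-") {
      pairs[[length(pairs) + 1L]] <- c(i_m, i_r)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 10) {
    stop("superpose_and_rmsd: fewer than 10 paired C-alpha atoms")
  }
  xm_all <- as.matrix(ca_m[pairs[, 1], c("x", "y", "z")])
  xr_all <- as.matrix(ca_r[pairs[, 2], c("x", "y", "z")])

  use <- rep(TRUE, nrow(pairs))
  fit_rmsd <- NA_real_
  R <- diag(3); shift_m <- shift_r <- c(0, 0, 0)
  for (cyc in 0:max(cycles, 0)) {
    cm <- colMeans(xm_all[use, , drop = FALSE])
    cr <- colMeans(xr_all[use, , drop = FALSE])
    A <- sweep(xm_all[use, , drop = FALSE], 2, cm)
    B <- sweep(xr_all[use, , drop = FALSE], 2, cr)
    sv <- svd(t(A) %*% B)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    shift_m <- cm; shift_r <- cr
    moved <- sweep(sweep(xm_all, 2, cm) %*% t(R), 2, cr, `+`)
    dev <- sqrt(rowSums((moved - xr_all)^2))
    fit_rmsd <- sqrt(mean(dev[use]^2))
    if (cyc == cycles) break
    new_use <- dev <= cutoff * max(fit_rmsd, 1e-6)
    if (sum(new_use) < 10 || all(new_use == use)) break
    use <- new_use
  }
  # transform all mobile CA coordinates (full structure frame of the region)
  mob_xyz <- as.matrix(ca_m[, c("x", "y", "z")])
  mob_fit <- sweep(sweep(mob_xyz, 2, shift_m) %*% t(R), 2, shift_r, `+`)

  prof <- list()
  for (a in anchors) {
    row <- c(anchor = a, rmsd0 = NA_real_, rmsd1 = NA_real_,
             rmsd2 = NA_real_, rmsd3 = NA_real_)
    for (w in 0:3) {
      res_set <- (a - w):(a + w)
      im <- match(res_set, ca_m$resno)
      ir <- match(res_set, ca_r$resno)
      if (any(is.na(im)) || any(is.na(ir))) next
      dev2 <- rowSums((mob_fit[im, , drop = FALSE] -
                         as.matrix(ca_r[ir, c("x", "y", "z")]))^2)
      row[[paste0("rmsd", w)]] <- sqrt(mean(dev2))
    }
    prof[[as.character(a)]] <- as.data.frame(as.list(row))
  }
  out <- do.call(rbind, prof)
  rownames(out) <- NULL
  attr(out, "n_pairs") <- sum(use)
  attr(out, "fit_rmsd") <- fit_rmsd
  attr(out, "region") <- range(region)
  class(out) <- c("rmsd_profile", "data.frame")
  out
}

#' Convert between construct and mature residue numbering
#'
#' The expression construct carries an N-terminal His-tag that shifts its
#' numbering by +6 relative to the mature receptor sequence.
#'
#' @param resno residue numbers.
#' @param from `"construct"` or `"mature"`.
#' @return renumbered residues.
#' @export
convert_numbering <- function(resno, from = c("construct", "mature")) {
  from <- match.arg(from)
  if (from == "construct") resno - 6 else resno + 6
}

#' Read a solvation-free-energy table
#'
#' CSV with columns `site`, `dG_solv`, `dG_pol`, `dG_cav`, `dG_disp`,
#' `sem` (kcal/mol; one row per sub-trajectory average or per site).
#' Rows whose dG_solv lies more than 3 SDs from their site's mean are
#' disregarded as erroneous calculations; site-level means and SEMs over
#' the surviving rows are returned.
#'
#' @param path CSV file.
#' @return data.frame with one row per site: `site`, `dG_solv`, `dG_pol`,
#'   `dG_cav`, `dG_disp`, `sem`, `n`, `n_excluded`.
#' @export
read_sfe_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "dG_solv") %in% names(raw)))
  if (!all(c("dG_pol", "dG_cav", "dG_disp") %in% names(raw))) {
    raw$dG_pol <- raw$dG_cav <- raw$dG_disp <- NA_real_
  }
  out <- list()
  for (s in unique(raw$site)) {
    sub <- raw[raw$site == s, ]
    if (nrow(sub) > 2) {
      m <- mean(sub$dG_solv); sdev <- stats::sd(sub$dG_solv)
      keep <- if (sdev > 0) abs(sub$dG_solv - m) <= 3 * sdev else rep(TRUE, nrow(sub))
    } else keep <- rep(TRUE, nrow(sub))
    kept <- sub[keep, ]
    out[[s]] <- data.frame(
      site = s,
      dG_solv = mean(kept$dG_solv),
      dG_pol = mean(kept$dG_pol),
      dG_cav = mean(kept$dG_cav),
      dG_disp = mean(kept$dG_disp),
      sem = if (nrow(kept) > 1) stats::sd(kept$dG_solv) / sqrt(nrow(kept))
            else if ("sem" %in% names(kept)) kept$sem[1] else NA_real_,
      n = nrow(kept),
      n_excluded = sum(!keep)
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlate click efficiency with a structural or solvation quantity
#'
#' Pairs per-site CE statistics with RMSD_0 values (per domain) or with
#' solvation free energies (globally) and delegates to [pearson_mc()]
#' with the CE SEMs as y-uncertainties. The secondary-axis scaling factor
#' of [differential_ce()] is reported when differential CEs are supplied.
#'
#' @param ce named numeric of per-site CE (or |dCE|) values.
#' @param ce_sem named numeric of matching SEMs (default 0).
#' @param structural named numeric of per-site structural values (RMSD_0
#'   in A, or dG_solv in kcal/mol).
#' @param n_resamples,seed forwarded to [pearson_mc()].
#' @return list from [pearson_mc()] plus `n_sites` and `scale_factor`.
#' @export
ce_structure_correlation <- function(ce, structural, ce_sem = 0,
                                     n_resamples = 10000, seed = 1) {
  common <- intersect(names(ce), names(structural))
  if (length(common) < 3) stop("ce_structure_correlation: < 3 matched sites")
  x <- unname(structural[common])
  y <- unname(ce[common])
  sy <- if (length(ce_sem) == 1) rep(ce_sem, length(common)) else
    unname(ce_sem[common])
  res <- pearson_mc(x, y, sx = 0, sy = sy, n_resamples = n_resamples,
                    seed = seed)
  res$n_sites <- length(common)
  res$scale_factor <- stats::sd(y) / stats::sd(x)
  res
}
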