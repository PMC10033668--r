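# trajectory post-processing: averages, B-factors, catchbox, ring angles,
# domain-wise RMSD profiles

test_that("average structure is exact for trivial and symmetric ensembles", {
  s <- synthetic_bcn_structure()
  one <- trajectory_ensemble(s$atoms, s$coords)
  expect_equal(average_structure(one), s$coords, tolerance = 1e-12)
  # symmetric +/- offset cancels
  off <- matrix(0.3, nrow(s$coords), 3)
  coords <- array(c(s$coords + off, s$coords - off),
                  c(nrow(s$coords), 3, 2))
  two <- trajectory_ensemble(s$atoms, coords)
  expect_equal(average_structure(two, superpose = FALSE), s$coords,
               tolerance = 1e-12)
  # permutation invariance of frame order
  traj <- simulate_trajectory(s$atoms, s$coords, sigma = 0.3, n_frames = 20,
                              seed = 5)
  perm <- trajectory_ensemble(s$atoms, traj$coords[, , 20:1])
  a1 <- average_structure(traj, superpose = FALSE)
  a2 <- average_structure(perm, superpose = FALSE)
  expect_equal(a1, a2, tolerance = 1e-12)
  # jittered (pre-aligned) ensemble converges to truth at sigma/sqrt(n)
  big <- simulate_trajectory(s$atoms, s$coords, sigma = 0.5, n_frames = 400,
                             seed = 6)
  avg <- average_structure(big, superpose = FALSE)
  expect_lt(max(abs(avg - s$coords)), 5 * 0.5 / sqrt(400))
  # sub-trajectory averages: 10 equal blocks
  subs <- average_structure(big, sub_ranges = 10)
  expect_length(subs, 10)
})

test_that("B-factors vanish for rigid ensembles and obey 8 pi^2 sigma^2", {
  s <- synthetic_bcn_structure()
  rigid <- simulate_trajectory(s$atoms, s$coords, sigma = 0, n_frames = 5,
                               seed = 1)
  expect_equal(max(bfactors(rigid)$B), 0, tolerance = 1e-18)
  # isotropic jitter sigma = 0.5 A: B = 8 pi^2 sigma^2 (per-axis variance
  # 0.25 A^2). Margin: 3 SE of the per-residue mean-square estimate plus
  # the 6/(3 N_atoms) variance fraction absorbed by the rigid-body fit.
  n_frames <- 2000
  jit <- simulate_trajectory(s$atoms, s$coords, sigma = 0.5,
                             n_frames = n_frames, seed = 9)
  b <- bfactors(jit)
  expected <- 8 * pi^2 * 0.25
  n_eff <- n_frames * 4 * 3      # frames x atoms/residue x axes
  margin <- expected * (3 * sqrt(2 / n_eff) + 6 / (3 * nrow(s$atoms)))
  expect_true(all(abs(b$B - expected) < margin))
  expect_lt(abs(mean(b$B) - expected), margin)
  # the BCN residue is evaluated through its renamed backbone
  expect_true(12 %in% b$resno)
  expect_equal(b$n_atoms[b$resno == 12], 4)
})

test_that("B-factors are insensitive to rigid-body tumbling", {
  s <- synthetic_bcn_structure()
  still <- simulate_trajectory(s$atoms, s$coords, sigma = 0.4,
                               n_frames = 300, seed = 21)
  tumb <- simulate_trajectory(s$atoms, s$coords, sigma = 0.4,
                              n_frames = 300, tumbling = TRUE, seed = 21)
  b_still <- mean(bfactors(still)$B)
  b_tumb <- mean(bfactors(tumb)$B)
  expect_lt(abs(b_tumb - b_still) / b_still, 0.1)
})

test_that("restrained residues show lower B than unrestrained ones", {
  s <- synthetic_bcn_structure()
  sig <- rep(0.6, nrow(s$coords))
  restrained <- s$atoms$resno <= 8
  sig[restrained] <- 0.15
  traj <- simulate_trajectory(s$atoms, s$coords, sigma = sig,
                              n_frames = 400, seed = 13)
  b <- bfactors(traj)
  expect_lt(mean(b$B[b$resno <= 8]), 0.5 * mean(b$B[b$resno > 8]))
})

test_that("catchbox membership equals the brute-force half-space oracle", {
  set.seed(17)
  ring <- rbind(C11 = c(-1.2, -0.8, 0), C14 = c(-0.6, 0.7, 0),
                C15 = c(0.6, 0.7, 0), C18 = c(1.2, -0.8, 0))
  ring <- rigid_transform(ring, angle = 0.8, axis = c(1, 2, 0.5),
                          shift = c(3, -1, 2))
  dims <- c(13.5, 4.5, 3.5)
  pts <- matrix(rnorm(3 * 10000, sd = 5), ncol = 3)
  got <- catchbox_contains(ring, pts, dims)
  # independent brute-force test against the six half-spaces
  c14 <- ring["C14", ]; c15 <- ring["C15", ]
  ex <- (c15 - c14) / sqrt(sum((c15 - c14)^2))
  center <- (c14 + c15) / 2
  centroid <- colMeans(ring)
  v <- center - centroid
  v <- v - sum(v * ex) * ex
  ey <- v / sqrt(sum(v^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2], ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  rel <- sweep(pts, 2, center)
  oracle <- abs(rel %*% ex) <= dims[1] / 2 &
    abs(rel %*% ey) <= dims[2] / 2 &
    abs(rel %*% ez) <= dims[3] / 2
  expect_identical(got, as.vector(oracle))
  # the bond midpoint is always inside; 7 A along x is outside (6.75 cut)
  probe <- rbind(center, center + 7 * ex)
  expect_identical(as.vector(catchbox_contains(ring, probe, dims)),
                   c(TRUE, FALSE))
})

test_that("catchbox census counts a planted atom in every frame", {
  s <- synthetic_bcn_structure()
  # plant a pseudo-atom at the C14-C15 midpoint
  bcn <- s$atoms$resno == 12
  c14 <- s$coords[which(bcn & s$atoms$name == "C14"), ]
  c15 <- s$coords[which(bcn & s$atoms$name == "C15"), ]
  s$atoms <- rbind(s$atoms, data.frame(name = "OW", resname = "HOH",
                                       resno = 999, chain = "W"))
  s$coords <- rbind(s$coords, (c14 + c15) / 2)
  traj <- simulate_trajectory(s$atoms, s$coords, sigma = 0, n_frames = 7,
                              seed = 2)
  cb <- catchbox_hits(traj, 12)
  row <- cb$counts[cb$counts$resno == 999, ]
  expect_equal(row$hits, 7)
  expect_equal(row$frequency, 1)
  # empty environment: no hits at all once the planted atom is removed
  traj2 <- simulate_trajectory(s$atoms[s$atoms$resno != 999, ],
                               s$coords[s$atoms$resno != 999, ],
                               sigma = 0, n_frames = 3, seed = 2)
  expect_equal(nrow(catchbox_hits(traj2, 12)$counts), 0)
})

test_that("ring orientation angles match the symbolic cross product", {
  # constructed frame: v1 = x, v2 = y gives the +z pole
  atoms <- data.frame(
    name = c("C11", "C14", "C15", "C18"),
    resname = "BCN", resno = 1, chain = "A")
  coords <- rbind(C11 = c(0, 0, 0), C14 = c(0, 1, 0),
                  C15 = c(1, 0, 0), C18 = c(0, 0, 0))
  tr <- trajectory_ensemble(atoms, coords)
  ro <- ring_orientation(tr, 1, superpose = FALSE)
  expect_equal(ro$polar, 0, tolerance = 1e-9)
  expect_equal(ro$azimuth, 0)    # azimuth convention at the pole
  # random vector pairs against an independent evaluation
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3); o <- rnorm(3)
    coords <- rbind(C11 = o, C14 = o + b, C15 = o + a, C18 = o)
    ro <- ring_orientation(trajectory_ensemble(atoms, coords), 1,
                           superpose = FALSE)
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    n <- n / sqrt(sum(n^2))
    expect_equal(ro$polar, acos(n[3]) * 180 / pi, tolerance = 1e-9)
    expect_equal(ro$azimuth, atan2(n[2], n[1]) * 180 / pi, tolerance = 1e-9)
  }
  # antiparallel vectors: collinear cross product flagged and excluded
  coords <- rbind(C11 = c(0, 0, 0), C14 = c(-2, 0, 0),
                  C15 = c(1, 0, 0), C18 = c(0, 0, 0))
  ro <- ring_orientation(trajectory_ensemble(atoms, coords), 1,
                         superpose = FALSE)
  expect_equal(nrow(ro), 0)
  expect_equal(attr(ro, "n_excluded"), 1)
})

test_that("angle density map integrates to one and finds cluster modes", {
  set.seed(41)
  # two well-separated clusters
  ang <- data.frame(
    azimuth = c(rnorm(120, -60, 3), rnorm(120, 50, 3)),
    polar = c(rnorm(120, 40, 3), rnorm(120, 120, 3))
  )
  kde <- angle_density_map(ang, grid_n = 81)
  expect_equal(kde$integral, 1, tolerance = 0.02)
  expect_length(kde$levels, 8)
  expect_equal(kde$floor, 10^-6.5)
  # the two modes sit near the cluster centers
  dens <- kde$density
  top <- which(dens == max(dens), arr.ind = TRUE)[1, ]
  mode1 <- c(kde$azimuth[top[1]], kde$polar[top[2]])
  expect_true(sqrt(sum((mode1 - c(-60, 40))^2)) < 10 ||
                sqrt(sum((mode1 - c(50, 120))^2)) < 10)
  # a tight repeated point drives the bandwidth to the grid minimum
  rep_pt <- data.frame(azimuth = rep(10, 15) + rnorm(15, 0, 1e-4),
                       polar = rep(90, 15) + rnorm(15, 0, 1e-4))
  kde2 <- angle_density_map(rep_pt, grid_n = 41)
  expect_equal(kde2$bandwidth, 0.1, tolerance = 1e-9)
  expect_error(angle_density_map(ang[1:5, ]), ">= 10")
})

test_that("domain superposition removes rigid transforms and reports anchor RMSDs", {
  s <- synthetic_bcn_structure(n_res = 30, bcn_resno = 40)  # no BCN inside
  ref <- trajectory_ensemble(s$atoms, s$coords)
  # rigidly moved copy with residue 20's CA displaced by 0.5 A
  moved <- s$coords
  ica <- which(s$atoms$name == "CA" & s$atoms$resno == 20)
  moved[ica, ] <- moved[ica, ] + c(0.5, 0, 0)
  moved <- rigid_transform(moved, angle = 1.1, axis = c(1, 0.3, 2),
                           shift = c(-4, 8, 1))
  mob <- trajectory_ensemble(s$atoms, moved)
  prof <- superpose_and_rmsd(mob, ref, region = 1:30, anchors = c(20, 5))
  expect_equal(prof$rmsd0[prof$anchor == 20], 0.5, tolerance = 0.01)
  expect_lt(prof$rmsd0[prof$anchor == 5], 0.02)
  # rmsd_w dilutes the single displacement as 0.5/sqrt(2w+1)
  expect_equal(prof$rmsd1[prof$anchor == 20], 0.5 / sqrt(3), tolerance = 0.02)
  expect_equal(prof$rmsd3[prof$anchor == 20], 0.5 / sqrt(7), tolerance = 0.02)
  # identical structures: all zeros
  prof0 <- superpose_and_rmsd(ref, ref, region = 1:30, anchors = c(10))
  expect_lt(max(unlist(prof0[, -1])), 1e-9)
  # invariance under rigid transforms of either input
  moved2 <- rigid_transform(moved, angle = -0.7, axis = c(0, 1, 0),
                            shift = c(10, 0, 5))
  prof2 <- superpose_and_rmsd(trajectory_ensemble(s$atoms, moved2), ref,
                              region = 1:30, anchors = c(20))
  expect_equal(prof2$rmsd0, prof$rmsd0[prof$anchor == 20], tolerance = 1e-9)
  expect_error(superpose_and_rmsd(mob, ref, region = 200:230, anchors = 210),
               "region")
})

test_that("numbering conversion shifts by the His-tag offset", {
  expect_equal(convert_numbering(97, from = "construct"), 91)
  expect_equal(convert_numbering(91, from = "mature"), 97)
  expect_equal(convert_numbering(convert_numbering(50, "construct"), "mature"),
               50)
})

test_that("SFE tables drop >3 SD outliers and aggregate per site", {
  tmp <- tempfile(fileext = ".csv")
  set.seed(2)
  good <- rnorm(12, -50, 0.5)
  tab <- data.frame(site = rep(c("K87", "E189"), each = 12),
                    dG_solv = c(good, rnorm(11, -30, 0.5), -300),
                    dG_pol = -40, dG_cav = 5, dG_disp = -15)
  write.csv(tab, tmp, row.names = FALSE)
  sfe <- read_sfe_table(tmp)
  expect_equal(nrow(sfe), 2)
  expect_equal(sfe$n_excluded[sfe$site == "E189"], 1)
  expect_equal(sfe$n[sfe$site == "E189"], 11)
  expect_equal(sfe$dG_solv[sfe$site == "K87"], mean(good), tolerance = 1e-9)
  unlink(tmp)
})

test_that("CE-structure correlation delegates to the Monte-Carlo Pearson", {
  ce <- c(K87 = 0.30, E94 = 0.25, K97 = 0.14, S44 = 0.22, E189 = 0.35)
  str_val <- 2 * ce + 0.01   # exactly linear
  res <- ce_structure_correlation(ce, str_val, ce_sem = 0, n_resamples = 20,
                                  seed = 4)
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_equal(res$n_sites, 5)
  # permuted labels on correlated data destroy the correlation
  set.seed(6)
  noisy <- str_val + rnorm(5, 0, 0.01)
  names(noisy) <- sample(names(noisy))
  res_perm <- ce_structure_correlation(ce, noisy, ce_sem = 0,
                                       n_resamples = 20, seed = 4)
  expect_lt(abs(res_perm$r), abs(res$r))
  expect_error(ce_structure_correlation(ce[1:2], str_val[1:2]), "3 matched")
})
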