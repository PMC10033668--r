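# Hill fits, kinetics, mixtures, Welch test, Monte-Carlo Pearson

test_that("Hill model half-saturates at c0 for a 1:1 site", {
  expect_equal(hill_model(1e-8, 1, 0, 1e-8, 1), 0.5)
  expect_equal(hill_model(1e-12, 1, 0.05, 1e-8, 1), 0.05, tolerance = 1e-2)
})

test_that("zero-noise Monte-Carlo Hill fit collapses to the exact solution", {
  grid <- 10^seq(-9, -6, length.out = 8)
  data <- titration_dataset(grid, hill_model(grid, 1, 0, 34e-9, 1),
                            sigma_c = 0, sigma_theta = 0)
  fit <- hill_fit_mc(data, n_resamples = 25, seed = 3)
  expect_equal(unname(fit$mc_mean["c0"]), 34e-9, tolerance = 1e-6)
  expect_equal(unname(fit$mc_sd["c0"]), 0, tolerance = 1e-12)
  expect_equal(unname(fit$base["c0"]), 34e-9, tolerance = 1e-6)
  # a single zero-noise resample equals the base fit
  fit1 <- hill_fit_mc(data, n_resamples = 1, seed = 3)
  expect_equal(fit1$mc_mean, fit1$base, tolerance = 1e-9)
  expect_error(hill_fit_mc(data[1:3, ]), ">= 4")
})

test_that("Monte-Carlo SD of c0 grows with the occupancy uncertainty", {
  grid <- 10^seq(-9, -6, length.out = 8)
  theta <- hill_model(grid, 1, 0, 34e-9, 1)
  sds <- vapply(c(0.01, 0.05, 0.1), function(s) {
    d <- titration_dataset(grid, theta, sigma_c = 0, sigma_theta = s)
    unname(hill_fit_mc(d, n_resamples = 400, seed = 11)$mc_sd["c0"])
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("simulated titrations recover the dissociation constant", {
  grid <- 10^seq(log10(1e-9), log10(1e-6), length.out = 8)
  data <- simulate_titration(grid, A = 1, A0 = 0, c0 = 34e-9, n = 1, seed = 42)
  fit <- hill_fit_mc(data, n_resamples = 500, seed = 7)
  expect_lt(abs(fit$mc_mean["c0"] - 34e-9), fit$mc_sd["c0"])
  # seeded bit-reproducibility
  fit2 <- hill_fit_mc(data, n_resamples = 500, seed = 7)
  expect_identical(fit$mc_mean, fit2$mc_mean)
  expect_identical(fit$mc_sd, fit2$mc_sd)
})

test_that("double-exponential kinetics are recovered from noiseless data", {
  t <- c(0.5, 1, 2, 4, 8, 15, 30, 60, 120)
  truth <- list(A_fast = 0.12, k_fast = 0.68, A_slow = 0.08, k_slow = 0.01)
  ce <- truth$A_fast * (1 - exp(-truth$k_fast * t)) +
    truth$A_slow * (1 - exp(-truth$k_slow * t))
  fit <- fit_double_exponential(t, ce)
  expect_equal(fit$k_fast, truth$k_fast, tolerance = 1e-6)
  expect_equal(fit$k_slow, truth$k_slow, tolerance = 1e-6)
  expect_equal(fit$A_fast, truth$A_fast, tolerance = 1e-6)
  expect_equal(fit$plateau, 0.20, tolerance = 1e-6)
  expect_true(fit$k_fast >= fit$k_slow)
  expect_true(fit$identifiable)
  # single-exponential data: rates collapse, flagged as unidentifiable
  ce1 <- 0.2 * (1 - exp(-0.5 * t))
  fit1 <- fit_double_exponential(t, ce1)
  expect_equal(fit1$A_fast * (1 - exp(-fit1$k_fast * t)) +
                 fit1$A_slow * (1 - exp(-fit1$k_slow * t)), ce1,
               tolerance = 1e-6)
  expect_error(fit_double_exponential(1:3, 1:3), ">= 5")
})

test_that("two-state saturation fit recovers both hyperbolas", {
  cgrid <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2)
  ce <- 0.15 * cgrid / (0.3 + cgrid) + 0.1 * cgrid / (5 + cgrid)
  fit <- fit_two_state_saturation(cgrid, ce)
  expect_equal(fit$K1, 0.3, tolerance = 1e-5)
  expect_equal(fit$K2, 5, tolerance = 1e-4)
  expect_equal(fit$B1, 0.15, tolerance = 1e-4)
  # single hyperbola: half-saturation at K1
  ce1 <- 0.2 * cgrid / (0.4 + cgrid)
  fit1 <- suppressWarnings(fit_two_state_saturation(cgrid, ce1))
  pred <- fit1$B1 * 0.4 / (fit1$K1 + 0.4) + fit1$B2 * 0.4 / (fit1$K2 + 0.4)
  expect_equal(pred, 0.1, tolerance = 1e-4)
  # strictly linear data drive a K to the bound and get flagged
  expect_warning(fit_two_state_saturation(cgrid, 0.01 * cgrid), "boundary")
})

test_that("mixture decomposition selects uni- vs bimodal correctly", {
  set.seed(1)
  uni <- rnorm(500, 0.5, 0.05)
  m1 <- fit_occupancy_mixture(uni)
  expect_equal(m1$k, 1)
  bi <- c(rnorm(250, 0.2, 0.04), rnorm(250, 0.7, 0.04))
  m2 <- fit_occupancy_mixture(bi)
  expect_equal(m2$k, 2)
  # means recovered within 3 standard errors (sigma/sqrt(n) per component)
  se <- 0.04 / sqrt(250)
  expect_lt(abs(sort(m2$means)[1] - 0.2), 3 * se + 0.005)
  expect_lt(abs(sort(m2$means)[2] - 0.7), 3 * se + 0.005)
  expect_equal(sum(m2$weights), 1, tolerance = 1e-9)
  # 2-component likelihood never below the 1-component likelihood
  for (vals in list(uni, bi, runif(60))) {
    m <- fit_occupancy_mixture(vals)
    expect_gte(m$loglik[2] + 1e-9, m$loglik[1])
  }
  expect_error(fit_occupancy_mixture(rnorm(10)), ">= 20")
})

test_that("Welch test matches the hand-computed statistic", {
  set.seed(8)
  a <- rnorm(12, 1, 2)
  b <- rnorm(20, 0.2, 0.5)
  w <- welch_test(a, b)
  va <- var(a) / 12
  vb <- var(b) / 20
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof_hand <- (va + vb)^2 / (va^2 / 11 + vb^2 / 19)
  p_hand <- 2 * pt(-abs(t_hand), dof_hand)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$dof, dof_hand, tolerance = 1e-12)
  expect_equal(w$p, p_hand, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  w0 <- welch_test(a, a)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("Monte-Carlo Pearson reduces to plain Pearson at zero noise", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 8, 9.8, 12.1)
  pm <- pearson_mc(x, y, 0, 0, n_resamples = 50, seed = 2)
  ct <- cor.test(x, y)
  expect_equal(pm$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pm$r_mc_mean, pm$r, tolerance = 1e-12)
  expect_equal(pm$r_mc_sd, 0, tolerance = 1e-12)
  # exactly linear data
  expect_equal(pearson_mc(x, 2 * x, n_resamples = 10, seed = 1)$r, 1,
               tolerance = 1e-12)
  expect_error(pearson_mc(x, rep(1, 6)), "constant")
  expect_error(pearson_mc(1:2, 1:2), ">= 3")
})

test_that("Monte-Carlo Pearson matches an independent resampler stream", {
  x <- c(0.1, 0.4, 0.2, 0.8, 0.6, 0.9, 0.3)
  y <- c(0.2, 0.5, 0.1, 0.9, 0.5, 1.0, 0.4)
  sx <- rep(0.05, 7)
  sy <- rep(0.08, 7)
  pm <- pearson_mc(x, y, sx, sy, n_resamples = 200, seed = 31)
  # brute-force re-implementation with the same RNG stream
  set.seed(31)
  rs <- numeric(200)
  for (i in 1:200) {
    xi <- x + rnorm(7, 0, sx)
    yi <- y + rnorm(7, 0, sy)
    rs[i] <- cor(xi, yi)
  }
  expect_equal(pm$r_mc_mean, mean(rs), tolerance = 1e-12)
  expect_equal(pm$r_mc_sd, sd(rs), tolerance = 1e-12)
  # symmetry in (x, y) with swapped uncertainty streams
  pm_sym <- pearson_mc(y, x, sy, sx, n_resamples = 200, seed = 31)
  expect_equal(pm_sym$r, pm$r, tolerance = 1e-12)
})

test_that("differential CE propagates SEMs and scales secondary axes", {
  pat <- data.frame(
    site = rep(c("K87", "E189", "S44"), each = 2),
    condition = rep(c("free", "occupied"), 3),
    ce_mean = c(0.30, 0.22, 0.10, 0.12, 0.20, 0.20),
    ce_sem = c(3, 4, 0.01, 0.01, 0.02, 0.02)
  )
  d <- differential_ce(pat)
  expect_equal(d$dce[d$site == "K87"], -0.08, tolerance = 1e-12)
  expect_equal(d$sem[d$site == "K87"], 5, tolerance = 1e-12)   # sqrt(3^2+4^2)
  expect_equal(d$dce[d$site == "S44"], 0)
  # secondary-axis factor equates the average spreads (SDs across sites)
  rmsd <- c(K87 = 1.035, E189 = 0.165, S44 = 0.4)
  d2 <- differential_ce(pat, secondary = rmsd)
  expect_equal(attr(d2, "scale_factor"), sd(d2$abs_dce) / sd(rmsd),
               tolerance = 1e-12)
  # incomplete site skipped with a warning
  pat_bad <- rbind(pat, data.frame(site = "T113", condition = "free",
                                   ce_mean = 0.1, ce_sem = 0.01))
  expect_warning(d3 <- differential_ce(pat_bad), "lacks a condition")
  expect_false("T113" %in% d3$site)
})
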