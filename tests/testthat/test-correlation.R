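# correlation models, curve fitting, run curation, FCCS corrections

test_that("membrane ACF matches an independent evaluation of the model terms", {
  set.seed(21)
  for (i in 1:20) {
    p <- draw_membrane_params()
    tau <- 10^runif(8, -6, 0)
    # independent re-evaluation written out term by term
    g_T <- 1 + p$f_T / (1 - p$f_T) * exp(-tau / p$tau_T)
    g_3D <- p$f_3D / ((1 + tau / p$tau_3D) * sqrt(1 + tau / (36 * p$tau_3D)))
    g_2D <- (1 - p$f_3D) / (1 + tau / p$tau_2D)
    expect_equal(model_membrane_acf(tau, p), g_T * (g_3D + g_2D) / p$N,
                 tolerance = 1e-12)
    expect_equal(model_membrane_acf(tau, p, combine = "product"),
                 g_T * g_3D * g_2D / p$N, tolerance = 1e-12)
  }
})

test_that("membrane ACF limits: amplitude 1/N, reduction to the 3D model", {
  p <- acf_params(N = 10, f_T = 0, f_3D = 0.5, tau_3D = 3e-4, tau_2D = 0.05)
  expect_equal(model_membrane_acf(1e-12, p), 0.1, tolerance = 1e-6)
  p3 <- acf_params(N = 7, f_T = 0, f_3D = 1, tau_3D = 3e-4)
  tau <- fcs_lag_grid(40)
  expect_equal(model_membrane_acf(tau, p3),
               model_solution_acf(tau, 7, 3e-4, 6), tolerance = 1e-12)
})

test_that("solution ACF: half amplitude at the diffusion time for large AR", {
  expect_equal(model_solution_acf(3e-4, 1, 3e-4, AR = 1e9), 0.5,
               tolerance = 1e-6)
  expect_equal(model_solution_acf(0, 5, 3e-4), 0.2)
  set.seed(5)
  for (i in 1:10) {
    N <- runif(1, 1, 50); tD <- 10^runif(1, -5, -2); AR <- runif(1, 3, 9)
    tau <- 10^runif(5, -6, -1)
    expect_equal(model_solution_acf(tau, N, tD, AR),
                 (1 / N) / ((1 + tau / tD) * sqrt(1 + tau / (AR^2 * tD))),
                 tolerance = 1e-12)
  }
})

test_that("noiseless curves are refit to machine precision (generator oracle)", {
  # solution model
  tau <- fcs_lag_grid()
  cv <- correlation_curve(tau, model_solution_acf(tau, 5, 1e-4),
                          mean_intensity = 50)
  f <- suppressWarnings(fit_acf(cv, "solution"))
  expect_equal(unname(f$params["N"]), 5, tolerance = 1e-6)
  expect_equal(unname(f$params["tau_3D"]), 1e-4, tolerance = 1e-6)
  expect_equal(f$CPP, 10, tolerance = 1e-6)           # CPP = F/N
  # membrane model with a 90 ms membrane transit
  p <- acf_params(N = 20, f_T = 0.15, tau_T = 8e-6, f_3D = 0.3,
                  tau_3D = 4e-4, tau_2D = 0.09)
  f2 <- suppressWarnings(fit_acf(make_membrane_curve(p), "membrane"))
  for (nm in c("N", "f_T", "tau_T", "f_3D", "tau_3D", "tau_2D")) {
    expect_equal(unname(f2$params[nm]), p[[nm]], tolerance = 1e-6)
  }
  expect_true(f2$converged)
})

test_that("CPP times N equals the curve's mean intensity for every fit", {
  set.seed(33)
  for (i in 1:5) {
    p <- draw_membrane_params()
    F_kHz <- runif(1, 10, 200)
    f <- suppressWarnings(fit_acf(make_membrane_curve(p, F_kHz), "membrane"))
    expect_equal(f$CPP * unname(f$params["N"]), F_kHz, tolerance = 1e-9)
  }
})

test_that("run curation keeps flat traces and rejects drifts and spikes", {
  set.seed(9)
  flat <- 100 + rnorm(500)
  drifting <- 100 + seq(0, 30, length.out = 500) + rnorm(500)
  spiky <- flat
  spiky[250] <- 10 * mean(flat)
  cur <- curate_runs(list(flat, drifting, spiky, flat + rnorm(500)))
  expect_equal(cur$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cur$n_kept, 2)
  # a dataset reduced below 2 runs is flagged for downstream refusal
  expect_warning(curate_runs(list(flat, drifting, spiky)), "appropriate runs")
  expect_error(curate_runs(list(drifting)), "no usable runs")
})

test_that("FCCS amplitude corrections behave as constructed", {
  # ideal co-diffusion: every particle in both channels -> rel_cc ~ 1
  mk <- function(N, F) {
    tau <- 10^seq(-4, 0, length.out = 60)
    correlation_curve(tau, model_2d_acf(tau, N, 0.03), mean_intensity = F)
  }
  res <- suppressWarnings(fccs_relative_amplitude(
    mk(10, 100), mk(10, 80), mk(10, 90), crosstalk_gr = 0))
  expect_equal(res$rel_cc, 1, tolerance = 1e-6)
  # no co-diffusion: tiny cross amplitude stays tiny after corrections
  res0 <- suppressWarnings(fccs_relative_amplitude(
    mk(10, 100), mk(10, 80), mk(1e5, 90), crosstalk_gr = 0))
  expect_lt(res0$rel_cc, 1e-3)
  # background correction is identity at B = 0 and monotone increasing in B
  amps <- vapply(c(0, 10, 20, 40), function(B) {
    suppressWarnings(fccs_relative_amplitude(
      mk(10, 100), mk(20, 80), mk(30, 90),
      background = c(green = B, red = 0), crosstalk_gr = 0))$G_g
  }, numeric(1))
  expect_equal(amps[1], 0.1, tolerance = 1e-6)
  expect_true(all(diff(amps) > 0))
  # joint detector-gain rescaling leaves rel_cc unchanged: amplitudes are
  # intensity-normalized, so scaling both F values cancels
  r1 <- suppressWarnings(fccs_relative_amplitude(
    mk(10, 100), mk(20, 80), mk(30, 90), crosstalk_gr = 0))
  r2 <- suppressWarnings(fccs_relative_amplitude(
    mk(10, 200), mk(20, 160), mk(30, 180), crosstalk_gr = 0))
  expect_equal(r1$rel_cc, r2$rel_cc, tolerance = 1e-9)
  expect_error(
    suppressWarnings(fccs_relative_amplitude(
      mk(10, 5), mk(10, 80), mk(10, 90),
      background = c(green = 10, red = 0))),
    "background exceeds signal")
})

test_that("cross-talk correction removes pure bleed-through cross-correlation", {
  # construct measured curves for two independent (non-co-diffusing) pools
  # with kappa bleed-through: cov_meas = kappa * var_g
  kappa <- 0.05
  N_g <- 10; N_r <- 20
  F_g <- 100; F_r_true <- 50
  F_r_meas <- F_r_true + kappa * F_g
  G_g <- 1 / N_g
  G_r_meas <- ((1 / N_r) * F_r_true^2 + kappa^2 * G_g * F_g^2) / F_r_meas^2
  G_x_meas <- kappa * G_g * F_g^2 / (F_g * F_r_meas)
  tau <- 10^seq(-4, 0, length.out = 60)
  shape <- function(G0, F) correlation_curve(
    tau, G0 * model_2d_acf(tau, 1, 0.03), mean_intensity = F)
  res <- suppressWarnings(fccs_relative_amplitude(
    shape(G_g, F_g), shape(G_r_meas, F_r_meas), shape(G_x_meas, F_r_meas),
    crosstalk_gr = kappa))
  expect_equal(res$G_x, 0, tolerance = 1e-8)
  expect_equal(res$G_r, 1 / N_r, tolerance = 1e-6)
  expect_equal(res$F_r, F_r_true, tolerance = 1e-9)
})
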