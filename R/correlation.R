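# ---- FCS / FCCS correlation analysis --------------------------------------

#' Correlation curve container
#'
#' Lag-time/amplitude pairs from one detection channel together with the
#' acquisition metadata needed downstream (mean count rate for CPP, run id
#' for curation).
#'
#' @param lags strictly increasing lag times (s).
#' @param G correlation amplitudes (dimensionless).
#' @param channel detector identifier, e.g. "green".
#' @param mean_intensity mean count rate F (kHz).
#' @param duration recording duration (s).
#' @param run_id integer run index.
#' @return object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, G, channel = "green",
                              mean_intensity = NA_real_,
                              duration = NA_real_, run_id = 1L) {
  stopifnot(is.numeric(lags), is.numeric(G), length(lags) == length(G))
  if (length(lags) < 2 || any(diff(lags) <= 0)) {
    stop("correlation_curve: lags must be strictly increasing")
  }
  if (!all(is.finite(G))) stop("correlation_curve: non-finite amplitudes")
  if (!is.na(mean_intensity) && mean_intensity < 0) {
    stop("correlation_curve: mean_intensity must be >= 0")
  }
  structure(list(lags = lags, G = G, channel = channel,
                 mean_intensity = mean_intensity,
                 duration = duration, run_id = as.integer(run_id)),
            class = "correlation_curve")
}

#' Model parameters for the membrane autocorrelation function
#'
#' Parameters of the two-component (3D + 2D) diffusion model with triplet
#' blinking used for autocorrelation curves recorded at the plasma membrane
#' in the presence of freely diffusing ligand.
#'
#' @param N total mean particle number in the observation volume (> 0).
#' @param f_T triplet fraction in `[0, 1)`.
#' @param tau_T triplet residence time (s); fitted within 1--100 us.
#' @param f_3D fraction of the freely diffusing (3D) species in `[0, 1]`.
#' @param tau_3D 3D diffusion time (s); fitted within 100 us -- 3 ms.
#' @param tau_2D 2D (membrane) diffusion time (s); fitted within 3--300 ms.
#' @param AR axis ratio of the observation volume, fixed to 6 by default.
#' @return object of class `acf_params`.
#' @export
acf_params <- function(N, f_T = 0, tau_T = 5e-6, f_3D = 0, tau_3D = 5e-4,
                       tau_2D = 5e-2, AR = 6) {
  stopifnot(N > 0, f_T >= 0, f_T < 1, f_3D >= 0, f_3D <= 1,
            tau_T > 0, tau_3D > 0, tau_2D > 0, AR > 0)
  structure(list(N = N, f_T = f_T, tau_T = tau_T, f_3D = f_3D,
                 tau_3D = tau_3D, tau_2D = tau_2D, AR = AR),
            class = "acf_params")
}

#' Membrane autocorrelation model (3D + 2D diffusion with triplet)
#'
#' G(tau) = (1/N) G_T(tau) (G_3D(tau) + G_2D(tau)) with
#' G_T = 1 + f_T exp(-tau/tau_T)/(1 - f_T),
#' G_3D = f_3D (1 + tau/tau_3D)^-1 (1 + tau/(AR^2 tau_3D))^-1/2,
#' G_2D = (1 - f_3D) / (1 + tau/tau_2D).
#'
#' The additive combination of the two diffusing components satisfies
#' G(0) = 1/N for f_T = 0, which the brightness definition CPP = F/N
#' requires. A product combination of the component terms is available via
#' `combine = "product"` for comparison only; its zero-lag amplitude is
#' f_3D (1 - f_3D) / N and it is not used for fitting.
#'
#' @param tau lag times (s).
#' @param p an [acf_params()] object.
#' @param combine `"additive"` (default) or `"product"`.
#' @return model amplitudes at `tau`.
#' @export
model_membrane_acf <- function(tau, p, combine = c("additive", "product")) {
  combine <- match.arg(combine)
  stopifnot(inherits(p, "acf_params"))
  g_T <- 1 + p$f_T * exp(-tau / p$tau_T) / (1 - p$f_T)
  g_3D <- p$f_3D * (1 + tau / p$tau_3D)^-1 *
    (1 + tau / (p$AR^2 * p$tau_3D))^-0.5
  g_2D <- (1 - p$f_3D) / (1 + tau / p$tau_2D)
  if (combine == "additive") {
    (1 / p$N) * g_T * (g_3D + g_2D)
  } else {
    (1 / p$N) * g_T * g_3D * g_2D
  }
}

#' Single-species 3D autocorrelation model
#'
#' G(tau) = (1/N) (1 + tau/tau_3D)^-1 (1 + tau/(AR^2 tau_3D))^-1/2,
#' the solution-FCS model used for brightness calibration and supernatant
#' concentration measurements.
#'
#' @param tau lag times (s).
#' @param N mean particle number.
#' @param tau_3D diffusion time (s).
#' @param AR axis ratio (default 6).
#' @return model amplitudes at `tau`.
#' @export
model_solution_acf <- function(tau, N, tau_3D, AR = 6) {
  stopifnot(N > 0, tau_3D > 0, AR > 0)
  (1 / N) * (1 + tau / tau_3D)^-1 * (1 + tau / (AR^2 * tau_3D))^-0.5
}

#' Single-species 2D (membrane) autocorrelation model
#'
#' G(tau) = (1/N) / (1 + tau/tau_2D); used for FCCS cross-correlation
#' curves of co-diffusing membrane species.
#'
#' @param tau lag times (s).
#' @param N mean particle number.
#' @param tau_2D 2D diffusion time (s).
#' @return model amplitudes at `tau`.
#' @export
model_2d_acf <- function(tau, N, tau_2D) {
  stopifnot(N > 0, tau_2D > 0)
  (1 / N) / (1 + tau / tau_2D)
}

#' Default fit bounds for autocorrelation models
#'
#' Triplet time 1--100 us, 3D diffusion time 100 us -- 3 ms, 2D diffusion
#' time 3--300 ms; fractions in `[0, 1]`, N in (0, Inf).
#'
#' @param model `"membrane"`, `"solution"`, or `"2d"`.
#' @return list with `lower` and `upper` named numeric vectors.
#' @export
default_acf_bounds <- function(model = c("membrane", "solution", "2d")) {
  model <- match.arg(model)
  switch(model,
    membrane = list(
      lower = c(N = 1e-3, f_T = 0, tau_T = 1e-6, f_3D = 0,
                tau_3D = 1e-4, tau_2D = 3e-3),
      upper = c(N = 1e6, f_T = 0.999, tau_T = 1e-4, f_3D = 1,
                tau_3D = 3e-3, tau_2D = 0.3)
    ),
    solution = list(
      lower = c(N = 1e-3, tau_3D = 1e-6),
      upper = c(N = 1e6, tau_3D = 1)
    ),
    `2d` = list(
      lower = c(N = 1e-3, tau_2D = 1e-4),
      upper = c(N = 1e6, tau_2D = 10)
    )
  )
}

# Deterministic start: bound midpoints (geometric mean for scale parameters,
# arithmetic for fractions), optionally followed by jittered restarts.
.acf_start <- function(bounds, restart = 0L) {
  lo <- bounds$lower
  hi <- bounds$upper
  start <- numeric(length(lo))
  names(start) <- names(lo)
  for (nm in names(lo)) {
    if (grepl("^f_", nm)) {
      start[nm] <- (lo[nm] + hi[nm]) / 2
    } else {
      start[nm] <- sqrt(max(lo[nm], 1e-12) * hi[nm])
    }
  }
  if (restart > 0) {
    # deterministic low-discrepancy jitter so retries explore the box
    frac <- ((restart * c(2, 3, 5, 7, 11, 13)[seq_along(start)]) %% 17) / 17
    for (i in seq_along(start)) {
      if (grepl("^f_", names(start)[i])) {
        start[i] <- lo[i] + frac[i] * (hi[i] - lo[i]) * 0.98 + 0.01 * (hi[i] - lo[i])
      } else {
        start[i] <- exp(log(max(lo[i], 1e-12)) +
                          frac[i] * (log(hi[i]) - log(max(lo[i], 1e-12))))
      }
    }
  }
  start
}

.acf_model_fun <- function(model) {
  switch(model,
    membrane = function(tau, par, AR) {
      p <- acf_params(N = par["N"], f_T = min(par["f_T"], 0.999),
                      tau_T = par["tau_T"], f_3D = min(par["f_3D"], 1),
                      tau_3D = par["tau_3D"], tau_2D = par["tau_2D"], AR = AR)
      model_membrane_acf(tau, p)
    },
    solution = function(tau, par, AR) {
      model_solution_acf(tau, par["N"], par["tau_3D"], AR)
    },
    `2d` = function(tau, par, AR) {
      model_2d_acf(tau, par["N"], par["tau_2D"])
    }
  )
}

#' Fit an autocorrelation model to a correlation curve
#'
#' Bounded Levenberg-Marquardt least squares with the membrane-model
#' constraints (triplet 1--100 us, 3D 100 us -- 3 ms, 2D 3--300 ms) and the
#' axis ratio fixed to 6 unless overridden. Scale parameters (N and the
#' diffusion/triplet times) are fitted in log space; fractions on the
#' natural scale. The fit starts from the bound midpoints and retries from
#' deterministic jittered starts if convergence is poor.
#'
#' The molecular brightness CPP = F/N is reported from the fitted particle
#' number and the curve's mean intensity.
#'
#' @param curve a [correlation_curve()].
#' @param model `"membrane"`, `"solution"`, or `"2d"`.
#' @param init optional named numeric start values (subset allowed).
#' @param bounds optional list(lower, upper) overriding
#'   [default_acf_bounds()].
#' @param AR fixed axis ratio (default 6).
#' @param weights optional residual weights (default unweighted).
#' @param max_restarts number of jittered restarts on poor convergence.
#' @return list with `params` (named estimates), `CPP` (kHz), `resid_norm`,
#'   `converged`, `at_bound` (names of parameters within 0.1% of a bound),
#'   `model`, and the curve.
#' @export
fit_acf <- function(curve, model = c("membrane", "solution", "2d"),
                    init = NULL, bounds = NULL, AR = 6, weights = NULL,
                    max_restarts = 8L) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "correlation_curve"))
  if (is.null(bounds)) bounds <- default_acf_bounds(model)
  lo <- bounds$lower
  hi <- bounds$upper
  par_names <- names(lo)
  is_frac <- grepl("^f_", par_names)
  tau <- curve$lags
  G <- curve$G
  if (is.null(weights)) weights <- rep(1, length(G))
  fn <- .acf_model_fun(model)

  # transform: log for scale parameters, identity for fractions
  tr <- function(p) ifelse(is_frac, p, log(p))
  inv <- function(q) {
    p <- ifelse(is_frac, q, exp(q))
    names(p) <- par_names
    p
  }
  resid_fun <- function(q) {
    p <- inv(q)
    (fn(tau, p, AR) - G) * weights
  }

  best <- NULL
  for (r in 0:max_restarts) {
    start <- .acf_start(bounds, restart = r)
    if (!is.null(init)) start[names(init)] <- init
    start <- pmin(pmax(start, lo), hi)
    out <- tryCatch(
      minpack.lm::nls.lm(
        par = tr(start), lower = tr(lo), upper = tr(hi), fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
      error = function(e) NULL)
    if (is.null(out)) next
    rn <- sqrt(sum(out$fvec^2))
    if (is.null(best) || rn < best$rn) {
      best <- list(fit = out, rn = rn)
    }
    # noiseless-quality fit: residual tiny relative to curve scale
    if (rn <= 1e-9 * sqrt(sum((G * weights)^2)) + 1e-14) break
  }
  if (is.null(best)) {
    return(list(params = NULL, CPP = NA_real_, resid_norm = NA_real_,
                converged = FALSE, at_bound = character(0), model = model,
                curve = curve))
  }
  est <- inv(best$fit$par)
  # closeness to a bound judged on the fitting scale (log for rates/times)
  at_bound <- vapply(par_names, function(nm) {
    if (is_frac[match(nm, par_names)]) {
      rng <- hi[nm] - lo[nm]
      (est[nm] - lo[nm]) < 1e-3 * rng || (hi[nm] - est[nm]) < 1e-3 * rng
    } else {
      est[nm] <= lo[nm] * 1.001 || est[nm] >= hi[nm] * 0.999
    }
  }, logical(1))
  at_bound <- par_names[at_bound]
  if (length(at_bound)) {
    warning("fit_acf: parameter(s) at bound: ", paste(at_bound, collapse = ", "))
  }
  converged <- best$fit$info %in% 1:4
  if (!converged) warning("fit_acf: optimizer did not report convergence")
  list(
    params = est,
    CPP = if (is.na(curve$mean_intensity)) NA_real_ else
      curve$mean_intensity / est[["N"]],
    resid_norm = best$rn,
    converged = converged,
    at_bound = at_bound,
    model = model,
    curve = curve
  )
}

#' Curate fluctuation runs by drift and spike rejection
#'
#' Discards a run when the fitted linear intensity drift across the run
#' exceeds `drift_threshold` of the mean intensity, or when any intensity
#' bin exceeds mean + `spike_threshold` standard deviations. Datasets
#' keeping fewer than `min_runs` runs are unusable downstream.
#'
#' @param traces list of numeric intensity traces (one per run), or a list
#'   of lists with elements `intensity` and optional `run_id`.
#' @param drift_threshold maximal |relative drift| over the run (default 0.1).
#' @param spike_threshold spike cut in SDs above the mean (default 5).
#' @param min_runs minimal number of surviving runs (default 2).
#' @return list with `keep` (logical), `report` (data.frame with drift and
#'   spike diagnostics per run), and `n_kept`. Errors when no run survives.
#' @export
curate_runs <- function(traces, drift_threshold = 0.1, spike_threshold = 5,
                        min_runs = 2L) {
  if (length(traces) < 1) stop("curate_runs: no runs supplied")
  if (is.numeric(traces)) traces <- list(traces)
  get_int <- function(x) if (is.list(x)) x$intensity else x
  n <- length(traces)
  drift <- spike <- numeric(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    y <- get_int(traces[[i]])
    t <- seq_along(y)
    m <- mean(y)
    slope <- stats::coef(stats::lm(y ~ t))[2]
    drift[i] <- abs(slope) * length(y) / max(m, .Machine$double.eps)
    s <- stats::sd(y)
    spike[i] <- if (s > 0) max((y - m) / s) else 0
    keep[i] <- drift[i] <= drift_threshold && spike[i] <= spike_threshold
  }
  if (!any(keep)) stop("curate_runs: no usable runs (all discarded)")
  if (sum(keep) < min_runs) {
    warning(sprintf("curate_runs: only %d run(s) kept; datasets need >= %d appropriate runs",
                    sum(keep), min_runs))
  }
  list(keep = keep,
       report = data.frame(run = seq_len(n), rel_drift = drift,
                           max_spike_sd = spike, kept = keep),
       n_kept = sum(keep))
}

# amplitude of a curve = fitted zero-lag value of the 2D diffusion model
.fccs_amplitude <- function(curve) {
  f <- fit_acf(curve, model = "2d")
  1 / f$params[["N"]]
}

#' Relative cross-correlation amplitude with background and cross-talk
#' corrections
#'
#' The auto- and cross-correlation amplitudes (zero-lag values from 2D
#' diffusion-model fits) are corrected for non-correlated background by
#' multiplying each autocorrelation amplitude with `(F/(F - B))^2` and the
#' cross-correlation amplitude with the product of the two channel factors.
#' Spectral cross-talk of a fraction `crosstalk_gr` of green counts into
#' the red channel is then removed via
#'
#'   G_x = (G_x' F_g F_r' - k G_g F_g^2) / ((F_r' - k F_g) F_g),
#'   G_r = (G_r' F_r'^2 - k^2 G_g F_g^2 - 2 k Cov_gr) / (F_r' - k F_g)^2,
#'
#' where primed quantities are measured, k is the cross-talk fraction and
#' Cov_gr the corrected count-rate covariance. The relative cross-correlation
#' amplitude (the co-diffusion readout) is the corrected cross amplitude
#' divided by the corrected amplitude of the `denominator` channel.
#'
#' @param green,red,cross [correlation_curve()]s of one measurement; their
#'   `mean_intensity` fields must be set (kHz).
#' @param background per-channel background count rates in kHz, named
#'   `c(green =, red =)` (default 0).
#' @param crosstalk_gr fraction of green signal detected in red (default 0.01).
#' @param denominator `"green"` (default) or `"red"`.
#' @return object of class `fccs_result` with `rel_cc`, corrected
#'   amplitudes `G_g`, `G_r`, `G_x`, the corrected count rates, and flags.
#' @export
fccs_relative_amplitude <- function(green, red, cross,
                                    background = c(green = 0, red = 0),
                                    crosstalk_gr = 0.01,
                                    denominator = c("green", "red")) {
  denominator <- match.arg(denominator)
  for (cv in list(green, red, cross)) {
    stopifnot(inherits(cv, "correlation_curve"))
    if (is.na(cv$mean_intensity)) {
      stop("fccs_relative_amplitude: curves need mean_intensity (kHz)")
    }
  }
  B_g <- unname(background["green"])
  B_r <- unname(background["red"])
  if (is.na(B_g)) B_g <- 0
  if (is.na(B_r)) B_r <- 0
  F_g <- green$mean_intensity
  F_r <- red$mean_intensity
  if (B_g >= F_g || B_r >= F_r) {
    stop("fccs_relative_amplitude: background exceeds signal")
  }
  G_g_m <- .fccs_amplitude(green)
  G_r_m <- .fccs_amplitude(red)
  G_x_m <- .fccs_amplitude(cross)

  # background correction on amplitudes, then on count rates
  cf_g <- F_g / (F_g - B_g)
  cf_r <- F_r / (F_r - B_r)
  G_g <- G_g_m * cf_g^2
  G_r <- G_r_m * cf_r^2
  G_x <- G_x_m * cf_g * cf_r
  F_g <- F_g - B_g
  F_r <- F_r - B_r

  # cross-talk correction (green bleeding into red)
  k <- crosstalk_gr
  if (k > 0) {
    F_r_true <- F_r - k * F_g
    if (F_r_true <= 0) stop("fccs_relative_amplitude: cross-talk exceeds red signal")
    cov_gr <- G_x * F_g * F_r - k * G_g * F_g^2
    G_x <- cov_gr / (F_g * F_r_true)
    var_r <- G_r * F_r^2 - k^2 * G_g * F_g^2 - 2 * k * cov_gr
    G_r <- var_r / F_r_true^2
    F_r <- F_r_true
  }
  denom_amp <- if (denominator == "green") G_g else G_r
  structure(list(
    rel_cc = G_x / denom_amp,
    G_g = G_g, G_r = G_r, G_x = G_x,
    F_g = F_g, F_r = F_r,
    corrected = TRUE,
    background_rates = c(green = B_g, red = B_r),
    crosstalk_gr = crosstalk_gr,
    denominator = denominator
  ), class = "fccs_result")
}
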