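# ---- physical calibration -------------------------------------------------
# Internal unit conventions: lengths in um, times in s, powers in uW,
# concentrations in mol/L. Converters live at the I/O boundary.

AVOGADRO <- 6.02214076e23

#' Dynamic viscosity of water
#'
#' Vogel-Fulcher-Tammann correlation eta = A * 10^(B / (T - C)) with
#' A = 2.414e-2 mPa s, B = 247.8 K, C = 140 K, accurate to ~1% between
#' 0 and 100 degC (e.g. 0.8900 mPa s at 25 degC, 0.8324 mPa s at 28 degC).
#'
#' @param temp_c temperature in degrees Celsius.
#' @return viscosity in mPa s.
#' @export
water_viscosity <- function(temp_c) {
  stopifnot(is.numeric(temp_c), all(is.finite(temp_c)))
  if (any(temp_c < -5 | temp_c > 100)) {
    stop("water_viscosity: temperature outside the liquid range")
  }
  2.414e-2 * 10^(247.8 / (temp_c + 273.15 - 140))
}

#' Reference dye for focal-volume calibration
#'
#' @param name dye identifier, e.g. "ATTO655-COOH".
#' @param D_ref translational diffusion coefficient (um^2/s) at `T_ref`.
#' @param T_ref reference temperature (degC) of `D_ref`.
#' @return an object of class `standard_dye`.
#' @export
standard_dye <- function(name, D_ref, T_ref = 25) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(D_ref) || length(D_ref) != 1 || !is.finite(D_ref) || D_ref <= 0) {
    stop("standard_dye: D_ref must be a positive number")
  }
  structure(list(name = name, D_ref = D_ref, T_ref = T_ref),
            class = "standard_dye")
}

#' Built-in calibration standards
#'
#' Free dyes with literature diffusion coefficients at 25 degC used to
#' calibrate the confocal observation volume of each laser line.
#'
#' @return named list of [standard_dye()] objects.
#' @export
calibration_standards <- function() {
  list(
    `ATTO488-COOH`  = standard_dye("ATTO488-COOH", 400, 25),
    `Alexa568-COOH` = standard_dye("Alexa568-COOH", 370, 25),
    `ATTO655-COOH`  = standard_dye("ATTO655-COOH", 426, 25),
    `RhodamineB`    = standard_dye("RhodamineB", 450, 25)
  )
}

#' Stokes-Einstein temperature rescaling of a diffusion coefficient
#'
#' D(T2) = D(T1) * (T2/T1) * (eta(T1)/eta(T2)) with temperatures in kelvin
#' and the built-in water-viscosity correlation. Used to adjust standard-dye
#' references measured at 25 degC to the focus temperature (typically 28 degC
#' under laser heating).
#'
#' @param D diffusion coefficient (um^2/s) at `T_from`.
#' @param T_from,T_to temperatures in degC.
#' @return rescaled diffusion coefficient (um^2/s).
#' @export
adjust_diffusion_temperature <- function(D, T_from, T_to) {
  stopifnot(is.numeric(D), all(D > 0))
  D * ((T_to + 273.15) / (T_from + 273.15)) *
    (water_viscosity(T_from) / water_viscosity(T_to))
}

#' Beam-waist radius from a standard-dye diffusion time
#'
#' w0 = sqrt(4 * D_t(T_meas) * tau_D_st), where the standard's reference
#' diffusion coefficient is temperature-adjusted by Stokes-Einstein scaling.
#'
#' @param dye a [standard_dye()].
#' @param tau_D_st fitted diffusion time of the standard (s).
#' @param T_meas temperature at the focus (degC); defaults to the dye's
#'   reference temperature (no adjustment).
#' @return beam-waist radius w0 (um).
#' @export
beam_waist_from_standard <- function(dye, tau_D_st, T_meas = dye$T_ref) {
  stopifnot(inherits(dye, "standard_dye"))
  if (!is.numeric(tau_D_st) || length(tau_D_st) != 1 ||
      !is.finite(tau_D_st) || tau_D_st <= 0) {
    stop("beam_waist_from_standard: tau_D_st must be a positive time in s")
  }
  D <- adjust_diffusion_temperature(dye$D_ref, dye$T_ref, T_meas)
  sqrt(4 * D * tau_D_st)
}

#' Effective confocal observation volume
#'
#' For a 3D Gaussian detection profile with beam waist `w0` and axial
#' half-length z0 = AR * w0: V_eff = pi^(3/2) w0^2 z0 and the equatorial
#' elliptical cross-section A_eff = pi w0 z0 used to convert membrane
#' particle numbers to surface densities.
#'
#' @param w0 beam-waist radius (um).
#' @param AR axis ratio z0/w0 (dimensionless, typically 6).
#' @param laser_line excitation wavelength (nm), optional bookkeeping.
#' @param timestamp acquisition time, optional bookkeeping.
#' @return object of class `focal_volume_calibration` with fields
#'   `laser_line`, `w0`, `z0`, `AR`, `V_eff` (um^3), `A_eff` (um^2).
#' @export
effective_volume <- function(w0, AR = 6, laser_line = NA_real_, timestamp = NULL) {
  if (!is.numeric(w0) || length(w0) != 1 || !is.finite(w0) || w0 <= 0) {
    stop("effective_volume: w0 must be a positive length in um")
  }
  if (!is.numeric(AR) || length(AR) != 1 || !is.finite(AR) || AR <= 0) {
    stop("effective_volume: AR must be positive")
  }
  z0 <- AR * w0
  structure(list(
    laser_line = laser_line,
    w0 = w0, z0 = z0, AR = AR,
    V_eff = pi^(3 / 2) * w0^2 * z0,
    A_eff = pi * w0 * z0,
    timestamp = timestamp
  ), class = "focal_volume_calibration")
}

#' @export
print.focal_volume_calibration <- function(x, ...) {
  cat(sprintf(
    "Focal volume calibration%s\n  w0 = %.4f um, z0 = %.4f um (AR = %.2f)\n  V_eff = %.4f um^3 (= %.4f fL), A_eff = %.4f um^2\n",
    if (is.na(x$laser_line)) "" else sprintf(" (%g nm)", x$laser_line),
    x$w0, x$z0, x$AR, x$V_eff, x$V_eff, x$A_eff))
  invisible(x)
}

#' Diffusion coefficient from a measured diffusion time
#'
#' D = w0^2 / (4 tau_D); the exact inverse of [beam_waist_from_standard()]
#' at equal temperature.
#'
#' @param w0 calibrated beam waist (um).
#' @param tau_D measured diffusion time (s).
#' @return diffusion coefficient (um^2/s).
#' @export
diffusion_coefficient <- function(w0, tau_D) {
  if (!is.numeric(w0) || any(w0 <= 0) || !all(is.finite(w0))) {
    stop("diffusion_coefficient: w0 must be positive")
  }
  if (!is.numeric(tau_D) || any(tau_D <= 0) || !all(is.finite(tau_D))) {
    stop("diffusion_coefficient: tau_D must be positive")
  }
  w0^2 / (4 * tau_D)
}

#' Excitation power density in the focal spot
#'
#' P_0 = 2 P_tot / (pi w0^2) for total laser power P_tot measured behind
#' the objective.
#'
#' @param P_tot total power (uW); may be zero.
#' @param w0 beam waist (um).
#' @return power density (uW/um^2).
#' @export
power_density <- function(P_tot, w0) {
  if (!is.numeric(P_tot) || any(P_tot < 0)) stop("power_density: P_tot must be >= 0")
  if (!is.numeric(w0) || any(w0 <= 0)) stop("power_density: w0 must be positive")
  2 * P_tot / (pi * w0^2)
}

#' Laser power measurement record
#'
#' @param laser_line wavelength (nm).
#' @param attenuation relative attenuation setting.
#' @param P_tot total power behind the objective (uW).
#' @param time measurement time in days (numeric) or a Date.
#' @param w0 session beam waist (um), optional; if given, P_0 is stored.
#' @return object of class `power_record`.
#' @export
power_record <- function(laser_line, attenuation, P_tot, time, w0 = NULL) {
  stopifnot(is.numeric(P_tot), P_tot >= 0)
  structure(list(
    laser_line = laser_line, attenuation = attenuation,
    P_tot = P_tot, time = as.numeric(time),
    P_0 = if (is.null(w0)) NA_real_ else power_density(P_tot, w0)
  ), class = "power_record")
}

#' Linear laser-ageing trend
#'
#' Ordinary least-squares fit of total power versus time over repeated
#' sessions of one laser line and attenuation setting, monitoring the
#' slow decay of laser output.
#'
#' @param records list of [power_record()]s, or a data.frame with columns
#'   `time` (days), `P_tot` (uW) and optionally `laser_line`, `attenuation`.
#' @return list with `slope` (uW/day), `intercept` (uW), `residual_sd`,
#'   `n`, and the underlying `lm` fit.
#' @export
laser_ageing_trend <- function(records) {
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, inherits, logical(1), "power_record"))) {
    records <- data.frame(
      time = vapply(records, `[[`, numeric(1), "time"),
      P_tot = vapply(records, `[[`, numeric(1), "P_tot"),
      laser_line = vapply(records, `[[`, numeric(1), "laser_line"),
      attenuation = vapply(records, `[[`, numeric(1), "attenuation")
    )
  }
  stopifnot(is.data.frame(records), all(c("time", "P_tot") %in% names(records)))
  if ("laser_line" %in% names(records) &&
      length(unique(records$laser_line)) > 1) {
    stop("laser_ageing_trend: records mix laser lines; fit one line at a time")
  }
  if ("attenuation" %in% names(records) &&
      length(unique(records$attenuation)) > 1) {
    stop("laser_ageing_trend: records mix attenuation settings")
  }
  if (length(unique(records$time)) < 2) {
    stop("laser_ageing_trend: need >= 2 distinct time points")
  }
  fit <- stats::lm(P_tot ~ time, data = records)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    residual_sd = if (nrow(records) > 2) summary(fit)$sigma else 0,
    n = nrow(records),
    fit = fit
  )
}

#' Degree of labeling from absorption spectroscopy
#'
#' DOL = A_dye,max * eps_prot,280 /
#'       ((A_dye,280 - A_dye,max * CF_280) * eps_dye,max),
#' the molar dye-to-protein ratio of a dye conjugate, where CF_280 is the
#' dye's relative absorbance at 280 nm. Scale-invariant in the absorbances.
#'
#' @param A_dye_max absorbance at the dye's absorption maximum.
#' @param A_dye_280 absorbance of the conjugate at 280 nm.
#' @param eps_dye_max dye extinction coefficient (M^-1 cm^-1).
#' @param eps_prot_280 protein extinction coefficient at 280 nm (M^-1 cm^-1).
#' @param CF_280 relative dye absorbance at 280 nm (0 <= CF_280 < 1).
#' @return degree of labeling as a fraction.
#' @export
degree_of_labeling <- function(A_dye_max, A_dye_280, eps_dye_max,
                               eps_prot_280, CF_280) {
  stopifnot(A_dye_max >= 0, A_dye_280 >= 0,
            eps_dye_max > 0, eps_prot_280 > 0,
            CF_280 >= 0, CF_280 < 1)
  denom <- (A_dye_280 - A_dye_max * CF_280) * eps_dye_max
  if (denom <= 0) {
    stop("degree_of_labeling: protein absorbance does not exceed dye bleed-through at 280 nm (inconsistent spectrum)")
  }
  A_dye_max * eps_prot_280 / denom
}

#' Molecular brightness versus excitation power density
#'
#' Least-squares line CPP(P_0) through brightness measurements of one
#' fluorophore at several excitation power densities; used to look up the
#' brightness at the power density an image was recorded with.
#'
#' @param P_0 excitation power densities (uW/um^2).
#' @param CPP counts per particle (kHz).
#' @return object of class `brightness_model` with `slope`
#'   (kHz per uW/um^2), `intercept` (kHz), and the measured range.
#' @export
brightness_vs_power <- function(P_0, CPP) {
  stopifnot(is.numeric(P_0), is.numeric(CPP), length(P_0) == length(CPP))
  if (length(unique(P_0)) < 2) {
    stop("brightness_vs_power: need >= 2 distinct power densities")
  }
  fit <- stats::lm(CPP ~ P_0)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    range = range(P_0),
    fit = fit
  ), class = "brightness_model")
}

#' Predict brightness at a given power density
#'
#' Interpolates on the [brightness_vs_power()] line; extrapolation beyond
#' the measured range triggers a warning.
#'
#' @param object a `brightness_model`.
#' @param P_0 power densities (uW/um^2) to evaluate.
#' @param ... unused.
#' @return predicted CPP (kHz).
#' @export
predict.brightness_model <- function(object, P_0, ...) {
  if (any(P_0 < object$range[1] | P_0 > object$range[2])) {
    warning("brightness model evaluated outside the measured power range (extrapolation)")
  }
  object$intercept + object$slope * P_0
}

#' Particle number to molar concentration
#'
#' c = N / (N_A V_eff) with Avogadro's number and the effective volume in
#' um^3 (1 um^3 = 1e-15 L).
#'
#' @param N mean particle number in the observation volume.
#' @param V_eff effective volume (um^3).
#' @return concentration in mol/L.
#' @export
concentration_from_particles <- function(N, V_eff) {
  stopifnot(is.numeric(N), all(N >= 0))
  if (!is.numeric(V_eff) || any(V_eff <= 0)) {
    stop("concentration_from_particles: V_eff must be positive")
  }
  N / (AVOGADRO * V_eff * 1e-15)
}
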