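# shared fixtures built in code

# dense quasi-log lag grid covering triplet to membrane time scales
fcs_lag_grid <- function(n = 200) 10^seq(-6.3, 0.3, length.out = n)

# noiseless membrane-model curve from known parameters
make_membrane_curve <- function(p, F_kHz = 100) {
  tau <- fcs_lag_grid()
  correlation_curve(tau, model_membrane_acf(tau, p), mean_intensity = F_kHz)
}

# random membrane-model parameters comfortably inside the fit bounds
draw_membrane_params <- function() {
  acf_params(
    N = stats::runif(1, 0.5, 200),
    f_T = stats::runif(1, 0.05, 0.4),
    tau_T = 10^stats::runif(1, log10(2e-6), log10(8e-5)),
    f_3D = stats::runif(1, 0.1, 0.9),
    tau_3D = 10^stats::runif(1, log10(1.5e-4), log10(2.5e-3)),
    tau_2D = 10^stats::runif(1, log10(4e-3), log10(2.5e-1))
  )
}

# reference focal-volume calibration used across imaging tests
test_calib <- function() effective_volume(0.2, 6, laser_line = 488)

# rigid rotation + translation applied to an n x 3 coordinate matrix
rigid_transform <- function(xyz, angle = 0.5, axis = c(0, 0, 1),
                            shift = c(5, 3, -2)) {
  axis <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + s1 * K + (1 - c1) * K %*% K
  xyz %*% t(R) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
}
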