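# ---- binding statistics and labeling kinetics -----------------------------

#' Hill binding model
#'
#' theta(c) = A / (1 + (c0/c)^n) + A0, the fraction of receptors bound at
#' free-ligand concentration c, with saturating fraction A, background A0,
#' dissociation constant c0 and Hill coefficient n.
#'
#' @param c free-ligand concentration (mol/L), positive.
#' @param A,A0,c0,n model parameters.
#' @return bound fraction.
#' @export
hill_model <- function(c, A, A0, c0, n = 1) {
  stopifnot(all(c > 0), c0 > 0)
  A / (1 + (c0 / c)^n) + A0
}

#' Titration dataset
#'
#' @param c free-ligand concentrations (mol/L).
#' @param theta bound fractions.
#' @param sigma_c,sigma_theta per-point 1-SD uncertainties (same length or
#'   scalar; default 0).
#' @param n_cells cells per point (bookkeeping).
#' @return data.frame of class `titration_dataset`.
#' @export
titration_dataset <- function(c, theta, sigma_c = 0, sigma_theta = 0,
                              n_cells = NA_integer_) {
  stopifnot(all(c > 0), all(is.finite(theta)),
            all(sigma_c >= 0), all(sigma_theta >= 0))
  out <- data.frame(c = c, theta = theta,
                    sigma_c = rep_len(sigma_c, length(c)),
                    sigma_theta = rep_len(sigma_theta, length(c)),
                    n_cells = rep_len(n_cells, length(c)))
  class(out) <- c("titration_dataset", "data.frame")
  out
}

# single bounded Hill least-squares fit; c0 in log space
.hill_fit_once <- function(c, theta, fix_n = TRUE, start = NULL) {
  n_free <- !fix_n
  par_names <- c("A", "A0", "log_c0", if (n_free) "n")
  if (is.null(start)) {
    start <- c(A = max(theta) - min(theta), A0 = min(theta),
               log_c0 = log(stats::median(c)), if (n_free) c(n = 1))
  }
  lo <- c(A = 0, A0 = -1, log_c0 = log(min(c)) - log(1e3),
          if (n_free) c(n = 0.1))
  hi <- c(A = 10, A0 = 1, log_c0 = log(max(c)) + log(1e3),
          if (n_free) c(n = 10))
  resid <- function(p) {
    n <- if (n_free) p[["n"]] else 1
    hill_model(c, p[["A"]], p[["A0"]], exp(p[["log_c0"]]), n) - theta
  }
  out <- minpack.lm::nls.lm(par = start[par_names], lower = lo[par_names],
                            upper = hi[par_names], fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- out$par
  c(A = p[["A"]], A0 = p[["A0"]], c0 = exp(p[["log_c0"]]),
    n = if (n_free) p[["n"]] else 1,
    converged = as.numeric(out$info %in% 1:4))
}

#' Monte-Carlo Hill fit of a titration curve
#'
#' Fits the Hill equation by nonlinear least squares (c0 in log space),
#' then repeats the fit `n_resamples` times on data perturbed by zero-mean
#' Gaussian noise of width sigma_c (concentration axis) and sigma_theta
#' (occupancy axis) per point, propagating both measurement uncertainties
#' into the parameter estimates. Reported parameters are the mean +/- SD
#' over resamples.
#'
#' @param data a [titration_dataset()] (or data.frame with columns `c`,
#'   `theta`, `sigma_c`, `sigma_theta`).
#' @param fix_n fix the Hill coefficient to 1 (1:1 binding, default TRUE);
#'   set FALSE to fit n.
#' @param n_resamples Monte-Carlo resamples (default 10000).
#' @param seed RNG seed (required for reproducibility).
#' @param perturb which axes to perturb: `"both"` (default), `"x"`, `"y"`.
#' @return object of class `hill_fit` with `base` (point estimates),
#'   `mc_mean`, `mc_sd`, `n_resamples`, `seed`, `failed_fraction`, and a
#'   `flagged` logical set when >20% of resamples failed to converge.
#' @export
hill_fit_mc <- function(data, fix_n = TRUE, n_resamples = 10000, seed = 1,
                        perturb = c("both", "x", "y")) {
  perturb <- match.arg(perturb)
  stopifnot(is.data.frame(data),
            all(c("c", "theta", "sigma_c", "sigma_theta") %in% names(data)))
  if (nrow(data) < 4) stop("hill_fit_mc: need >= 4 titration points")
  base <- .hill_fit_once(data$c, data$theta, fix_n = fix_n)
  start <- c(A = unname(base["A"]), A0 = unname(base["A0"]),
             log_c0 = log(unname(base["c0"])),
             if (!fix_n) c(n = unname(base["n"])))
  set.seed(seed)
  draws <- matrix(NA_real_, n_resamples, 4,
                  dimnames = list(NULL, c("A", "A0", "c0", "n")))
  ok <- logical(n_resamples)
  for (i in seq_len(n_resamples)) {
    ci <- data$c
    yi <- data$theta
    if (perturb %in% c("both", "x")) {
      ci <- ci + stats::rnorm(nrow(data), 0, data$sigma_c)
    }
    if (perturb %in% c("both", "y")) {
      yi <- yi + stats::rnorm(nrow(data), 0, data$sigma_theta)
    }
    ci <- pmax(ci, min(data$c) * 1e-3)   # keep concentrations positive
    fit <- tryCatch(.hill_fit_once(ci, yi, fix_n = fix_n, start = start),
                    error = function(e) NULL)
    if (!is.null(fit) && fit[["converged"]] == 1) {
      draws[i, ] <- fit[c("A", "A0", "c0", "n")]
      ok[i] <- TRUE
    }
  }
  failed <- 1 - mean(ok)
  if (failed > 0.2) {
    warning(sprintf("hill_fit_mc: %.0f%% of resamples failed to converge", 100 * failed))
  }
  structure(list(
    base = base[c("A", "A0", "c0", "n")],
    mc_mean = colMeans(draws[ok, , drop = FALSE]),
    mc_sd = apply(draws[ok, , drop = FALSE], 2, stats::sd),
    n_resamples = n_resamples,
    seed = seed,
    failed_fraction = failed,
    flagged = failed > 0.2
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (Monte Carlo, %d resamples, seed %s)\n",
              x$n_resamples, format(x$seed)))
  for (p in c("A", "A0", "c0", "n")) {
    cat(sprintf("  %-3s = %.4g +/- %.2g\n", p, x$mc_mean[[p]], x$mc_sd[[p]]))
  }
  invisible(x)
}

# generic multi-start bounded LM helper for the kinetics fits
.ms_fit <- function(resid, lo, hi, starts) {
  best <- NULL
  for (s in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lo, upper = hi, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(out)) next
    rn <- sum(out$fvec^2)
    if (is.null(best) || rn < best$rn) best <- list(fit = out, rn = rn)
  }
  best
}

#' Double-exponential labeling kinetics
#'
#' Fits CE(t) = A_fast (1 - exp(-k_fast t)) + A_slow (1 - exp(-k_slow t)),
#' the rising biphasic time course of click-labeling yield, by bounded
#' multi-start least squares (rates in log space). By convention
#' k_fast >= k_slow; the fit is flagged as poorly identifiable when the
#' rate ratio is below 3.
#'
#' @param t time points (minutes), >= 5 values.
#' @param ce click efficiencies at `t`.
#' @return list with `A_fast`, `k_fast`, `A_slow`, `k_slow` (min^-1),
#'   `plateau`, `resid_norm`, `converged`, `identifiable`.
#' @export
fit_double_exponential <- function(t, ce) {
  stopifnot(length(t) == length(ce))
  if (length(t) < 5) stop("fit_double_exponential: need >= 5 time points")
  amp <- max(ce)
  resid <- function(p) {
    p[["Af"]] * (1 - exp(-exp(p[["lkf"]]) * t)) +
      p[["As"]] * (1 - exp(-exp(p[["lks"]]) * t)) - ce
  }
  lo <- c(Af = 0, lkf = log(1e-4), As = 0, lks = log(1e-4))
  hi <- c(Af = 10 * max(amp, 0.1), lkf = log(1e3),
          As = 10 * max(amp, 0.1), lks = log(1e3))
  t_scale <- stats::median(diff(sort(unique(t))))
  starts <- list(
    c(Af = amp / 2, lkf = log(1 / t_scale), As = amp / 2, lks = log(0.01 / t_scale)),
    c(Af = amp * 0.8, lkf = log(0.5), As = amp * 0.2, lks = log(0.01)),
    c(Af = amp * 0.5, lkf = log(2), As = amp * 0.5, lks = log(0.05)),
    c(Af = amp, lkf = log(0.1), As = amp * 0.1, lks = log(0.001))
  )
  best <- .ms_fit(resid, lo, hi, starts)
  if (is.null(best)) stop("fit_double_exponential: all starts failed")
  p <- best$fit$par
  k1 <- exp(p[["lkf"]]); k2 <- exp(p[["lks"]])
  A1 <- p[["Af"]]; A2 <- p[["As"]]
  if (k2 > k1) {        # enforce k_fast >= k_slow
    tmp <- k1; k1 <- k2; k2 <- tmp
    tmp <- A1; A1 <- A2; A2 <- tmp
  }
  list(A_fast = A1, k_fast = k1, A_slow = A2, k_slow = k2,
       plateau = A1 + A2,
       resid_norm = sqrt(best$rn),
       converged = best$fit$info %in% 1:4,
       identifiable = (k1 / k2) >= 3)
}

#' Two-state saturation of click efficiency versus label concentration
#'
#' Fits the sublinear concentration dependence CE(c) = B1 c/(K1 + c) +
#' B2 c/(K2 + c), a sum of two binding hyperbolas representing two
#' reaction-limited states. Degenerate (near-linear) data drive K toward
#' the upper bound and are flagged as a boundary solution.
#'
#' @param conc label concentrations (uM), >= 5 values.
#' @param ce click efficiencies at `conc`.
#' @return list with `B1`, `K1`, `B2`, `K2` (K in the units of `conc`,
#'   K1 <= K2), `resid_norm`, `converged`, `boundary`.
#' @export
fit_two_state_saturation <- function(conc, ce) {
  stopifnot(length(conc) == length(ce))
  if (length(conc) < 5) stop("fit_two_state_saturation: need >= 5 concentrations")
  resid <- function(p) {
    p[["B1"]] * conc / (exp(p[["lK1"]]) + conc) +
      p[["B2"]] * conc / (exp(p[["lK2"]]) + conc) - ce
  }
  cmax <- max(conc); cmin <- min(conc)
  K_hi <- log(cmax * 1e3)
  lo <- c(B1 = 0, lK1 = log(cmin * 1e-3), B2 = 0, lK2 = log(cmin * 1e-3))
  hi <- c(B1 = 10 * max(ce, 0.1), lK1 = K_hi, B2 = 10 * max(ce, 0.1), lK2 = K_hi)
  m <- max(ce)
  starts <- list(
    c(B1 = m / 2, lK1 = log(cmin), B2 = m / 2, lK2 = log(cmax)),
    c(B1 = m, lK1 = log(stats::median(conc)), B2 = m / 4, lK2 = log(cmax * 10)),
    c(B1 = m / 4, lK1 = log(cmin / 10), B2 = m, lK2 = log(stats::median(conc)))
  )
  best <- .ms_fit(resid, lo, hi, starts)
  if (is.null(best)) stop("fit_two_state_saturation: all starts failed")
  p <- best$fit$par
  K1 <- exp(p[["lK1"]]); K2 <- exp(p[["lK2"]])
  B1 <- p[["B1"]]; B2 <- p[["B2"]]
  if (K1 > K2) {
    tmp <- K1; K1 <- K2; K2 <- tmp
    tmp <- B1; B1 <- B2; B2 <- tmp
  }
  B_hi <- 10 * max(ce, 0.1)
  boundary <- log(K2) > K_hi - 1e-3 || log(K1) < log(cmin * 1e-3) + 1e-3 ||
    B1 > 0.999 * B_hi || B2 > 0.999 * B_hi
  if (boundary) warning("fit_two_state_saturation: boundary solution (data close to linear?)")
  list(B1 = B1, K1 = K1, B2 = B2, K2 = K2,
       resid_norm = sqrt(best$rn),
       converged = best$fit$info %in% 1:4,
       boundary = boundary)
}

# small-sample-corrected information criterion
.aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Gaussian-mixture decomposition of single-cell occupancies
#'
#' Fits 1- and 2-component Gaussian mixtures to per-cell occupancy values
#' by maximum-likelihood EM and selects between unimodal and bimodal
#' descriptions with the small-sample-corrected information criterion
#' (AICc). A bimodal result indicates two co-existing receptor states.
#'
#' @param values per-cell occupancies (>= 20 cells).
#' @param k_max maximal number of components (default 2).
#' @return object of class `mixture_fit` with `k` (chosen components),
#'   `weights`, `means`, `sds`, `loglik` per candidate, `aicc` per
#'   candidate.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_occupancy_mixture <- function(values, k_max = 2) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  if (length(values) < 20) stop("fit_occupancy_mixture: need >= 20 cells")
  n <- length(values)
  sd_floor <- 0.01 * diff(range(values))
  fits <- list()
  for (k in seq_len(k_max)) {
    mf <- mclust::Mclust(values, G = k, modelNames = "V", verbose = FALSE)
    if (is.null(mf)) next
    sds <- sqrt(mf$parameters$variance$sigmasq)
    sds <- pmax(sds, sd_floor)
    fits[[k]] <- list(
      k = k,
      weights = mf$parameters$pro,
      means = as.numeric(mf$parameters$mean),
      sds = rep_len(sds, k),
      loglik = mf$loglik,
      df = mf$df
    )
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("fit_occupancy_mixture: EM failed for all k")
  # likelihood must be monotone in k; guard against EM local optima
  for (i in seq_along(fits)[-1]) {
    if (fits[[i]]$loglik < fits[[i - 1]]$loglik) {
      fits[[i]]$loglik <- fits[[i - 1]]$loglik
      fits[[i]]$degenerate_to <- i - 1
      fits[[i]]$weights <- c(fits[[i - 1]]$weights, 0)[seq_len(fits[[i]]$k)]
      fits[[i]]$means <- rep_len(fits[[i - 1]]$means, fits[[i]]$k)
      fits[[i]]$sds <- rep_len(fits[[i - 1]]$sds, fits[[i]]$k)
    }
  }
  aicc <- vapply(fits, function(f) .aicc(f$loglik, f$df, n), numeric(1))
  pick <- fits[[which.min(aicc)]]
  structure(list(
    k = pick$k,
    weights = pick$weights / sum(pick$weights),
    means = pick$means,
    sds = pick$sds,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = aicc,
    n = n
  ), class = "mixture_fit")
}

#' Welch's two-sample t-test
#'
#' Two-sided t-test with unequal variances and Welch-Satterthwaite
#' degrees of freedom; the test used to compare click-efficiency
#' distributions between conditions with unequal cell numbers.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @return list with `t`, `dof`, `p`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("welch_test: each sample needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, dof = length(a) + length(b) - 2, p = 1))
    stop("welch_test: zero variance in both samples")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Monte-Carlo Pearson correlation with measurement uncertainties
#'
#' Pearson r and two-tailed p on the unperturbed data plus mean +/- SD of
#' both over `n_resamples` resamples in which each point is perturbed by
#' zero-mean Gaussian noise of its stated uncertainty.
#'
#' @param x,y paired values (>= 3 pairs).
#' @param sx,sy per-point 1-SD uncertainties (scalar or vector; default 0).
#' @param n_resamples resamples (default 10000).
#' @param seed RNG seed.
#' @return list with `r`, `p` (unperturbed), `r_mc_mean`, `r_mc_sd`,
#'   `p_mc_mean`, `p_mc_sd`, `n_resamples`, `seed`.
#' @export
pearson_mc <- function(x, y, sx = 0, sy = 0, n_resamples = 10000, seed = 1) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("pearson_mc: need >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_mc: constant x or y")
  }
  sx <- rep_len(sx, length(x))
  sy <- rep_len(sy, length(y))
  ct <- stats::cor.test(x, y, method = "pearson")
  set.seed(seed)
  rs <- ps <- numeric(n_resamples)
  for (i in seq_len(n_resamples)) {
    xi <- x + stats::rnorm(length(x), 0, sx)
    yi <- y + stats::rnorm(length(y), 0, sy)
    cti <- stats::cor.test(xi, yi, method = "pearson")
    rs[i] <- unname(cti$estimate)
    ps[i] <- cti$p.value
  }
  list(r = unname(ct$estimate), p = ct$p.value,
       r_mc_mean = mean(rs), r_mc_sd = stats::sd(rs),
       p_mc_mean = mean(ps), p_mc_sd = stats::sd(ps),
       n_resamples = n_resamples, seed = seed)
}

#' Differential click efficiency between occupied and free states
#'
#' For every incorporation site with both conditions, computes
#' dCE = CE_occ - CE_free with the SEM propagated for independent
#' variables, sqrt(SEM_occ^2 + SEM_free^2), and its absolute value.
#' Optionally returns the scaling factor that maps a structural quantity
#' (e.g. RMSD) onto the differential-CE axis by equating the average
#' spread (SD across sites) of the two quantities.
#'
#' @param pattern data.frame with columns `site`, `condition` ("free" or
#'   "occupied"), `ce_mean`, `ce_sem`.
#' @param secondary optional named numeric (site -> structural value) used
#'   to compute the secondary-axis scaling factor.
#' @return data.frame with one row per complete site: `site`, `dce`,
#'   `sem`, `abs_dce`; attribute `scale_factor` when `secondary` is given.
#' @export
differential_ce <- function(pattern, secondary = NULL) {
  stopifnot(is.data.frame(pattern),
            all(c("site", "condition", "ce_mean", "ce_sem") %in% names(pattern)))
  sites <- unique(pattern$site)
  rows <- list()
  for (s in sites) {
    sub <- pattern[pattern$site == s, ]
    f <- sub[sub$condition == "free", ]
    o <- sub[sub$condition == "occupied", ]
    if (nrow(f) != 1 || nrow(o) != 1) {
      warning(sprintf("differential_ce: site '%s' lacks a condition; skipped", s))
      next
    }
    rows[[s]] <- data.frame(
      site = s,
      dce = o$ce_mean - f$ce_mean,
      sem = sqrt(o$ce_sem^2 + f$ce_sem^2)
    )
  }
  if (!length(rows)) stop("differential_ce: no complete sites")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$abs_dce <- abs(out$dce)
  if (!is.null(secondary)) {
    sec <- secondary[match(out$site, names(secondary))]
    if (any(is.na(sec))) {
      warning("differential_ce: secondary values missing for some sites")
    }
    attr(out, "scale_factor") <-
      stats::sd(out$abs_dce) / stats::sd(sec[!is.na(sec)])
  }
  out
}
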