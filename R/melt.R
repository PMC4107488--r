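R_GAS <- 8.314e-3  # kJ/(mol K)

#' Gibbs free energy of unfolding at temperature T
#'
#' Gibbs-Helmholtz form of the two-state model with constant heat-capacity
#' change:
#' dG_U(T) = dHm (1 - T/Tm) - dCp (Tm - T + T ln(T/Tm)).
#'
#' @param temperature Temperature(s), K.
#' @param tm Unfolding midpoint, K.
#' @param dHm van 't Hoff enthalpy at `tm`, kJ/mol.
#' @param dCp Heat-capacity change of unfolding, kJ/(mol K).
#' @return dG_U in kJ/mol.
#' @export
delta_g_unfolding <- function(temperature, tm, dHm, dCp = pab_dcp()) {
  stopifnot(all(temperature > 0), tm > 0)
  dHm * (1 - temperature / tm) -
    dCp * (tm - temperature + temperature * log(temperature / tm))
}

#' Mole fraction of unfolded protein
#'
#' Boltzmann-weighted two-state population:
#' fU = exp(-dG_U/RT) / (1 + exp(-dG_U/RT)); exactly 0.5 at `tm`.
#'
#' @inheritParams delta_g_unfolding
#' @return Fraction unfolded in (0, 1).
#' @export
fraction_unfolded <- function(temperature, tm, dHm, dCp = pab_dcp()) {
  dg <- delta_g_unfolding(temperature, tm, dHm, dCp)
  stats::plogis(-dg / (R_GAS * temperature))
}

two_state_signal <- function(temperature, tm, dHm, dCp, aN, bN, aU, bU) {
  fu <- fraction_unfolded(temperature, tm, dHm, dCp)
  (aN + bN * temperature) * (1 - fu) + (aU + bU * temperature) * fu
}

#' Simulate a CD melting curve
#'
#' Two-state unfolding signal (ellipticity-like units) with linear folded
#' and unfolded baselines and additive Gaussian noise.
#'
#' @inheritParams delta_g_unfolding
#' @param temperature Temperature grid, K (default 278-373 K, 1 K steps, the
#'   usual melting-scan window).
#' @param baselines Numeric vector `c(aN, bN, aU, bU)`: intercept and slope
#'   of the folded (native) and unfolded baselines.
#' @param noise_sd Gaussian noise standard deviation in signal units.
#' @param seed Integer seed.
#' @return Data frame of class `melt_curve` with columns `temperature`,
#'   `signal`; true parameters kept in `attr(, "params")`.
#' @export
simulate_melting_curve <- function(tm, dHm, dCp = pab_dcp(),
                                   temperature = seq(278, 373, by = 1),
                                   baselines = c(aN = -20, bN = 0.01,
                                                 aU = -2, bU = 0.005),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(all(diff(temperature) > 0), length(baselines) == 4L)
  set.seed(seed)
  mu <- two_state_signal(temperature, tm, dHm, dCp,
                         baselines[1], baselines[2],
                         baselines[3], baselines[4])
  curve <- data.frame(temperature = temperature,
                      signal = mu + stats::rnorm(length(mu), 0, noise_sd))
  attr(curve, "params") <- list(tm = tm, dHm = dHm, dCp = dCp,
                                baselines = baselines, noise_sd = noise_sd)
  class(curve) <- c("melt_curve", class(curve))
  curve
}

melt_start_values <- function(temperature, signal) {
  n <- length(temperature)
  k <- max(3L, floor(0.1 * n))
  lo <- seq_len(k)
  hi <- seq(n - k + 1L, n)
  fN <- stats::lm(signal[lo] ~ temperature[lo])
  fU <- stats::lm(signal[hi] ~ temperature[hi])
  aN <- unname(coef(fN)[1]); bN <- unname(coef(fN)[2])
  aU <- unname(coef(fU)[1]); bU <- unname(coef(fU)[2])
  base_n <- aN + bN * temperature
  base_u <- aU + bU * temperature
  fu <- (signal - base_n) / (base_u - base_n)
  fu <- pmin(pmax(fu, 1e-4), 1 - 1e-4)
  # midpoint: first crossing of fu = 0.5
  cross <- which(diff(sign(fu - 0.5)) != 0)
  tm0 <- if (length(cross)) {
    i <- cross[1L]
    stats::approx(fu[c(i, i + 1L)], temperature[c(i, i + 1L)], xout = 0.5,
                  ties = "ordered")$y
  } else {
    temperature[which.min(abs(fu - 0.5))]
  }
  # van 't Hoff slope of logit(fu) in the transition zone
  zone <- which(fu > 0.2 & fu < 0.8)
  dHm0 <- if (length(zone) >= 3L) {
    sl <- unname(coef(stats::lm(stats::qlogis(fu[zone]) ~
                                  temperature[zone]))[2])
    max(50, min(800, sl * R_GAS * tm0^2))
  } else {
    250
  }
  list(tm = tm0, dHm = dHm0, aN = aN, bN = bN, aU = aU, bU = bU)
}

#' Fit the two-state unfolding model to a melting curve
#'
#' Nonlinear least squares over (Tm, dHm, and four baseline coefficients)
#' with the heat-capacity change held fixed, as is standard for small
#' domains where dCp is poorly determined by a single scan. Starting values
#' are data-driven: baselines from the terminal 10% of points, Tm from the
#' apparent-fraction crossing of 0.5, dHm from a van 't Hoff slope.
#'
#' @param curve A `melt_curve`, or any data frame with `temperature` and
#'   `signal` columns.
#' @param dCp_fixed Heat-capacity change held during the fit, kJ/(mol K).
#' @param start Optional named list overriding the automatic starting
#'   values.
#' @return Object of class `melt_fit` with `coef`, `se`, `dCp`, `rms`,
#'   `fit` (the underlying `nls` object), `data`, and `flags`.
#' @export
fit_two_state <- function(curve, dCp_fixed = pab_dcp(), start = NULL) {
  temperature <- curve$temperature
  signal <- curve$signal
  stopifnot(length(temperature) >= 20L, all(diff(temperature) > 0))
  noise_hat <- stats::sd(diff(signal)) / sqrt(2)
  rng <- diff(range(signal))
  if (!is.finite(noise_hat) || rng <= 0 || rng < 6 * noise_hat) {
    stop("no unfolding transition detected: signal range within noise")
  }
  s0 <- melt_start_values(temperature, signal)
  if (!is.null(start)) s0[names(start)] <- start
  dat <- data.frame(temperature = temperature, signal = signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ two_state_signal(temperature, tm, dHm, dCp_fixed,
                                aN, bN, aU, bU),
      data = dat, start = s0,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf(
        "two-state fit did not converge (%s); starting values: tm=%.2f dHm=%.1f",
        conditionMessage(e), s0$tm, s0$dHm))
    })
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  flags <- character(0)
  if (cf[["tm"]] < min(temperature) || cf[["tm"]] > max(temperature)) {
    flags <- c(flags, "transition outside temperature grid")
  }
  structure(list(coef = cf, se = se, dCp = dCp_fixed,
                 rms = sqrt(mean(residuals(fit)^2)), fit = fit, data = dat,
                 flags = flags),
            class = "melt_fit")
}

#' @export
coef.melt_fit <- function(object, ...) object$coef

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state thermal unfolding fit\n")
  cat(sprintf("  Tm  = %.2f K (SE %.3f)\n", x$coef[["tm"]], x$se[["tm"]]))
  cat(sprintf("  dHm = %.1f kJ/mol (SE %.2f)\n",
              x$coef[["dHm"]], x$se[["dHm"]]))
  cat(sprintf("  dCp = %.3f kJ/(mol K) [fixed]\n", x$dCp))
  cat(sprintf("  residual RMS = %.4g\n", x$rms))
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' @export
summary.melt_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coef, se = object$se)
  attr(out, "dCp") <- object$dCp
  out
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  temperature <- if (is.null(newdata)) object$data$temperature else
    newdata$temperature
  cf <- object$coef
  two_state_signal(temperature, cf[["tm"]], cf[["dHm"]], object$dCp,
                   cf[["aN"]], cf[["bN"]], cf[["aU"]], cf[["bU"]])
}

#' @export
residuals.melt_fit <- function(object, ...) {
  object$data$signal - predict(object)
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$data$temperature, x$data$signal, pch = 16, cex = 0.5,
                 xlab = "Temperature (K)", ylab = "Signal", ...)
  graphics::lines(x$data$temperature, predict(x), col = "red2", lwd = 2)
  invisible(x)
}

#' Heat-capacity change from molecular weight
#'
#' Empirical proportionality between protein size and the heat-capacity
#' change of unfolding. The default slope is calibrated so a 6.7 kDa domain
#' (the scanned B domain) gives 2.643 kJ/(mol K); the slope is a convention
#' to be overridden when a calibrated coefficient is available.
#'
#' @param mw Molecular weight, Da.
#' @param slope kJ/(mol K Da).
#' @return dCp in kJ/(mol K).
#' @export
delta_cp_from_mw <- function(mw, slope = pab_dcp() / 6700) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  slope * mw
}

#' Tm shift of a variant relative to wild type
#' @param variant_tm,wt_tm Midpoints in K.
#' @return `variant_tm - wt_tm`.
#' @export
delta_tm <- function(variant_tm, wt_tm) variant_tm - wt_tm
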