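one_to_one_response <- function(time, conc, t_assoc, ka, kd, rmax) {
  kobs <- ka * conc + kd
  req <- ka * conc * rmax / kobs
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(time <= t_assoc,
         req * (1 - exp(-kobs * time)),
         r_end * exp(-kd * (time - t_assoc)))
}

#' Simulate a 1:1 binding sensorgram
#'
#' Langmuir 1:1 interaction: association
#' R(t) = Req (1 - exp(-(ka C + kd) t)) with Req = ka C rmax / (ka C + kd),
#' followed by first-order dissociation from the level reached at the end of
#' the contact time. Gaussian noise is added per point.
#'
#' @param ka Association rate constant, 1/(M s).
#' @param kd Dissociation rate constant, 1/s.
#' @param rmax Saturating response, RU.
#' @param conc Analyte concentration, M.
#' @param t_assoc,t_dissoc Phase durations, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Gaussian noise SD, RU.
#' @param seed Integer seed.
#' @return Data frame of class `sensorgram` with columns `time`, `response`,
#'   `concentration`, `phase`.
#' @export
simulate_sensorgram <- function(ka, kd, rmax, conc, t_assoc = 120,
                                t_dissoc = 300, dt = 1, noise_sd = 0,
                                seed = 1L) {
  stopifnot(ka > 0, kd > 0, rmax > 0, conc > 0, t_assoc > 0, t_dissoc > 0)
  set.seed(seed)
  time <- seq(0, t_assoc + t_dissoc, by = dt)
  mu <- one_to_one_response(time, conc, t_assoc, ka, kd, rmax)
  out <- data.frame(time = time,
                    response = mu + stats::rnorm(length(mu), 0, noise_sd),
                    concentration = conc,
                    phase = ifelse(time <= t_assoc, "association",
                                   "dissociation"),
                    stringsAsFactors = FALSE)
  class(out) <- c("sensorgram", class(out))
  out
}

#' Simulate a multi-concentration sensorgram series
#'
#' @inheritParams simulate_sensorgram
#' @param concs Vector of analyte concentrations, M.
#' @return Stacked data frame of sensorgrams (one per concentration).
#' @export
simulate_sensorgram_set <- function(ka, kd, rmax, concs, t_assoc = 120,
                                    t_dissoc = 300, dt = 1, noise_sd = 0,
                                    seed = 1L) {
  out <- do.call(rbind, lapply(seq_along(concs), function(i) {
    simulate_sensorgram(ka, kd, rmax, concs[i], t_assoc, t_dissoc, dt,
                        noise_sd, seed = seed + i - 1L)
  }))
  class(out) <- c("sensorgram", class(out))
  out
}

spr_start_values <- function(dat) {
  # kd from the dissociation tails; equilibrium half-saturation for KD
  dis <- dat[dat$phase == "dissociation" & dat$response > 0, ]
  kd0 <- 1e-3
  if (nrow(dis) > 10L) {
    t0 <- stats::ave(dis$time, dis$concentration, FUN = min)
    sl <- tryCatch(
      unname(coef(stats::lm(log(dis$response) ~ I(dis$time - t0)))[2]),
      error = function(e) NA_real_)
    if (is.finite(sl) && sl < 0) kd0 <- min(1, max(1e-6, -sl))
  }
  req <- tapply(dat$response[dat$phase == "association"],
                dat$concentration[dat$phase == "association"],
                function(r) stats::quantile(r, 0.98, names = FALSE))
  concs <- as.numeric(names(req))
  half <- max(req) / 2
  kD0 <- if (any(req <= half) && any(req > half)) {
    stats::approx(as.numeric(req), concs, xout = half, ties = "ordered")$y
  } else {
    stats::median(concs)
  }
  if (!is.finite(kD0) || kD0 <= 0) kD0 <- stats::median(concs)
  rmax0 <- max(req) * (1 + kD0 / max(concs))
  list(lka = log(kd0 / kD0), lkd = log(kd0), lrmax = log(rmax0))
}

#' Global 1:1 fit of a sensorgram series
#'
#' Fits a single set of (ka, kd, Rmax) to all concentrations simultaneously
#' (the standard global 1:1 analysis) by nonlinear least squares on
#' log-transformed parameters, and reports KD = kd/ka with a
#' delta-method standard error. The result is censored ("not determinable",
#' as reported for interactions too weak to quantify) when the fit fails,
#' when the fitted KD exceeds 10 times the highest analyte concentration,
#' or when the relative standard error of KD exceeds 100%.
#'
#' @param sensorgrams A stacked sensorgram data frame (columns `time`,
#'   `response`, `concentration`, `phase`) or a list of such data frames;
#'   at least 3 concentrations spanning at least 10-fold.
#' @return Object of class `spr_fit`: list with `ka`, `kd`, `rmax`, `kD`,
#'   `kD_se`, `censored`, `reason`, `fit`, `data`.
#' @export
fit_one_to_one <- function(sensorgrams) {
  dat <- if (is.data.frame(sensorgrams)) sensorgrams else
    do.call(rbind, lapply(sensorgrams, as.data.frame))
  stopifnot(all(c("time", "response", "concentration", "phase") %in%
                  names(dat)))
  concs <- sort(unique(dat$concentration))
  if (length(concs) < 3L || max(concs) / min(concs) < 10) {
    stop("need >= 3 analyte concentrations spanning at least 10-fold")
  }
  # per-curve clock: time measured from each curve's own first sample, so
  # the fit is invariant to a shift of the whole time axis
  dat$time <- dat$time - stats::ave(dat$time, dat$concentration, FUN = min)
  # association end per concentration, from the phase labels
  t_assoc <- tapply(dat$time[dat$phase == "association"],
                    dat$concentration[dat$phase == "association"], max)
  dat$t_assoc <- as.numeric(t_assoc[as.character(dat$concentration)])

  s0 <- spr_start_values(dat)
  censored <- function(reason) {
    structure(list(ka = NA_real_, kd = NA_real_, rmax = NA_real_,
                   kD = NA_real_, kD_se = NA_real_, censored = TRUE,
                   reason = reason, fit = NULL, data = dat),
              class = "spr_fit")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ one_to_one_response(time, concentration, t_assoc,
                                     exp(lka), exp(lkd), exp(lrmax)),
      data = dat, start = s0,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(censored("fit did not converge"))

  cf <- coef(fit)
  ka <- exp(cf[["lka"]]); kd <- exp(cf[["lkd"]]); rmax <- exp(cf[["lrmax"]])
  kD <- kd / ka
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  kD_se <- if (!is.null(vc) && all(is.finite(vc))) {
    v <- vc["lkd", "lkd"] + vc["lka", "lka"] - 2 * vc["lkd", "lka"]
    kD * sqrt(max(v, 0))
  } else {
    NA_real_
  }
  if (kD > 10 * max(concs)) {
    return(censored(sprintf("fitted KD (%.3g M) above 10x highest analyte concentration", kD)))
  }
  if (!is.finite(kD_se) || kD_se / kD > 1) {
    return(censored("relative standard error of KD above 100%"))
  }
  structure(list(ka = ka, kd = kd, rmax = rmax, kD = kD, kD_se = kD_se,
                 censored = FALSE, reason = NULL, fit = fit, data = dat),
            class = "spr_fit")
}

#' @export
coef.spr_fit <- function(object, ...) {
  c(ka = object$ka, kd = object$kd, rmax = object$rmax, kD = object$kD)
}

#' @export
print.spr_fit <- function(x, ...) {
  cat("Global 1:1 binding fit\n")
  if (x$censored) {
    cat("  KD: ND (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("  ka   = %.3g 1/(M s)\n  kd   = %.3g 1/s\n", x$ka, x$kd))
    cat(sprintf("  Rmax = %.3g RU\n  KD   = %.3g M (SE %.2g)\n",
                x$rmax, x$kD, x$kD_se))
  }
  invisible(x)
}

#' @export
predict.spr_fit <- function(object, newdata = NULL, ...) {
  if (object$censored) stop("censored fit has no predictions")
  d <- if (is.null(newdata)) object$data else newdata
  one_to_one_response(d$time, d$concentration, d$t_assoc,
                      object$ka, object$kd, object$rmax)
}

#' @export
residuals.spr_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.spr_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$time, d$response, pch = 16, cex = 0.3,
                 xlab = "Time (s)", ylab = "Response (RU)", ...)
  if (!x$censored) {
    for (cc in unique(d$concentration)) {
      sel <- d$concentration == cc
      graphics::lines(d$time[sel], predict(x)[sel], col = "red2")
    }
  }
  invisible(x)
}

#' KD ratio of a variant relative to a reference
#'
#' @param variant_kD,reference_kD Dissociation constants, M; `NA` marks a
#'   censored (not determinable) value.
#' @return `variant_kD / reference_kD` at 2 significant figures, or `NA`
#'   when either input is censored.
#' @export
kd_ratio <- function(variant_kD, reference_kD) {
  ifelse(is.na(variant_kD) | is.na(reference_kD), NA_real_,
         signif(variant_kD / reference_kD, 2))
}

#' Render a KD ratio for a report table
#' @param ratio Value from [kd_ratio()].
#' @return Character; `"-"` for censored/reference entries.
#' @export
render_kd_ratio <- function(ratio) {
  ifelse(is.na(ratio), "-", format(ratio, trim = TRUE))
}
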