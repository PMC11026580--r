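#' Predicted 1:1 binding response over a concentration schedule
#'
#' Exact piecewise-exponential solution of dR/dt = ka C(t) (Rmax - R) -
#' kd R for a trace's concentration schedule, evaluated at the trace's
#' time points.
#'
#' @param time ascending times (s).
#' @param conc molar concentration at each time point (piecewise
#'   constant).
#' @param ka,kd,Rmax model parameters.
#' @return numeric response vector (RU).
#' @keywords internal
predict_1to1 <- function(time, conc, ka, kd, Rmax) {
  R <- numeric(length(time))
  R0 <- 0; t0 <- time[1]; C0 <- conc[1]
  R[1] <- 0
  for (i in seq_along(time)[-1]) {
    if (conc[i] != C0) { C0 <- conc[i]; t0 <- time[i - 1]; R0 <- R[i - 1] }
    kobs <- ka * C0 + kd
    Req <- if (kobs > 0) Rmax * ka * C0 / kobs else 0
    R[i] <- Req + (R0 - Req) * exp(-kobs * (time[i] - t0))
  }
  R
}

#' Fit a 1:1 kinetic model to a single-cycle SPR trace
#'
#' Nonlinear least squares of the integrated 1:1 Langmuir model over the
#' whole sensorgram (association steps and dissociation), on log-scaled
#' rate parameters, multistarted from a coarse grid of rate-constant
#' guesses to avoid local minima. The equilibrium dissociation constant
#' is K_D = kd / ka.
#'
#' @param trace a `binding_trace` (see [simulate_spr_trace()]).
#' @param start optional list with `ka`, `kd`, `Rmax` initial guesses;
#'   when omitted a coarse grid multistart is used.
#' @return list of class `spr_fit`: `ka` (1/M/s), `kd` (1/s), `Rmax`
#'   (RU), `KD` (M), `rmse` (RU), `fitted`, and `identifiable` (FALSE
#'   with a warning when the sampled concentrations cannot separate ka
#'   from kd).
#' @export
fit_spr_1to1 <- function(trace, start = NULL) {
  time <- trace$time; R <- trace$R; conc <- trace$conc
  if (length(unique(conc[conc > 0])) < 1L) stop("trace has no injections")
  if (stats::sd(R) < 1e-12) stop("non-identifiable trace: no signal")
  resid_fun <- function(par) {
    R - predict_1to1(time, conc, exp(par[1]), exp(par[2]), exp(par[3]))
  }
  fit_from <- function(p0) {
    tryCatch(minpack.lm::nls.lm(par = p0, fn = resid_fun,
                                control = minpack.lm::nls.lm.control(maxiter = 200)),
             error = function(e) NULL)
  }
  starts <- if (!is.null(start)) {
    list(log(c(start$ka, start$kd, start$Rmax)))
  } else {
    Rmax0 <- max(R) * 1.5
    grid <- expand.grid(ka = c(1e4, 1e5, 1e6), kd = c(1e-3, 1e-2, 1e-1))
    lapply(seq_len(nrow(grid)), function(i)
      log(c(grid$ka[i], grid$kd[i], Rmax0)))
  }
  fits <- Filter(Negate(is.null), lapply(starts, fit_from))
  if (!length(fits)) stop("SPR fit failed from every start")
  dev <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  bestfit <- fits[[which.min(dev)]]
  par <- exp(bestfit$par)
  ka <- par[1]; kd <- par[2]; Rmax <- par[3]
  fitted <- predict_1to1(time, conc, ka, kd, Rmax)
  rmse <- sqrt(mean((R - fitted)^2))
  # identifiability: if every injected concentration saturates the
  # surface, only Rmax and the on-rate product are constrained
  cmax <- max(conc); cmin <- min(conc[conc > 0])
  KD <- kd / ka
  identifiable <- TRUE
  if (cmin > 20 * KD) {
    identifiable <- FALSE
    warning("all concentrations far above K_D: ka and kd are correlated; ",
            "K_D is poorly determined")
  }
  structure(list(ka = ka, kd = kd, Rmax = Rmax, KD = KD, rmse = rmse,
                 fitted = fitted, identifiable = identifiable),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: ka = %.3g /M/s, kd = %.3g /s, Rmax = %.1f RU\n",
              x$ka, x$kd, x$Rmax))
  cat(sprintf("  K_D = %.1f nM, rmse = %.2f RU%s\n", x$KD * 1e9, x$rmse,
              if (x$identifiable) "" else "  [ka/kd poorly identified]"))
  invisible(x)
}

#' Melting temperature from a thermal unfolding curve
#'
#' Tm is the temperature at the extremum of the Savitzky-Golay-smoothed
#' first derivative of the signal; the sign of the transition (rising or
#' falling signal) is handled automatically, and the result is refined by
#' quadratic interpolation around the grid extremum. Invariant under
#' affine transformations of the signal.
#'
#' @param curve a `melt_curve` (see [simulate_melt_curve()]), or any list
#'   with `temperature` and `signal`.
#' @param window Savitzky-Golay window (points, odd).
#' @return Tm in degrees C.
#' @export
compute_tm <- function(curve, window = 11L) {
  Tg <- curve$temperature; S <- curve$signal
  if (length(Tg) < 20L) stop("melting curve needs at least 20 points")
  if (is.unsorted(Tg, strictly = TRUE)) stop("temperatures must ascend")
  if (window %% 2L == 0L) window <- window + 1L
  rng <- diff(range(S))
  if (rng < 1e-12) stop("flat curve: Tm undefined")
  Sn <- (S - min(S)) / rng               # affine invariance
  h <- mean(diff(Tg))
  dS <- signal::sgolayfilt(Sn, p = 3, n = window, m = 1) / h
  edge <- (window - 1L) %/% 2L
  core <- (edge + 1L):(length(Tg) - edge)
  i0 <- core[which.max(abs(dS[core]))]
  # a transition shows as a clear derivative peak; a monotone or linear
  # signal has a near-constant derivative and no defined Tm
  if (max(abs(dS[core])) < 2 * stats::median(abs(dS[core])))
    stop("no clear unfolding transition: Tm undefined")
  if (i0 <= core[1] || i0 >= core[length(core)])
    stop("derivative extremum at the grid edge: Tm undefined")
  s <- sign(dS[i0])
  y <- s * dS[(i0 - 1L):(i0 + 1L)]
  denom <- y[1] - 2 * y[2] + y[3]
  delta <- if (abs(denom) > 1e-12) 0.5 * (y[1] - y[3]) / denom else 0
  Tg[i0] + max(-1, min(1, delta)) * h
}
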