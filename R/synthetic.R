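#' Ground truth of a synthetic two-state scattering experiment
#'
#' Describes the mixture an experiment is simulated from: which conformers
#' contribute, with which weights, and the q-dependent noise level.
#'
#' @param conformers character ids of the contributing conformers (by
#'   convention `closed` first, `open` second).
#' @param weights non-negative weights summing to 1; the default equal
#'   split reflects the similar closed/open populations seen for the
#'   fully glycosylated antibody.
#' @param noise relative sigma at low q (e.g. 0.02 for 2%).
#' @param noise_slope coefficient c (Angstrom) of the q-dependent error
#'   growth sigma(q) = noise * I(q) * (1 + c q).
#' @param q_min,q_max,n_q q-grid specification (1/Angstrom).
#' @return a list of class `mixture_truth`.
#' @export
mixture_truth <- function(conformers = c("closed", "open"),
                          weights = c(0.5, 0.5),
                          noise = 0.02, noise_slope = 5,
                          q_min = 0.01, q_max = 0.45, n_q = 200L) {
  weights <- as.numeric(weights)
  if (length(weights) != length(conformers))
    stop("weights and conformers lengths differ")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (noise < 0) stop("noise must be >= 0")
  if (q_min <= 0 || q_max <= q_min) stop("invalid q range")
  structure(list(conformers = conformers, weights = weights, noise = noise,
                 noise_slope = noise_slope, q_min = q_min, q_max = q_max,
                 n_q = as.integer(n_q)),
            class = "mixture_truth")
}

#' Simulate a noisy scattering profile of a conformer mixture
#'
#' Forms the weighted sum of the conformer profiles and adds Gaussian
#' noise with sigma(q) = noise * I(q) * (1 + c q), a relative error that
#' grows towards high q as detector counting statistics degrade. The
#' sigma column of the returned profile records the true noise level.
#'
#' @param truth a [mixture_truth()].
#' @param profiles list of [scattering_profile()]s, one per conformer in
#'   `truth$conformers`, all on the same q grid.
#' @param seed integer seed.
#' @return a [scattering_profile()] with sigma.
#' @export
simulate_experiment <- function(truth, profiles, seed = 1L) {
  stopifnot(inherits(truth, "mixture_truth"))
  if (length(profiles) != length(truth$conformers))
    stop("need one profile per conformer in the truth")
  q <- profiles[[1]]$q
  for (p in profiles[-1]) check_same_grid(profiles[[1]], p)
  I_mix <- Reduce(`+`, Map(function(w, p) w * p$I, truth$weights, profiles))
  sig <- truth$noise * abs(I_mix) * (1 + truth$noise_slope * q)
  if (truth$noise == 0)
    return(scattering_profile(q, I_mix,
                              sigma = pmax(1e-12 * max(abs(I_mix)), 1e-300) + 0 * q))
  I_obs <- withr::with_seed(as.integer(seed), I_mix + stats::rnorm(length(q), 0, sig))
  scattering_profile(q, I_obs, sigma = sig)
}

#' Simulate a SEC-SAXS frame stack
#'
#' Emulates continuous X-ray exposures across a size-exclusion elution:
#' leading buffer frames contain background scattering plus noise; peak
#' frames add the conformer-mixture signal scaled by a Gaussian elution
#' concentration profile.
#'
#' @param truth a [mixture_truth()].
#' @param profiles conformer profiles as in [simulate_experiment()].
#' @param n_buffer number of pure-buffer frames before the peak (>= 2).
#' @param n_peak number of frames across the elution peak.
#' @param peak_frac apex concentration as a multiple of the mixture
#'   profile (scales signal-to-background).
#' @param elution_width Gaussian elution width in frames.
#' @param background constant background intensity (arbitrary units,
#'   relative to the mixture I(0) = 1 normalization is not applied; the
#'   background is added as-is).
#' @param seed integer seed.
#' @return a list of class `frame_stack` with elements `q`, `I` (matrix,
#'   one column per frame), `sigma` (same shape), `is_buffer` (logical)
#'   and `truth_concentration` (the per-frame scale factors).
#' @export
simulate_secsaxs_frames <- function(truth, profiles, n_buffer = 10L,
                                    n_peak = 30L, peak_frac = 1,
                                    elution_width = 6, background = NULL,
                                    seed = 1L) {
  stopifnot(inherits(truth, "mixture_truth"))
  if (n_buffer < 2L) stop("need at least 2 buffer frames")
  q <- profiles[[1]]$q
  I_mix <- Reduce(`+`, Map(function(w, p) w * p$I, truth$weights, profiles))
  if (is.null(background)) background <- 0.05 * max(I_mix)
  bkg <- rep(background, length(q))
  n_frames <- n_buffer + n_peak
  apex <- n_buffer + ceiling(n_peak / 2)
  conc <- c(rep(0, n_buffer),
            peak_frac * exp(-((seq_len(n_peak) + n_buffer - apex)^2) /
                              (2 * elution_width^2)))
  withr::with_seed(as.integer(seed), {
    I <- matrix(0, length(q), n_frames)
    S <- matrix(0, length(q), n_frames)
    for (j in seq_len(n_frames)) {
      mean_j <- bkg + conc[j] * I_mix
      sig_j <- pmax(truth$noise * abs(mean_j) * (1 + truth$noise_slope * q),
                    1e-12 * max(abs(mean_j), 1))
      I[, j] <- mean_j + stats::rnorm(length(q), 0, sig_j)
      S[, j] <- sig_j
    }
    structure(list(q = q, I = I, sigma = S,
                   is_buffer = seq_len(n_frames) <= n_buffer,
                   truth_concentration = conc),
              class = "frame_stack")
  })
}

#' Simulate a single-cycle SPR sensorgram (1:1 kinetics)
#'
#' Integrates the 1:1 Langmuir binding model dR/dt = ka C(t) (Rmax - R) -
#' kd R piecewise over the injection schedule using the exact exponential
#' solution on each constant-concentration interval, then adds Gaussian
#' noise. In single-cycle mode the analyte concentration steps up without
#' regeneration, finishing with a dissociation phase.
#'
#' @param ka association rate constant (1/M/s), > 0.
#' @param kd dissociation rate constant (1/s), > 0.
#' @param Rmax saturation response (RU), > 0.
#' @param concentrations molar analyte concentrations of the successive
#'   injections, in increasing order (default: 2-fold ladder topping at
#'   400 nM, five steps from 25 nM; the emulated instrument series spans
#'   12.5-400 nM).
#' @param t_assoc,t_dissoc association time per injection and final
#'   dissociation time (s).
#' @param dt sampling interval (s).
#' @param noise standard deviation of additive Gaussian noise (RU).
#' @param seed integer seed.
#' @return a list of class `binding_trace` with `time` (s), `R` (RU),
#'   `conc` (molar concentration at each time point) and the true
#'   parameters in `truth`.
#' @export
simulate_spr_trace <- function(ka = 2e5, kd = 6e-2, Rmax = 100,
                               concentrations = 400e-9 / 2^(4:0),
                               t_assoc = 60, t_dissoc = 60, dt = 0.5,
                               noise = 1, seed = 1L) {
  if (ka <= 0 || kd <= 0 || Rmax <= 0)
    stop("ka, kd and Rmax must be > 0")
  if (is.unsorted(concentrations)) stop("concentration schedule must be ordered")
  phases <- data.frame(conc = c(concentrations, 0),
                       dur = c(rep(t_assoc, length(concentrations)), t_dissoc))
  tt <- list(); cc <- list(); rr <- list()
  t0 <- 0; R0 <- 0
  for (i in seq_len(nrow(phases))) {
    tloc <- seq(dt, phases$dur[i], by = dt)
    C <- phases$conc[i]
    kobs <- ka * C + kd
    Req <- if (kobs > 0) Rmax * ka * C / kobs else 0
    R <- Req + (R0 - Req) * exp(-kobs * tloc)
    tt[[i]] <- t0 + tloc
    cc[[i]] <- rep(C, length(tloc))
    rr[[i]] <- R
    t0 <- t0 + phases$dur[i]
    R0 <- R[length(R)]
  }
  time <- c(0, unlist(tt)); conc <- c(phases$conc[1], unlist(cc))
  R <- c(0, unlist(rr))
  if (noise > 0)
    R <- withr::with_seed(as.integer(seed),
                          R + stats::rnorm(length(R), 0, noise))
  structure(list(time = time, R = R, conc = conc,
                 truth = list(ka = ka, kd = kd, Rmax = Rmax, KD = kd / ka)),
            class = "binding_trace")
}

#' Simulate a thermal melting curve
#'
#' Two-state unfolding sigmoid with linear pre- and post-transition
#' baselines plus Gaussian noise, emulating a DSF / nanoDSF / CD melt.
#'
#' @param tm melting temperature (deg C), must lie inside the grid.
#' @param width transition width (deg C, the 10-90% transition spans
#'   about 4.4 * width).
#' @param T_grid temperatures (deg C, ascending; default 15-90 in 0.5
#'   steps).
#' @param baselines list with `pre` and `post`, each c(intercept, slope)
#'   of the folded / unfolded baselines.
#' @param amplitude signal change across the transition.
#' @param noise Gaussian noise sd (signal units).
#' @param seed integer seed.
#' @return a list of class `melt_curve` with `temperature`, `signal` and
#'   `truth`.
#' @export
simulate_melt_curve <- function(tm = 67, width = 2.2,
                                T_grid = seq(15, 90, by = 0.5),
                                baselines = list(pre = c(1, -0.002),
                                                 post = c(0.2, -0.001)),
                                amplitude = -0.6, noise = 0.002, seed = 1L) {
  if (tm <= min(T_grid) || tm >= max(T_grid))
    stop("tm must lie inside the temperature grid")
  if (is.unsorted(T_grid, strictly = TRUE))
    stop("temperature grid must be strictly ascending")
  frac <- 1 / (1 + exp(-(T_grid - tm) / width))
  pre <- baselines$pre[1] + baselines$pre[2] * T_grid
  post <- baselines$post[1] + baselines$post[2] * T_grid
  signal <- (1 - frac) * pre + frac * (post + amplitude)
  if (noise > 0)
    signal <- withr::with_seed(as.integer(seed),
                               signal + stats::rnorm(length(signal), 0, noise))
  structure(list(temperature = T_grid, signal = signal,
                 truth = list(tm = tm, width = width)),
            class = "melt_curve")
}

#' Lattice-filled sphere bead model
#'
#' A solid sphere of unit-weight beads on a cubic lattice, rescaled so the
#' bead Rg equals the continuum value sqrt(3/5) R. Used as the analytic
#' calibration body for the Debye, Guinier, P(r) and Dmax machinery.
#'
#' @param radius sphere radius R (Angstrom).
#' @param n_target approximate bead count.
#' @return a [structure_model()].
#' @export
sphere_model <- function(radius = 50, n_target = 2000L) {
  sp <- (4 / 3 * pi * radius^3 / n_target)^(1 / 3)
  g <- seq(-radius, radius, by = sp)
  gr <- as.matrix(expand.grid(x = g, y = g, z = g))
  gr <- gr[rowSums(gr^2) <= radius^2, , drop = FALSE]
  gr <- gr * sqrt(3 / 5) * radius / sqrt(mean(rowSums(gr^2)))
  n <- nrow(gr)
  beads <- data.frame(x = gr[, 1], y = gr[, 2], z = gr[, 3], f = 1,
                      kind = "protein", chain = "A", resno = seq_len(n),
                      region = "sphere", stringsAsFactors = FALSE)
  structure_model(beads, bodies = list(sphere = seq_len(n)),
                  info = list(radius = radius))
}

#' Write mixture ground truth as a key=value sidecar
#'
#' @param truth a [mixture_truth()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_truth <- function(truth, file) {
  lines <- c(paste0("conformers=", paste(truth$conformers, collapse = ",")),
             paste0("weights=", paste(format(truth$weights), collapse = ",")),
             paste0("noise=", format(truth$noise)),
             paste0("noise_slope=", format(truth$noise_slope)),
             paste0("q_min=", format(truth$q_min)),
             paste0("q_max=", format(truth$q_max)),
             paste0("n_q=", truth$n_q))
  writeLines(lines, file)
  invisible(file)
}
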