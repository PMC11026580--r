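#' Detect peaks and shoulders of a smooth curve
#'
#' Savitzky-Golay smoothing followed by derivative analysis on a uniform
#' grid. Peaks are interior local maxima of the smoothed curve exceeding a
#' fraction of the global maximum; shoulders are flattenings of the slope
#' (interior local maxima of the first derivative where the curve is
#' descending, or local minima where it is ascending), the visual
#' "shoulder" of scattering curves and P(r) functions.
#'
#' @param x ascending abscissa (resampled to uniform if needed).
#' @param y ordinate.
#' @param window odd Savitzky-Golay window length (points).
#' @param min_peak_frac peaks below this fraction of the global maximum
#'   are ignored.
#' @param min_prominence shoulders whose slope rebound is below this
#'   fraction of the slope scale are ignored.
#' @return data.frame with columns `x`, `y`, `type`
#'   (`"peak"`/`"shoulder"`) and `prominence` (peak height relative to the
#'   global maximum; for shoulders, the slope rebound relative to the
#'   slope scale), ordered by `x`.
#' @export
find_curve_features <- function(x, y, window = 11L, min_peak_frac = 0.1,
                                min_prominence = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= window)
  if (window %% 2L == 0L) window <- window + 1L
  dx <- diff(x)
  if (max(dx) - min(dx) > 1e-8 * mean(dx)) {   # resample to uniform grid
    xr <- seq(min(x), max(x), length.out = length(x))
    y <- stats::approx(x, y, xout = xr)$y
    x <- xr
    dx <- diff(x)
  }
  h <- mean(dx)
  ys <- signal::sgolayfilt(y, p = 3, n = window)
  dy <- signal::sgolayfilt(y, p = 3, n = window, m = 1) / h
  interior <- 2:(length(x) - 1L)
  is_lmax <- function(v) {
    out <- logical(length(v))
    out[interior] <- v[interior] >= v[interior - 1L] & v[interior] > v[interior + 1L]
    out
  }
  pk <- which(is_lmax(ys) & ys > min_peak_frac * max(ys))
  # drop the smoothing edge region
  edge <- (window - 1L) %/% 2L
  pk <- pk[pk > edge & pk <= length(x) - edge]
  sh <- which((is_lmax(dy) & dy < 0) | (is_lmax(-dy) & dy > 0))
  sh <- sh[sh > edge & sh <= length(x) - edge]
  # keep only prominent flattenings: the slope must rebound towards zero
  # by a noticeable fraction of the slope scale around the candidate
  sh_prom <- numeric(0)
  if (length(sh)) {
    dscale <- max(abs(dy))
    prom <- vapply(sh, function(i) {
      lo <- max(1L, i - 2L * window); hi <- min(length(dy), i + 2L * window)
      if (dy[i] < 0)   # descending flattening: rebound above surrounding minima
        min(dy[i] - min(dy[lo:i]), dy[i] - min(dy[i:hi]))
      else             # ascending flattening: dip below surrounding maxima
        min(max(dy[lo:i]) - dy[i], max(dy[i:hi]) - dy[i])
    }, numeric(1)) / dscale
    keep <- prom >= min_prominence
    sh <- sh[keep]; sh_prom <- prom[keep]
  }
  # a shoulder adjacent to a detected peak is the peak itself; drop it
  if (length(pk) && length(sh)) {
    keep <- vapply(sh, function(i) min(abs(i - pk)) > window, logical(1))
    sh <- sh[keep]; sh_prom <- sh_prom[keep]
  }
  # sub-grid peak refinement by quadratic interpolation
  pk_x <- vapply(pk, function(i) {
    if (i <= 1L || i >= length(x)) return(x[i])
    denom <- ys[i - 1L] - 2 * ys[i] + ys[i + 1L]
    delta <- if (abs(denom) > 1e-12) 0.5 * (ys[i - 1L] - ys[i + 1L]) / denom else 0
    x[i] + max(-1, min(1, delta)) * h
  }, numeric(1))
  out <- rbind(
    if (length(pk)) data.frame(x = pk_x, y = ys[pk], type = "peak",
                               prominence = ys[pk] / max(ys)),
    if (length(sh)) data.frame(x = x[sh], y = ys[sh], type = "shoulder",
                               prominence = sh_prom))
  if (is.null(out))
    return(data.frame(x = numeric(0), y = numeric(0), type = character(0),
                      prominence = numeric(0)))
  out[order(out$x), , drop = FALSE]
}

#' Guinier fit with a self-consistent q Rg window
#'
#' Fits ln I = ln I(0) - q^2 Rg^2 / 3 by weighted least squares over a
#' low-q window chosen self-consistently: starting from the lowest usable
#' q (leading non-positive intensities are skipped), the window is shrunk
#' or extended until q_max Rg <= `qRg_limit` and the Rg estimate changes
#' by less than 0.1% between iterations; ties are broken toward the widest
#' valid window.
#'
#' @param profile a [scattering_profile()]; sigma, if present, weights the
#'   fit.
#' @param qRg_limit upper limit for q Rg in the fit window (default 1.5).
#' @param min_points minimum number of points in the window.
#' @return list of class `guinier_result`: `Rg` (Angstrom), `I0`, `window`
#'   (q_min, q_max), `n_points`, `r2` (coefficient of determination of the
#'   linearized fit), `qRg_max`.
#' @export
guinier_fit <- function(profile, qRg_limit = 1.5, min_points = 5L) {
  q <- profile$q; I <- profile$I
  start <- match(TRUE, I > 0)
  if (is.na(start)) stop("no positive intensities at low q")
  usable <- start - 1L + match(TRUE, cumsum(I[start:length(I)] <= 0) > 0,
                               nomatch = length(I) - start + 2L) - 1L
  q <- q[start:(start + usable - 1L)]
  I <- I[start:(start + usable - 1L)]
  w <- if (!is.null(profile$sigma)) {
    s <- profile$sigma[start:(start + usable - 1L)]
    (I / s)^2                         # delta(ln I) = sigma / I
  } else rep(1, length(I))
  if (length(q) < min_points) stop("fewer than min_points positive low-q points")

  fit_window <- function(n) {
    x <- q[1:n]^2; yy <- log(I[1:n]); ww <- w[1:n]
    fit <- stats::lm.wfit(cbind(1, x), yy, ww)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) return(NULL)
    rg <- sqrt(-3 * slope)
    yhat <- cbind(1, x) %*% fit$coefficients
    ssr <- sum(ww * (yy - yhat)^2)
    sst <- sum(ww * (yy - stats::weighted.mean(yy, ww))^2)
    list(Rg = rg, I0 = exp(fit$coefficients[1]),
         r2 = if (sst > 0) 1 - ssr / sst else 1, n = n)
  }
  n <- min(length(q), max(3L * min_points, 10L))
  last_rg <- Inf
  res <- NULL
  for (iter in 1:100) {
    res <- fit_window(n)
    if (is.null(res)) {
      n <- n + 2L
      if (n > length(q)) stop("no convergent Guinier window")
      next
    }
    n_new <- max(min_points, findInterval(qRg_limit / res$Rg, q))
    n_new <- min(n_new, length(q))
    if (n_new == n && abs(res$Rg - last_rg) / res$Rg < 1e-3) break
    last_rg <- res$Rg
    n <- n_new
  }
  if (is.null(res)) stop("no convergent Guinier window")
  # tie-break: extend while still within the q Rg limit
  while (res$n < length(q) && q[res$n + 1L] * res$Rg <= qRg_limit) {
    cand <- fit_window(res$n + 1L)
    if (is.null(cand) || cand$Rg * q[cand$n] > qRg_limit) break
    res <- cand
  }
  structure(list(Rg = unname(res$Rg), I0 = unname(res$I0),
                 window = c(q[1], q[res$n]), n_points = res$n,
                 r2 = unname(res$r2), qRg_max = unname(q[res$n] * res$Rg)),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.2f A, I(0) = %.4g, window q [%.4f, %.4f] (%d pts, qRg_max = %.2f, R2 = %.4f)\n",
              x$Rg, x$I0, x$window[1], x$window[2], x$n_points, x$qRg_max, x$r2))
  invisible(x)
}

# pair-distribution container
pair_distribution <- function(r, p, dmax, i0, chi2 = NA_real_,
                              alpha = NA_real_, source = "ift") {
  keep <- p > 0
  rg <- sqrt(sum(r^2 * p) / (2 * sum(p)))
  feats <- if (length(r) >= 17L)
    find_curve_features(r, p / max(p), window = 17L)
  else data.frame(x = numeric(0), y = numeric(0), type = character(0))
  structure(list(r = r, p = p, p_norm = p / max(p), dmax = dmax, Rg = rg,
                 I0 = i0, chi2 = chi2, alpha = alpha, features = feats,
                 source = source),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("P(r) [%s]: Dmax = %.0f A, Rg = %.2f A, I(0) = %.4g", x$source,
              x$dmax, x$Rg, x$I0))
  if (is.finite(x$chi2)) cat(sprintf(", fit chi2 = %.2f", x$chi2))
  cat("\n")
  if (nrow(x$features))
    cat(paste(sprintf("  %s at r = %.1f A", x$features$type, x$features$x),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Pair distribution by regularized indirect Fourier transform
#'
#' Solves for p(r) on an n-point grid over \[0, Dmax\] such that
#' I(q) = 4 pi sum p(r) sinc(q r) dr reproduces the data, by non-negative
#' least squares with a second-difference smoothness penalty alpha and
#' endpoint ties p(0) = p(Dmax) = 0 (the GNOM-style regularized
#' inversion). Unless given, the regularization weight is scanned over a
#' log-spaced grid and the smoothest solution whose data misfit remains
#' statistically indistinguishable from the best one is kept (a
#' discrepancy rule along the L-curve).
#'
#' @param profile a [scattering_profile()] with sigma.
#' @param dmax assumed maximal dimension (Angstrom), > 0.
#' @param alpha regularization weight, or `NULL` for L-curve selection.
#' @param n_r number of r-grid points (default 201).
#' @param chi2_warn warn about a systematic misfit (Dmax too small) above
#'   this reduced chi2.
#' @return a `pair_distribution` with derived Rg, I(0) and the data-fit
#'   chi2.
#' @export
ift_pr <- function(profile, dmax, alpha = NULL, n_r = 201L, chi2_warn = 5) {
  if (dmax <= 0) stop("dmax must be > 0")
  if (is.null(profile$sigma)) stop("IFT needs a profile with sigma")
  q <- profile$q
  r <- seq(0, dmax, length.out = n_r)
  dr <- r[2] - r[1]
  rint <- r[2:(n_r - 1L)]                    # interior unknowns
  A <- 4 * pi * dr * sinc_qr(outer(q, rint)) # n_q x (n_r - 2)
  Aw <- A / profile$sigma
  bw <- profile$I / profile$sigma
  m <- length(rint)
  # second differences over the full grid with zero endpoints
  D2 <- matrix(0, m, m)
  for (j in seq_len(m)) {
    D2[j, j] <- -2
    if (j > 1L) D2[j, j - 1L] <- 1
    if (j < m) D2[j, j + 1L] <- 1
  }
  zero <- rep(0, m)
  solve_alpha <- function(a) {
    fit <- pracma::lsqnonneg(rbind(Aw, sqrt(a) * D2), c(bw, zero))
    p <- fit$x
    list(p = p, resid = sum((Aw %*% p - bw)^2), rough = sum((D2 %*% p)^2))
  }
  if (is.null(alpha)) {
    # wide log grid below the heavy-smoothing scale; keep the smoothest
    # solution whose data misfit is still statistically indistinguishable
    # from the best one (discrepancy rule on the L-curve)
    scale0 <- sum(Aw^2) / sum(D2^2)
    alphas <- scale0 * 10^seq(-12, 0, by = 1.5)
    sols <- lapply(alphas, solve_alpha)
    chi <- vapply(sols, `[[`, numeric(1), "resid") / length(q)
    ok <- chi <= max(1.05 * min(chi), min(chi) + 0.1)
    k <- max(which(ok))
    alpha <- alphas[k]
    sol <- sols[[k]]
  } else {
    sol <- solve_alpha(alpha)
  }
  p <- sol$p
  chi2_fit <- sol$resid / length(q)
  if (chi2_fit > chi2_warn)
    warning(sprintf("IFT misfit (chi2 = %.1f): Dmax = %.0f A is likely too small",
                    chi2_fit, dmax))
  i0 <- 4 * pi * sum(p) * dr
  pair_distribution(rint, p, dmax, i0, chi2 = chi2_fit, alpha = alpha,
                    source = "ift")
}

#' Exact pair distribution of a bead model
#'
#' Weighted pair-distance histogram of the model coordinates, normalized
#' at the maximum. Derived Rg and I(0) use the unnormalized histogram.
#'
#' @param model a [structure_model()].
#' @param bin_width histogram bin width (Angstrom, default 1).
#' @return a `pair_distribution` (p normalized at the maximum; `I0` holds
#'   the Debye forward scattering (sum f)^2).
#' @export
pr_from_model <- function(model, bin_width = 1) {
  f <- model$beads$f
  d <- as.vector(stats::dist(model_xyz(model)))
  fw <- outer(f, f)
  w2 <- 2 * fw[lower.tri(fw)]
  nb <- max(1L, ceiling(max(d) / bin_width))
  idx <- pmin(nb, floor(d / bin_width) + 1L)
  p <- numeric(nb)
  p[sort(unique(idx))] <- as.vector(rowsum(w2, idx, reorder = TRUE))
  r <- (seq_len(nb) - 0.5) * bin_width
  pd <- pair_distribution(r, p / bin_width, dmax = max(d),
                          i0 = sum(f)^2, source = "model")
  attr(pd, "raw_max") <- max(p) / bin_width
  pd$p <- pd$p_norm                     # normalized at the maximum
  pd
}

#' Scan for the maximal dimension Dmax
#'
#' Runs the regularized IFT over a bracket of candidate Dmax values and
#' returns the smallest for which the solution decays properly: the tail
#' of p(r) near Dmax stays below 1% of the peak and the data misfit is
#' within 30% of the best misfit across the scan. Ties break toward
#' smaller Dmax.
#'
#' @param profile a [scattering_profile()] with sigma.
#' @param dmax_range length-2 bracket (Angstrom).
#' @param step scan step (Angstrom).
#' @param n_r IFT grid size during the scan.
#' @return list of class `dmax_scan`: `dmax`, the scan `table`, and the
#'   `pr` solution at the chosen Dmax. A degenerate profile (no decay
#'   within the bracket) selects the bracket minimum and sets
#'   `degenerate = TRUE`.
#' @export
dmax_scan <- function(profile, dmax_range = c(80, 250), step = 10,
                      n_r = 101L) {
  stopifnot(length(dmax_range) == 2L, dmax_range[1] < dmax_range[2])
  cands <- seq(dmax_range[1], dmax_range[2], by = step)
  rows <- lapply(cands, function(dm) {
    pr <- suppressWarnings(ift_pr(profile, dm, n_r = n_r))
    tail_idx <- pr$r >= 0.98 * dm
    data.frame(dmax = dm, chi2 = pr$chi2,
               tail_frac = max(pr$p_norm[tail_idx]))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$tail_frac <= 0.01 & tab$chi2 <= 1.3 * min(tab$chi2)
  degenerate <- !any(ok)
  dmax <- if (degenerate) cands[1] else cands[which(ok)[1]]
  structure(list(dmax = dmax, table = tab,
                 pr = suppressWarnings(ift_pr(profile, dmax, n_r = n_r)),
                 degenerate = degenerate),
            class = "dmax_scan")
}

#' Dimensionless Kratky curve
#'
#' Returns x = q Rg, y = (q Rg)^2 I(q) / I(0) with the Guinier-derived Rg
#' and I(0). A compact folded particle peaks at q Rg = sqrt(3) ~ 1.73
#' with y ~ 1.1; multidomain separation shows up as shoulders at higher
#' q Rg. Features are detected on the smoothed curve.
#'
#' @param profile a [scattering_profile()].
#' @param guinier a [guinier_fit()] result for the same profile.
#' @return list of class `kratky_curve`: `x`, `y`, `features`.
#' @export
kratky_dimensionless <- function(profile, guinier) {
  x <- profile$q * guinier$Rg
  y <- x^2 * profile$I / guinier$I0
  feats <- find_curve_features(x, y, window = 11L)
  structure(list(x = x, y = y, features = feats), class = "kratky_curve")
}

#' @export
print.kratky_curve <- function(x, ...) {
  cat(sprintf("dimensionless Kratky: qRg in [%.2f, %.2f]\n",
              min(x$x), max(x$x)))
  if (nrow(x$features))
    cat(paste(sprintf("  %s at qRg = %.2f", x$features$type, x$features$x),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Subtract the averaged buffer from a SEC-SAXS frame stack
#'
#' The buffer frames are averaged; the average is subtracted from every
#' frame with uncertainties propagated in quadrature.
#'
#' @param frames a `frame_stack` (see [simulate_secsaxs_frames()]).
#' @param buffer_idx indices of the buffer frames (defaults to the
#'   stack's `is_buffer` flags).
#' @return a `frame_stack` with subtracted intensities; the buffer mean is
#'   kept in `$background`.
#' @export
subtract_buffer <- function(frames, buffer_idx = which(frames$is_buffer)) {
  if (length(buffer_idx) < 1L) stop("need at least one buffer frame")
  B <- rowMeans(frames$I[, buffer_idx, drop = FALSE])
  sigB2 <- rowSums(frames$sigma[, buffer_idx, drop = FALSE]^2) /
    length(buffer_idx)^2
  out <- frames
  out$I <- frames$I - B
  out$sigma <- sqrt(frames$sigma^2 + sigB2)
  out$background <- B
  out$subtracted <- TRUE
  out
}

#' Merge elution-peak frames into one profile
#'
#' Maps the elution peak by the per-frame integral ratio to background,
#' keeps frames whose Guinier Rg deviates less than `rg_tol` from the
#' apex-frame Rg and whose integral ratio exceeds `ratio_min` times the
#' apex ratio, and averages them with quadrature error propagation.
#'
#' @param frames a buffer-subtracted `frame_stack`.
#' @param rg_tol relative Rg tolerance around the apex frame (default 5%).
#' @param ratio_min minimal signal-to-background integral ratio, as a
#'   fraction of the apex frame's ratio.
#' @return a [scattering_profile()]; the selected frame indices are kept
#'   in `attr(, "frames")`.
#' @export
merge_frames <- function(frames, rg_tol = 0.05, ratio_min = 0.2) {
  if (!isTRUE(frames$subtracted))
    stop("merge_frames expects a buffer-subtracted stack")
  cand <- which(!frames$is_buffer)
  ratio <- colSums(abs(frames$I[, cand, drop = FALSE])) /
    sum(abs(frames$background))
  apex <- cand[which.max(ratio)]
  rg_of <- function(j) {
    pr <- scattering_profile(frames$q, frames$I[, j], frames$sigma[, j])
    tryCatch(guinier_fit(pr)$Rg, error = function(e) NA_real_)
  }
  rg_apex <- rg_of(apex)
  if (is.na(rg_apex)) stop("Guinier fit failed on the apex frame")
  keep <- cand[ratio >= ratio_min * max(ratio)]
  rgs <- vapply(keep, rg_of, numeric(1))
  keep <- keep[!is.na(rgs) & abs(rgs - rg_apex) / rg_apex < rg_tol]
  if (!length(keep)) keep <- apex
  I <- rowMeans(frames$I[, keep, drop = FALSE])
  sig <- sqrt(rowSums(frames$sigma[, keep, drop = FALSE]^2)) / length(keep)
  out <- scattering_profile(frames$q, I, sig)
  attr(out, "frames") <- keep
  out
}

#' Report the inter-domain shoulder of a pair distribution
#'
#' The inter-domain (Fab-Fc separation) shoulder is the longest-range
#' flattening of p(r) within the first half of the distance support:
#' distances beyond Dmax/2 cross the whole molecule rather than
#' separating two domains, so flattenings out there belong to the far
#' tail. Detection runs at a low (2%) prominence floor because the
#' distal edge of the inter-domain shelf is a subtle but reproducible
#' feature.
#'
#' @param pd a `pair_distribution`.
#' @return shoulder position in Angstrom (`NA` if no shoulder detected).
#' @export
pr_interdomain_shoulder <- function(pd) {
  ft <- find_curve_features(pd$r, pd$p_norm, window = 17L,
                            min_prominence = 0.02)
  sh <- ft[ft$type == "shoulder" & ft$x <= pd$dmax / 2, ]
  if (!nrow(sh)) return(NA_real_)
  max(sh$x)
}

#' Report the secondary feature of a dimensionless Kratky curve
#'
#' The primary feature of the curve is its low-q bell (the compactness
#' maximum, or its flattening for very extended particles); the secondary
#' feature, the next peak or shoulder at higher q Rg, marks the distinct
#' Fab/Fc domain separation.
#'
#' @param kratky a `kratky_curve`.
#' @return q Rg position of the secondary feature (`NA` if fewer than two
#'   features are detected).
#' @export
kratky_secondary_feature <- function(kratky) {
  ft <- kratky$features[order(kratky$features$x), ]
  if (nrow(ft) < 2L) return(NA_real_)
  ft$x[2L]
}

#' Pair distribution of a two-state conformer mixture
#'
#' Weighted average of the exact pair-distance histograms of two
#' conformers of the same molecule, normalized at the maximum. This is
#' the model counterpart of the experimental P(r) of a two-state system:
#' inter-domain features that are washed out within a single compact
#' conformer (the Fab-Fc separation shoulder) appear here through the
#' open population.
#'
#' @param model_a,model_b the two conformer [structure_model()]s.
#' @param weights length-2 non-negative weights (summing to 1).
#' @param bin_width histogram bin width (Angstrom).
#' @return a `pair_distribution` (p normalized at the maximum).
#' @export
pr_two_state <- function(model_a, model_b, weights = c(0.5, 0.5),
                         bin_width = 1) {
  stopifnot(length(weights) == 2L, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8)
  ha <- pr_from_model(model_a, bin_width)
  hb <- pr_from_model(model_b, bin_width)
  raw_a <- ha$p_norm * attr(ha, "raw_max")
  raw_b <- hb$p_norm * attr(hb, "raw_max")
  nb <- max(length(raw_a), length(raw_b))
  pad <- function(p) c(p, rep(0, nb - length(p)))
  p <- weights[1] * pad(raw_a) + weights[2] * pad(raw_b)
  r <- (seq_len(nb) - 0.5) * bin_width
  pd <- pair_distribution(r, p, dmax = max(ha$dmax, hb$dmax),
                          i0 = weights[1] * ha$I0 + weights[2] * hb$I0,
                          source = "two-state model")
  pd$p <- pd$p_norm
  pd
}
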