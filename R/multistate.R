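# non-negative least squares for a small number of columns, robust to
# the iteration cap of the active-set solver: falls back to exact
# enumeration of support sets (optimal for the column counts used in
# multistate fitting)
nnls_coef <- function(A, b) {
  k <- ncol(A)
  if (k == 1L) return(max(0, sum(A * b) / sum(A^2)))
  res <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) NULL)
  if (!is.null(res)) return(res)
  if (k > 12L) stop("non-negative least squares failed to converge")
  best <- rep(0, k)
  best_r <- sum(b^2)
  for (S in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(S, 2^(seq_len(k) - 1L)) > 0)
    cf <- tryCatch(qr.coef(qr(A[, idx, drop = FALSE]), b),
                   error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf)) || any(cf < 0)) next
    r <- sum((b - A[, idx, drop = FALSE] %*% cf)^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best <- rep(0, k); best[idx] <- cf
    }
  }
  best
}

#' Fit non-negative weights of a multistate model
#'
#' Given an experimental profile and k conformer profiles on the same q
#' grid, solves the non-negative least-squares problem for the combined
#' coefficients c w_k minimizing the chi-square of the weighted sum, then
#' splits the solution into a scale c (absorbing overall magnitude) and
#' weights w on the unit simplex.
#'
#' @param exp a [scattering_profile()] with sigma.
#' @param profiles matrix (columns = conformers) or list of
#'   [scattering_profile()]s on the same q grid as `exp`.
#' @param ids optional conformer identifiers.
#' @return list of class `multistate_fit`: `ids`, `weights` (sum 1),
#'   `scale`, `chi2`, `k`.
#' @export
fit_weights <- function(exp, profiles, ids = NULL) {
  if (is.null(exp$sigma)) stop("experimental profile needs sigma")
  A <- if (is.matrix(profiles)) profiles
  else {
    for (p in profiles) check_same_grid(exp, p)
    vapply(profiles, function(p) p$I, numeric(nrow(exp)))
  }
  if (nrow(A) != nrow(exp)) stop("profile grid does not match experiment")
  if (is.null(ids)) ids <- as.character(seq_len(ncol(A)))
  Aw <- A / exp$sigma
  bw <- exp$I / exp$sigma
  coef <- nnls_coef(Aw, bw)
  if (all(coef <= 0))
    stop("degenerate fit: all non-negative weights are zero")
  scale <- sum(coef)
  w <- coef / scale
  resid <- bw - Aw %*% coef
  structure(list(ids = ids, weights = as.vector(w), scale = scale,
                 chi2 = mean(resid^2), k = ncol(A)),
            class = "multistate_fit")
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat(sprintf("multistate fit (k = %d): chi2 = %.3f, scale = %.4g\n",
              x$k, x$chi2, x$scale))
  cat(paste(sprintf("  %s: w = %.3f", x$ids, x$weights), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Search for the best k-state models against an experimental profile
#'
#' k = 1 is scored exhaustively. For k >= 2 a best-first beam search is
#' seeded from the top single-state fits: every subset kept in the beam is
#' extended by each remaining conformer, scored by [fit_weights()], and
#' the best `beam_width` subsets advance. Returns the `top_n` fits per k,
#' sorted by chi2 with ties broken by smaller weighted mean Rg and then
#' lexicographic conformer ids, which makes the search deterministic for a
#' fixed ensemble order.
#'
#' @param exp a [scattering_profile()] with sigma.
#' @param ensemble an [sample_ensemble()] result, or a list with
#'   `profiles` (matrix) and `rg`.
#' @param k_max largest number of states to consider.
#' @param top_n fits retained per k.
#' @param beam_width beam width for k >= 2.
#' @return list of class `multistate_search`: per-k data.frames with
#'   columns `chi2`, `scale`, `mean_rg`, `ids` and `weights`
#'   (semicolon-separated), plus `best` (the best fit object per k).
#' @export
multistate_search <- function(exp, ensemble, k_max = 3L, top_n = 300L,
                              beam_width = 100L) {
  A <- ensemble$profiles
  rg <- ensemble$rg
  n <- ncol(A)
  if (n < k_max) stop("ensemble smaller than k_max")
  ids <- colnames(A)
  if (is.null(ids)) ids <- sprintf("c%04d", seq_len(n))
  Aw <- A / exp$sigma
  bw <- exp$I / exp$sigma
  M <- nrow(A)

  score_subset <- function(sub) {
    coef <- nnls_coef(Aw[, sub, drop = FALSE], bw)
    s <- sum(coef)
    w <- if (s > 0) coef / s else rep(1 / length(sub), length(sub))
    resid <- bw - Aw[, sub, drop = FALSE] %*% coef
    list(chi2 = mean(resid^2), scale = s, weights = w,
         mean_rg = sum(w * rg[sub]))
  }
  rank_order <- function(chi2, mean_rg, key) {
    order(round(chi2, 10), round(mean_rg, 6), key)
  }

  results <- list()
  best <- list()
  # k = 1: exhaustive
  sc1 <- lapply(seq_len(n), function(j) score_subset(j))
  chi1 <- vapply(sc1, `[[`, numeric(1), "chi2")
  mrg1 <- vapply(sc1, `[[`, numeric(1), "mean_rg")
  ord1 <- rank_order(chi1, mrg1, ids)
  subsets <- lapply(ord1, identity)
  scores <- sc1[ord1]
  results[["1"]] <- data.frame(
    chi2 = chi1[ord1][seq_len(min(top_n, n))],
    scale = vapply(scores, `[[`, numeric(1), "scale")[seq_len(min(top_n, n))],
    mean_rg = mrg1[ord1][seq_len(min(top_n, n))],
    ids = ids[ord1][seq_len(min(top_n, n))],
    weights = "1",
    stringsAsFactors = FALSE)
  best[["1"]] <- structure(list(ids = ids[ord1[1]], weights = 1,
                                scale = scores[[1]]$scale,
                                chi2 = chi1[ord1[1]], k = 1L),
                           class = "multistate_fit")

  beam <- lapply(ord1[seq_len(min(beam_width, n))], identity)
  if (k_max >= 2L) for (k in 2:k_max) {
    seen <- new.env(hash = TRUE)
    cand_subsets <- list()
    for (sub in beam) {
      for (j in seq_len(n)) {
        if (j %in% sub) next
        ns <- sort(c(sub, j))
        key <- paste(ns, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        cand_subsets[[length(cand_subsets) + 1L]] <- ns
      }
    }
    sc <- lapply(cand_subsets, score_subset)
    chi <- vapply(sc, `[[`, numeric(1), "chi2")
    mrg <- vapply(sc, `[[`, numeric(1), "mean_rg")
    key <- vapply(cand_subsets, function(s) paste(ids[s], collapse = ";"),
                  character(1))
    ord <- rank_order(chi, mrg, key)
    keep <- ord[seq_len(min(top_n, length(ord)))]
    results[[as.character(k)]] <- data.frame(
      chi2 = chi[keep],
      scale = vapply(sc[keep], `[[`, numeric(1), "scale"),
      mean_rg = mrg[keep],
      ids = key[keep],
      weights = vapply(sc[keep], function(s)
        paste(sprintf("%.8f", s$weights), collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    b1 <- ord[1]
    best[[as.character(k)]] <- structure(
      list(ids = ids[cand_subsets[[b1]]], weights = sc[[b1]]$weights,
           scale = sc[[b1]]$scale, chi2 = chi[b1], k = k),
      class = "multistate_fit")
    beam <- cand_subsets[ord[seq_len(min(beam_width, length(ord)))]]
  }
  structure(list(results = results, best = best, ids = ids, rg = rg,
                 k_max = k_max, top_n = top_n, beam_width = beam_width),
            class = "multistate_search")
}

#' @export
print.multistate_search <- function(x, ...) {
  for (k in names(x$best))
    cat(sprintf("k = %s: best chi2 = %.3f (%s)\n", k, x$best[[k]]$chi2,
                paste(x$best[[k]]$ids, collapse = ", ")))
  invisible(x)
}

#' Exhaustive k-state enumeration (reference implementation)
#'
#' Scores every k-subset of the ensemble by [fit_weights()]. Used as the
#' oracle the beam search is checked against on small pools.
#'
#' @inheritParams multistate_search
#' @param k subset size.
#' @return data.frame sorted like [multistate_search()] results.
#' @export
multistate_exhaustive <- function(exp, ensemble, k, top_n = 300L) {
  A <- ensemble$profiles
  rg <- ensemble$rg
  n <- ncol(A)
  ids <- colnames(A)
  if (is.null(ids)) ids <- sprintf("c%04d", seq_len(n))
  Aw <- A / exp$sigma
  bw <- exp$I / exp$sigma
  combs <- utils::combn(n, k, simplify = FALSE)
  sc <- lapply(combs, function(sub) {
    coef <- nnls_coef(Aw[, sub, drop = FALSE], bw)
    s <- sum(coef)
    w <- if (s > 0) coef / s else rep(1 / length(sub), length(sub))
    resid <- bw - Aw[, sub, drop = FALSE] %*% coef
    list(chi2 = mean(resid^2), scale = s, weights = w,
         mean_rg = sum(w * rg[sub]))
  })
  chi <- vapply(sc, `[[`, numeric(1), "chi2")
  mrg <- vapply(sc, `[[`, numeric(1), "mean_rg")
  key <- vapply(combs, function(s) paste(ids[s], collapse = ";"), character(1))
  ord <- order(round(chi, 10), round(mrg, 6), key)
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(chi2 = chi[keep],
             scale = vapply(sc[keep], `[[`, numeric(1), "scale"),
             mean_rg = mrg[keep],
             ids = key[keep],
             weights = vapply(sc[keep], function(s)
               paste(sprintf("%.8f", s$weights), collapse = ";"),
               character(1)),
             stringsAsFactors = FALSE)
}

#' Estimate the number of conformational states from top multistate fits
#'
#' Pools the conformer Rg values of the top fits for one k, each weighted
#' by its fitted weight (and uniformly across fits), forms a weighted
#' histogram and a smoothed density, and counts the peaks exceeding 10%
#' of the density maximum. The peak count estimates the number of states
#' in solution; peak positions and masses localize them.
#'
#' @param search a [multistate_search()] result.
#' @param k which k's top fits to pool (default 2).
#' @param bin_width histogram bin width (Angstrom).
#' @param bw kernel bandwidth for the smoothed density (Angstrom).
#' @param chi2_window only fits whose chi2 is within this fraction of the
#'   best fit's are pooled (the "same goodness-of-fit" plateau);
#'   `Inf` pools all retained fits.
#' @return list of class `state_count_report`: `n_states`, `peaks`
#'   (data.frame with `rg` and `mass`), `histogram`, `density`.
#' @export
state_count <- function(search, k = 2L, bin_width = 1, bw = 1.5,
                        chi2_window = 0.05) {
  tab <- search$results[[as.character(k)]]
  if (is.null(tab) || !nrow(tab)) stop("no fits for this k")
  # pool only the fits sharing the best goodness-of-fit plateau
  if (is.finite(chi2_window))
    tab <- tab[tab$chi2 <= (1 + chi2_window) * tab$chi2[1], , drop = FALSE]
  rg_by_id <- stats::setNames(search$rg, search$ids)
  samples <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    ids_i <- strsplit(tab$ids[i], ";", fixed = TRUE)[[1]]
    w_i <- as.numeric(strsplit(tab$weights[i], ";", fixed = TRUE)[[1]])
    data.frame(rg = rg_by_id[ids_i], w = w_i / nrow(tab))
  }))
  samples <- samples[samples$w > 0, ]
  breaks <- seq(floor(min(samples$rg)) - bin_width,
                ceiling(max(samples$rg)) + bin_width, by = bin_width)
  bin <- cut(samples$rg, breaks)
  hist_tab <- tapply(samples$w, bin, sum, default = 0)
  den <- stats::density(samples$rg, weights = samples$w / sum(samples$w),
                        bw = bw, n = 512)
  iy <- den$y
  lmax <- which(iy > c(-Inf, iy[-length(iy)]) & iy >= c(iy[-1], -Inf))
  lmax <- lmax[iy[lmax] > 0.1 * max(iy)]
  # assign density mass to the nearest peak
  peaks_x <- den$x[lmax]
  masses <- if (length(peaks_x) == 1L) 1 else {
    assign_peak <- vapply(samples$rg, function(r)
      which.min(abs(peaks_x - r)), integer(1))
    as.vector(tapply(samples$w, factor(assign_peak,
                                       levels = seq_along(peaks_x)),
                     sum, default = 0) / sum(samples$w))
  }
  structure(list(n_states = length(peaks_x),
                 peaks = data.frame(rg = peaks_x, mass = masses),
                 histogram = data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                                        weight = as.vector(hist_tab)),
                 density = den, k = k),
            class = "state_count_report")
}

#' @export
print.state_count_report <- function(x, ...) {
  cat(sprintf("state count (k = %d fits): %d state(s)\n", x$k, x$n_states))
  cat(paste(sprintf("  Rg %.1f A (mass %.2f)", x$peaks$rg, x$peaks$mass),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Write a multistate search result as a tab-separated table
#'
#' @param search a [multistate_search()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_multistate <- function(search, file) {
  rows <- do.call(rbind, lapply(names(search$results), function(k) {
    tab <- search$results[[k]]
    cbind(k = k, tab)
  }))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# k\tchi2\tscale\tmean_rg\tids\tweights", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
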