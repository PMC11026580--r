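#' Flexibility definition of a structure model
#'
#' Groups the model beads into the units moved by the rigid-body sampler:
#' each Fab arm (its hinge linker, the Fab body, and the glycan chains
#' riding on it), the flexible tails, and the remaining glycan chains.
#' Derived directly from the topology the builder annotated.
#'
#' @param model a [structure_model()] with rigid-body and flexible labels.
#' @return list of class `flexibility_definition` with `arms`, `tails`,
#'   `glycans` and `groups` (the bead partition used for clash checks).
#' @export
flexibility_definition <- function(model) {
  if (!length(model$linkers))
    stop("model has no flexible linkers to sample")
  glycans_on <- function(host)
    model$glycans[vapply(model$glycans, function(g) identical(g$host, host),
                         logical(1))]
  arms <- lapply(model$linkers, function(lk) {
    gl <- glycans_on(lk$to)
    from_idx <- model$bodies[[lk$from]]
    list(linker_idx = lk$idx, body = lk$to, from = lk$from,
         body_idx = model$bodies[[lk$to]],
         glycan_idx = unlist(lapply(gl, `[[`, "idx"), use.names = FALSE))
  })
  tails <- lapply(model$tails, function(tl) {
    nm <- names(which(vapply(model$tails, identical, logical(1), tl)))
    list(idx = tl$idx)
  })
  tails <- lapply(names(model$tails), function(nm) {
    gl <- glycans_on(nm)
    list(idx = model$tails[[nm]]$idx,
         glycan_idx = unlist(lapply(gl, `[[`, "idx"), use.names = FALSE))
  })
  names(tails) <- names(model$tails)
  # clash groups: rigid bodies plus the glycans riding on them; linker
  # beads (hinges, tails) are bonded to their neighbours and excluded,
  # as are beads within a bonded-junction radius of the attachment
  # points: the IgA2 hinge is so short that the Fab shoulder rests
  # against the Fc top in compact conformations, so contacts across
  # that native interface must not count as clashes
  xyz <- model_xyz(model)
  junction_r2 <- 23^2
  groups <- lapply(arms, function(a) {
    tip <- xyz[a$linker_idx[length(a$linker_idx)], ]
    body_keep <- a$body_idx[rowSums(sweep(xyz[a$body_idx, , drop = FALSE],
                                          2, tip)^2) > junction_r2]
    c(body_keep, a$glycan_idx)
  })
  core_bodies <- setdiff(names(model$bodies),
                         vapply(arms, `[[`, character(1), "body"))
  core <- unlist(model$bodies[core_bodies], use.names = FALSE)
  anchors <- lapply(arms, function(a) xyz[a$linker_idx[1], ])
  for (an in anchors)
    core <- core[rowSums(sweep(xyz[core, , drop = FALSE], 2, an)^2) > junction_r2]
  groups$core <- c(core, unlist(lapply(tails, function(t) t$glycan_idx),
                                use.names = FALSE))
  structure(list(arms = arms, tails = tails, glycans = model$glycans,
                 groups = groups),
            class = "flexibility_definition")
}

# TRUE if any bead pair between different groups is closer than cutoff.
# A coarse subset pass catches most clashing candidates cheaply (subset
# pairs are real pairs, so a coarse hit is a definite clash); only
# coarse-clean group pairs pay for the full check.
has_clash <- function(xyz, groups, cutoff) {
  gn <- names(groups)
  c2 <- cutoff^2
  pair_min2 <- function(da, db) {
    min(outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * tcrossprod(da, db))
  }
  for (a in seq_along(gn)) {
    for (b in seq_along(gn)) {
      if (b <= a) next
      ia <- groups[[a]]; ib <- groups[[b]]
      da <- xyz[ia, , drop = FALSE]
      db <- xyz[ib, , drop = FALSE]
      # cheap bounding-sphere reject
      ca <- colMeans(da); cb <- colMeans(db)
      ra <- sqrt(max(rowSums(sweep(da, 2, ca)^2)))
      rb <- sqrt(max(rowSums(sweep(db, 2, cb)^2)))
      if (sqrt(sum((ca - cb)^2)) > ra + rb + cutoff) next
      if (length(ia) > 60L && length(ib) > 60L) {
        sa <- da[seq(1L, nrow(da), by = 3L), , drop = FALSE]
        sb <- db[seq(1L, nrow(db), by = 3L), , drop = FALSE]
        if (pair_min2(sa, sb) < c2) return(TRUE)
      }
      if (pair_min2(da, db) < c2) return(TRUE)
    }
  }
  FALSE
}

# straighten a linker chain to its full contour length along the seed
# chord direction, translating the downstream beads rigidly with it;
# high-temperature exploration is agnostic to the seed hinge geometry,
# so arm proposals start from this fully extended reference
straighten_chain <- function(xyz, chain_idx, downstream_idx,
                             body_idx = downstream_idx, spacing = 3.8) {
  n <- length(chain_idx)
  first <- xyz[chain_idx[1], ]
  last <- xyz[chain_idx[n], ]
  chord <- last - first
  len <- sqrt(sum(chord^2))
  dir0 <- if (len > 1) chord / len else {
    v <- stats::rnorm(3); v / sqrt(sum(v^2))
  }
  new_chain <- sweep(outer(seq_len(n) - 1, spacing * dir0), 2, first, `+`)
  shift <- new_chain[n, ] - last
  xyz[chain_idx, ] <- new_chain
  if (length(downstream_idx)) {
    xyz[downstream_idx, ] <- sweep(xyz[downstream_idx, , drop = FALSE],
                                   2, shift, `+`)
    # align the downstream body axis with the chain so the reference arm
    # is fully extended, not folded back over its anchor
    pivot <- new_chain[n, ]
    ctr <- colMeans(xyz[body_idx, , drop = FALSE])
    axis0 <- ctr - pivot
    if (sqrt(sum(axis0^2)) > 1) {
      R <- rotation_between(axis0, dir0)
      xyz[downstream_idx, ] <- sweep(sweep(xyz[downstream_idx, , drop = FALSE],
                                           2, pivot) %*% t(R), 2, pivot, `+`)
    }
  }
  xyz
}

# rigid affine x -> (x - piv) R^T + piv applied to rows of X, written
# as X R^T + offset to avoid per-row sweeps
apply_rot <- function(X, R, piv) {
  Y <- X %*% t(R)
  off <- piv - as.vector(R %*% piv)
  Y[, 1] <- Y[, 1] + off[1]
  Y[, 2] <- Y[, 2] + off[2]
  Y[, 3] <- Y[, 3] + off[3]
  Y
}

# apply the pivot-move cascade for one chain: for each chain bead k, a
# random-axis rotation of everything downstream about that bead. The
# rotations acting on the (large) downstream body are composed into one
# affine map and applied once.
pivot_chain <- function(xyz, chain_idx, downstream_of_chain, angle_sd,
                        first_uniform = FALSE) {
  R_acc <- diag(3); t_acc <- c(0, 0, 0); moved <- FALSE
  nc <- length(chain_idx)
  for (k in seq_len(nc)) {
    piv <- xyz[chain_idx[k], ]
    if (k == 1L && first_uniform && angle_sd > 0) {
      axis <- stats::rnorm(3)
      ang <- stats::runif(1, -pi, pi)
    } else {
      axis <- stats::rnorm(3)
      ang <- stats::rnorm(1, 0, angle_sd)
    }
    if (ang == 0) next
    R <- rotation_about(axis, ang)
    if (k < nc) {
      ci <- chain_idx[(k + 1L):nc]
      xyz[ci, ] <- apply_rot(xyz[ci, , drop = FALSE], R, piv)
    }
    R_acc <- R %*% R_acc
    t_acc <- as.vector(R %*% (t_acc - piv)) + piv
    moved <- TRUE
  }
  if (moved && length(downstream_of_chain)) {
    Y <- xyz[downstream_of_chain, , drop = FALSE] %*% t(R_acc)
    Y[, 1] <- Y[, 1] + t_acc[1]
    Y[, 2] <- Y[, 2] + t_acc[2]
    Y[, 3] <- Y[, 3] + t_acc[3]
    xyz[downstream_of_chain, ] <- Y
  }
  xyz
}

#' Sample a rigid-body conformational ensemble
#'
#' Generates conformers by randomized pivot moves on the flexible regions:
#' for every hinge-linker bead a random-axis rotation (angle ~ N(0,
#' `move_sd`)) is applied to all beads downstream of that arm, so the two
#' Fab arms move independently of each other; tails and glycan chains are
#' perturbed the same way. To emulate the ergodic exploration that
#' high-temperature dynamics provides, arm proposals start from the
#' straightened hinge reference, the first pivot of each arm is drawn
#' uniformly (decorrelating the arm direction from the seed), and the
#' pivot magnitude is drawn per conformer. Sampling is stratified over
#' target Rg windows (`rg_strata`), the desk equivalent of running the
#' high-temperature dynamics in Rg ranges, so the pool covers compact
#' through fully splayed arm arrangements evenly. Candidates with steric
#' clashes (any bead pair from different groups closer than
#' `clash_cutoff`) are rejected and redrawn. Rigid-body internal
#' coordinates are copied unchanged; the Debye profile and Rg are
#' computed for every accepted conformer. With `move_sd = 0` and
#' `glycan_move_sd = 0` the input model is returned unchanged.
#'
#' @param model seed [structure_model()].
#' @param flexdef a [flexibility_definition()]; derived from the model if
#'   `NULL`.
#' @param n number of conformers.
#' @param q q grid for the per-conformer profiles.
#' @param move_sd pivot angle standard deviation, radians (default 25
#'   degrees).
#' @param glycan_move_sd pivot angle sd for glycan-chain beads.
#' @param clash_cutoff minimal allowed inter-group bead distance
#'   (Angstrom).
#' @param rg_strata boundaries of the target Rg windows (Angstrom); the
#'   default spans the compact-to-splayed range reachable by an
#'   IgA2-like monomer under the steric rules.
#'   `NULL` disables stratification. A stratum that stays unreachable
#'   within the retry budget falls back to unconstrained sampling.
#' @param max_retry attempts per conformer before giving up.
#' @param seed integer seed.
#' @return list of class `ensemble`: `models` (list of
#'   [structure_model()]), `rg` (numeric), `profiles` (matrix, one column
#'   per conformer), `q`, and `meta` (generation parameters).
#' @export
sample_ensemble <- function(model, flexdef = NULL, n = 1000L,
                            q = default_q_grid(), move_sd = 25 * pi / 180,
                            glycan_move_sd = 30 * pi / 180,
                            clash_cutoff = 3.0,
                            rg_strata = seq(44, 68, by = 4),
                            max_retry = 400L, seed = 1L) {
  stopifnot(n >= 1L)
  if (is.null(flexdef)) flexdef <- flexibility_definition(model)
  xyz0 <- model_xyz(model)
  f_w <- model$beads$f
  w2_pair <- pair_weights(f_w)
  self_term <- sum(f_w^2)
  rg_of <- function(xyz) {
    ctr <- colSums(xyz * f_w) / sum(f_w)
    sqrt(sum(f_w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(f_w))
  }
  withr::with_seed(as.integer(seed), {
    models <- vector("list", n)
    rg <- numeric(n)
    profs <- matrix(0, length(q), n)
    frozen <- move_sd == 0 && glycan_move_sd == 0
    # with zero moves the input is returned untouched; otherwise arm
    # proposals start from the straightened (fully extended) reference
    if (!frozen)
      for (arm in flexdef$arms)
        xyz0 <- straighten_chain(xyz0, arm$linker_idx,
                                 c(arm$body_idx, arm$glycan_idx),
                                 body_idx = arm$body_idx)
    n_strata <- if (is.null(rg_strata) || frozen) 0L else length(rg_strata) - 1L
    propose <- function(sfrac) {
      xyz <- xyz0
      for (arm in flexdef$arms) {
        # heterogeneous pivot magnitude: compact strata draw large moves,
        # extended strata small ones, emulating the range of effective
        # temperatures that lets the dynamics visit the whole Rg range
        sd_i <- if (move_sd > 0)
          move_sd * (0.2 + stats::runif(1) * (0.2 + 2 * (1 - sfrac)))
        else 0
        xyz <- pivot_chain(xyz, arm$linker_idx,
                           c(arm$body_idx, arm$glycan_idx),
                           sd_i, first_uniform = TRUE)
      }
      for (tl in flexdef$tails) xyz <- pivot_chain(xyz, tl$idx,
                                                   tl$glycan_idx, move_sd)
      for (gl in flexdef$glycans) xyz <- pivot_chain(xyz, gl$idx, integer(0),
                                                     glycan_move_sd)
      xyz
    }
    for (i in seq_len(n)) {
      if (frozen) {
        xyz <- xyz0
      } else {
        stratum <- if (n_strata > 0L) (i - 1L) %% n_strata + 1L else 0L
        bounds <- if (stratum > 0L) rg_strata[stratum + 0:1] else NULL
        sfrac <- if (n_strata > 1L) (stratum - 1) / (n_strata - 1) else 0.5
        xyz <- NULL
        for (try in seq_len(max_retry)) {
          cand <- propose(sfrac)
          if (!is.null(bounds)) {
            rg_c <- rg_of(cand)
            if (rg_c < bounds[1] || rg_c >= bounds[2]) next
          }
          if (!has_clash(cand, flexdef$groups, clash_cutoff)) {
            xyz <- cand
            break
          }
        }
        if (is.null(xyz)) {
          # stratum unreachable within the retry budget: fall back to the
          # first clash-free candidate regardless of Rg
          for (try in seq_len(max_retry)) {
            cand <- propose(0.5)
            if (!has_clash(cand, flexdef$groups, clash_cutoff)) {
              xyz <- cand
              break
            }
          }
        }
        if (is.null(xyz))
          stop(sprintf(paste0("no clash-free conformer found in %d retries ",
                              "(move_sd = %.2f rad, cutoff = %.1f A)"),
                       max_retry, move_sd, clash_cutoff))
      }
      mi <- model
      mi$beads$x <- xyz[, 1]; mi$beads$y <- xyz[, 2]; mi$beads$z <- xyz[, 3]
      models[[i]] <- mi
      rg[i] <- model_rg(mi)
      profs[, i] <- debye_binned_I(as.vector(stats::dist(xyz)), w2_pair,
                                   self_term, q, bin_width = 0.25)
    }
    colnames(profs) <- sprintf("c%04d", seq_len(n))
    structure(list(models = models, rg = rg, profiles = profs, q = q,
                   meta = list(seed = as.integer(seed), n = n,
                               move_sd = move_sd,
                               glycan_move_sd = glycan_move_sd,
                               clash_cutoff = clash_cutoff,
                               rg_strata = rg_strata)),
              class = "ensemble")
  })
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d conformers, Rg %.1f-%.1f A (seed %d)\n",
              length(x$rg), min(x$rg), max(x$rg), x$meta$seed))
  invisible(x)
}

#' Rg span and histogram of an ensemble
#'
#' @param ensemble an [sample_ensemble()] result.
#' @param bin_width histogram bin width (Angstrom).
#' @return list with `min`, `max`, `mean`, and `histogram` (an object from
#'   [hist()], not plotted).
#' @export
ensemble_rg_span <- function(ensemble, bin_width = 1) {
  rg <- ensemble$rg
  if (!length(rg)) stop("empty ensemble")
  breaks <- seq(floor(min(rg)) - bin_width, ceiling(max(rg)) + bin_width,
                by = bin_width)
  list(min = min(rg), max = max(rg), mean = mean(rg),
       histogram = graphics::hist(rg, breaks = breaks, plot = FALSE))
}
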