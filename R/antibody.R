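#' Specification of a coarse-grained IgA2-like antibody
#'
#' Collects the parameters of the toy-antibody builder: bead counts for the
#' two Fab arms and the Fc, the heavy-chain intervals treated as flexible
#' (hinge and C-terminal tailpiece), the N-glycosylation sites, and the
#' excess scattering weight of glycan beads. Defaults emulate a monomeric
#' IgA2 (m2) antibody with five N-glycosylation sites per heavy chain.
#'
#' @param n_res_fab residue (bead) count per Fab arm. The default 440
#'   covers VH+CH1 of the heavy chain plus a full light chain.
#' @param n_res_fc residue count of the Fc (CH2-CH3 of both heavy chains).
#' @param hinge_range two integers, heavy-chain residue interval of the
#'   flexible hinge (1-based sequential numbering per heavy chain).
#' @param tail_range residue interval of the C-terminal tailpiece.
#' @param glycan_sites data.frame with columns `site` (label), `residue`
#'   (heavy-chain residue the chain is attached to), `length` (beads per
#'   chain, one bead per monosaccharide) and `occupancy` (probability in
#'   \[0, 1\] that a given copy of the site carries a glycan). The default
#'   lists the five IgA2 (m2) sites; the tailpiece site (NVS sequon) is
#'   partially occupied.
#' @param glycan_weight_ratio per-bead scattering weight of a glycan bead
#'   relative to a protein bead; must be >= 1 because glycans scatter in
#'   excess of protein at equal volume.
#' @param seed integer seed for the stochastic parts of the builder
#'   (ellipsoid bead filling, glycan occupancy draws, small placement
#'   jitter).
#'
#' @return a list of class `antibody_spec`.
#' @export
antibody_spec <- function(n_res_fab = 440L,
                          n_res_fc = 450L,
                          hinge_range = c(228L, 235L),
                          tail_range = c(449L, 466L),
                          glycan_sites = default_glycan_sites(),
                          glycan_weight_ratio = 1.3,
                          seed = 1L) {
  stopifnot(n_res_fab >= 50L, n_res_fc >= 50L,
            length(hinge_range) == 2L, length(tail_range) == 2L,
            hinge_range[1] < hinge_range[2], tail_range[1] < tail_range[2])
  if (hinge_range[2] >= tail_range[1])
    stop("hinge and tail residue ranges overlap")
  if (glycan_weight_ratio < 1)
    stop("glycan_weight_ratio must be >= 1 (glycans scatter in excess of protein)")
  gs <- as.data.frame(glycan_sites)
  need <- c("site", "residue", "length", "occupancy")
  if (!all(need %in% names(gs)))
    stop("glycan_sites needs columns: ", paste(need, collapse = ", "))
  if (any(gs$occupancy < 0 | gs$occupancy > 1))
    stop("glycan occupancy must be in [0, 1]")
  if (any(gs$length < 0)) stop("glycan chain length must be >= 0")
  structure(list(n_res_fab = as.integer(n_res_fab),
                 n_res_fc = as.integer(n_res_fc),
                 hinge_range = as.integer(hinge_range),
                 tail_range = as.integer(tail_range),
                 glycan_sites = gs,
                 glycan_weight_ratio = glycan_weight_ratio,
                 seed = as.integer(seed)),
            class = "antibody_spec")
}

#' Default IgA2 (m2) N-glycosylation sites
#'
#' Five sites per heavy chain: two in CH1 (carried on the Fab arms), two in
#' CH2 (on the Fc) and one on the tailpiece. The tailpiece sequon (NVS) is
#' modelled as partially occupied; the others as fully occupied. One bead
#' per monosaccharide, default chain length 9 (a biantennary complex
#' glycan).
#'
#' @return data.frame with columns `site`, `residue`, `length`, `occupancy`.
#' @export
default_glycan_sites <- function() {
  data.frame(site = c("NVT", "NSS", "NLT", "NIT", "NVS"),
             residue = c(166L, 211L, 263L, 337L, 459L),
             length = 9L,
             occupancy = c(1, 1, 1, 1, 0.8),
             stringsAsFactors = FALSE)
}

# quasi-uniform fill of an ellipsoid with n beads: a low-discrepancy
# (R2-sequence) ball scaled to the semi-axes, plus a small seeded jitter.
# The deterministic fill keeps the pair-distance structure of the domain
# stable across builder seeds; the jitter breaks lattice-like artifacts.
# semi = semi-axes (A) along the local x/y/z axes.
fill_ellipsoid <- function(n, semi, jitter = 0.8) {
  i <- seq_len(n)
  r <- ((i - 0.5) / n)^(1 / 3)
  cz <- 1 - 2 * ((i * 0.7548776662467) %% 1)
  sz <- sqrt(pmax(0, 1 - cz^2))
  ph <- 2 * pi * ((i * 0.5698402909980) %% 1)
  xyz <- cbind(x = semi[1] * r * sz * cos(ph),
               y = semi[2] * r * sz * sin(ph),
               z = semi[3] * r * cz)
  xyz + matrix(stats::rnorm(3L * n, 0, jitter), ncol = 3L)
}

# place n beads on a smooth curve from `from` to `to` whose length is
# close to `contour` (a bulged quadratic Bezier when the chord is shorter
# than the contour). Returns an n x 3 matrix excluding both endpoints.
lay_chain <- function(from, to, n, contour, bulge_dir = NULL) {
  chord <- sqrt(sum((to - from)^2))
  tgrid <- seq(0, 1, length.out = n + 2L)[-c(1L, n + 2L)]
  if (chord >= contour || chord < 1e-9) {
    return(sweep(outer(tgrid, to - from), 2, from, `+`))
  }
  if (is.null(bulge_dir)) {
    d <- (to - from) / chord
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    bulge_dir <- c(d[2] * ref[3] - d[3] * ref[2],
                   d[3] * ref[1] - d[1] * ref[3],
                   d[1] * ref[2] - d[2] * ref[1])
    bulge_dir <- bulge_dir / sqrt(sum(bulge_dir^2))
  }
  bez_len <- function(h) {
    ctrl <- (from + to) / 2 + h * bulge_dir
    tt <- seq(0, 1, length.out = 64L)
    p <- outer((1 - tt)^2, from) + outer(2 * tt * (1 - tt), ctrl) +
      outer(tt^2, to)
    sum(sqrt(rowSums(diff(p)^2)))
  }
  h <- tryCatch(stats::uniroot(function(h) bez_len(h) - contour,
                               c(0, 2 * contour))$root,
                error = function(e) 0.5 * contour)
  ctrl <- (from + to) / 2 + h * bulge_dir
  outer((1 - tgrid)^2, from) + outer(2 * tgrid * (1 - tgrid), ctrl) +
    outer(tgrid^2, to)
}

# Fab-arm placement per conformational mode, in the molecular frame
# (Fc centred at the origin, its long axis along y, hinge anchors near
# the top of the Fc). `x` and `y` place the Fab centroid at (+/-x, y, 0);
# `tilt` rotates the Fab long axis away from the radial (anchor-to-centre)
# direction, about z, in degrees. Calibrated so whole-molecule Rg lands in
# the windows seen for IgA2 (m2) two-state models: closed 43-46 A, open
# 52-54 A, extended 63-66 A.
arm_placement <- function(mode) {
  switch(mode,
         closed   = list(x = 32, y = 49, z = 0, tilt = 10),
         open     = list(x = 47, y = 51.5, z = 0, tilt = 15),
         extended = list(x = 68, y = 47, z = 0, tilt = 0),
         stop("unknown conformer mode: ", mode))
}

# Fab long-axis direction for an arm: the radial direction tilted about z
fab_axis_dir <- function(radial, tilt_deg, sgn) {
  as.vector(rotation_about(c(0, 0, 1), sgn * tilt_deg * pi / 180) %*% radial)
}

# geometric constants of the builder (Angstrom)
builder_geometry <- function() {
  list(fab_semi = c(47, 30, 24),     # local long axis x; domain Rg ~27 A
       fc_semi = c(28, 43, 25),      # long axis y (vertical); Rg ~25 A
       anchor = c(10, 41, 0),        # hinge exit on the Fc surface (+x copy)
       tail_root = c(8, -40, 0),     # tailpiece exit near the Fc bottom
       ca_spacing = 3.8,
       glycan_spacing = 4.3,
       tail_helix_radius = 7,
       tail_helix_pitch = 0.8,
       jitter_angle_sd = 2 * pi / 180, # per-arm placement jitter
       jitter_dist_sd = 1)
}

#' Build a coarse-grained IgA2-like antibody model
#'
#' Constructs a three-domain bead model (two Fab arms and one Fc) with
#' standard immunoglobulin-domain dimensions (each domain Rg roughly
#' 20-27 A), connected by flexible hinge linkers, with C-terminal
#' tailpieces and N-glycan bead chains attached at the specified sites.
#' Rigid-body labels (`Fab1`, `Fab2`, `Fc`) and flexible labels (hinges,
#' tails, glycan chains) are assigned for downstream conformational
#' sampling. The model is built in the closed conformation; use
#' [make_conformer()] for open/extended arrangements.
#'
#' @param spec an [antibody_spec()].
#' @return a [structure_model()].
#' @export
make_toy_antibody <- function(spec = antibody_spec()) {
  stopifnot(inherits(spec, "antibody_spec"))
  withr::with_seed(spec$seed, build_antibody(spec, mode = "closed"))
}

#' Reposition the Fab arms of an antibody model
#'
#' Returns a new model with identical intra-rigid-body geometry and the
#' Fab arms repositioned to a target conformational mode: `closed` is the
#' compact Y (Rg calibrated to 43-46 A), `open` an extended arrangement
#' (52-54 A), `extended` a maximally splayed one (63-66 A). A small seeded
#' jitter is applied to the arm placement so different seeds give distinct
#' but mode-consistent conformers.
#'
#' @param model a model from [make_toy_antibody()].
#' @param mode one of `"closed"`, `"open"`, `"extended"`.
#' @param seed integer seed for the placement jitter.
#' @return a [structure_model()].
#' @export
make_conformer <- function(model, mode = c("closed", "open", "extended"),
                           seed = 1L) {
  mode <- match.arg(mode)
  info <- model$info
  if (is.null(info$arms))
    stop("model lacks builder arm metadata; build it with make_toy_antibody()")
  geo <- builder_geometry()
  withr::with_seed(as.integer(seed), {
    beads <- model$beads
    xyz <- model_xyz(model)
    for (i in 1:2) {
      arm <- info$arms[[i]]
      sgn <- if (i == 1L) 1 else -1
      place <- arm_placement(mode)
      new_center <- c(sgn * (place$x + stats::rnorm(1, 0, geo$jitter_dist_sd)),
                      place$y + stats::rnorm(1, 0, geo$jitter_dist_sd),
                      sgn * place$z)
      anchor <- c(sgn * geo$anchor[1], geo$anchor[2], geo$anchor[3])
      radial <- new_center - anchor
      radial <- radial / sqrt(sum(radial^2))
      jit_ax <- stats::rnorm(3)
      radial <- as.vector(rotation_about(jit_ax,
                                         stats::rnorm(1, 0, geo$jitter_angle_sd)) %*% radial)
      new_dir <- fab_axis_dir(radial, place$tilt, sgn)
      R <- rotation_between(arm$dir, new_dir)
      move_idx <- c(model$bodies[[arm$body]],
                    unlist(lapply(model$glycans, function(g)
                      if (identical(g$host, arm$body)) g$idx else integer(0)),
                      use.names = FALSE))
      xyz[move_idx, ] <- sweep(sweep(xyz[move_idx, , drop = FALSE], 2,
                                     arm$center) %*% t(R), 2, new_center, `+`)
      # re-lay the hinge between the Fc anchor and the new proximal Fab tip
      tips <- rbind(new_center - geo$fab_semi[1] * new_dir,
                    new_center + geo$fab_semi[1] * new_dir)
      tip <- tips[which.min(rowSums(sweep(tips, 2, anchor)^2)), ]
      hidx <- model$linkers[[arm$linker]]$idx
      contour <- (length(hidx) + 1L) * geo$ca_spacing
      xyz[hidx, ] <- lay_chain(anchor, tip, length(hidx), contour)
      info$arms[[i]]$center <- new_center
      info$arms[[i]]$dir <- new_dir
    }
    beads$x <- xyz[, 1]; beads$y <- xyz[, 2]; beads$z <- xyz[, 3]
    info$mode <- mode
    structure_model(beads, model$bodies, model$linkers, model$tails,
                    model$glycans, info)
  })
}

# core builder, assumes the RNG state is already set by the caller
build_antibody <- function(spec, mode) {
  geo <- builder_geometry()
  n_fab <- spec$n_res_fab
  n_heavy_fab <- min(spec$hinge_range[1] - 1L, n_fab)
  n_hinge <- diff(spec$hinge_range) + 1L
  n_tail <- diff(spec$tail_range) + 1L
  n_fc_chain <- ceiling(spec$n_res_fc / 2)

  rows <- list(); bodies <- list(); linkers <- list(); tails <- list()
  glycans <- list(); arms <- list()
  bead_row <- function(xyz, kind, chain, resno, region, f) {
    data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], f = f, kind = kind,
               chain = chain, resno = resno, region = region,
               stringsAsFactors = FALSE)
  }
  n_so_far <- 0L
  add <- function(df) {
    rows[[length(rows) + 1L]] <<- df
    idx <- n_so_far + seq_len(nrow(df))
    n_so_far <<- n_so_far + nrow(df)
    idx
  }

  # --- Fc, centred at the origin, long axis along y
  fc_xyz <- fill_ellipsoid(spec$n_res_fc, geo$fc_semi)
  fc_chain <- rep(c("A", "B"), c(n_fc_chain, spec$n_res_fc - n_fc_chain))
  fc_resno <- c(seq_len(n_fc_chain), seq_len(spec$n_res_fc - n_fc_chain)) +
    spec$hinge_range[2]
  bodies$Fc <- add(bead_row(fc_xyz, "protein", fc_chain, fc_resno, "Fc", 1))

  # --- two Fab arms with hinge linkers
  place <- arm_placement(mode)
  for (i in 1:2) {
    sgn <- if (i == 1L) 1 else -1
    body <- paste0("Fab", i)
    center <- c(sgn * (place$x + stats::rnorm(1, 0, geo$jitter_dist_sd)),
                place$y + stats::rnorm(1, 0, geo$jitter_dist_sd),
                sgn * place$z)
    anchor <- c(sgn * geo$anchor[1], geo$anchor[2], geo$anchor[3])
    radial <- center - anchor
    radial <- radial / sqrt(sum(radial^2))
    radial <- as.vector(rotation_about(stats::rnorm(3),
                                       stats::rnorm(1, 0, geo$jitter_angle_sd)) %*% radial)
    dir <- fab_axis_dir(radial, place$tilt, sgn)
    R <- rotation_between(c(1, 0, 0), dir)
    fab_local <- fill_ellipsoid(n_fab, geo$fab_semi)
    fab_xyz <- sweep(fab_local %*% t(R), 2, center, `+`)
    heavy <- c("A", "B")[i]; light <- c("L", "M")[i]
    fab_chain <- rep(c(heavy, light), c(n_heavy_fab, n_fab - n_heavy_fab))
    fab_resno <- c(seq_len(n_heavy_fab), seq_len(n_fab - n_heavy_fab))
    bodies[[body]] <- add(bead_row(fab_xyz, "protein", fab_chain, fab_resno,
                                   body, 1))
    tips <- rbind(center - geo$fab_semi[1] * dir,
                  center + geo$fab_semi[1] * dir)
    tip <- tips[which.min(rowSums(sweep(tips, 2, anchor)^2)), ]
    contour <- (n_hinge + 1L) * geo$ca_spacing
    hxyz <- lay_chain(anchor, tip, n_hinge, contour)
    lname <- paste0("hinge", i)
    lidx <- add(bead_row(hxyz, "protein", heavy,
                         seq(spec$hinge_range[1], spec$hinge_range[2]),
                         lname, 1))
    linkers[[lname]] <- list(idx = lidx, from = "Fc", to = body)
    arms[[i]] <- list(body = body, linker = lname, center = center,
                      dir = dir, anchor = anchor)
  }

  # --- C-terminal tailpieces: compact helical curls below the Fc
  for (i in 1:2) {
    sgn <- if (i == 1L) 1 else -1
    root <- c(sgn * geo$tail_root[1], geo$tail_root[2], geo$tail_root[3])
    k <- seq_len(n_tail)
    ang <- 0.9 * k + if (i == 2L) pi else 0
    txyz <- cbind(root[1] + geo$tail_helix_radius * cos(ang),
                  root[2] - geo$tail_helix_pitch * k,
                  root[3] + geo$tail_helix_radius * sin(ang))
    tname <- paste0("tail", i)
    tidx <- add(bead_row(txyz, "protein", c("T", "U")[i],
                         seq(spec$tail_range[1], spec$tail_range[2]),
                         tname, 1))
    tails[[tname]] <- list(idx = tidx, from = "Fc")
  }

  beads <- do.call(rbind, rows)

  # --- glycan chains: one bead per monosaccharide, occupancy drawn per copy
  site_host <- function(residue) {
    if (residue < spec$hinge_range[1]) "fab"
    else if (residue >= spec$tail_range[1] && residue <= spec$tail_range[2]) "tail"
    else "fc"
  }
  centers <- list(Fab1 = arms[[1]]$center, Fab2 = arms[[2]]$center,
                  Fc = c(0, 0, 0))
  for (s in seq_len(nrow(spec$glycan_sites))) {
    site <- spec$glycan_sites[s, ]
    if (site$length < 1L) next
    for (copy in 1:2) {
      if (stats::runif(1) >= site$occupancy) next
      hostkind <- site_host(site$residue)
      heavy <- c("A", "B")[copy]
      if (hostkind == "fab") {
        host <- paste0("Fab", copy)
        anchor_bead <- which(beads$region == host & beads$chain == heavy &
                               beads$resno == site$residue)[1]
        ctr <- centers[[host]]
      } else if (hostkind == "tail") {
        host <- paste0("tail", copy)
        tidx <- tails[[host]]$idx
        anchor_bead <- tidx[length(tidx)]
        ctr <- c(0, 0, 0)
      } else {
        host <- "Fc"
        anchor_bead <- which(beads$region == "Fc" & beads$chain == heavy &
                               beads$resno == site$residue)[1]
        ctr <- centers$Fc
      }
      if (is.na(anchor_bead))
        anchor_bead <- which(beads$region == host)[1]
      apos <- as.numeric(beads[anchor_bead, c("x", "y", "z")])
      dir <- apos - ctr
      nd <- sqrt(sum(dir^2))
      dir <- if (nd < 1e-6) c(0, 1, 0) else dir / nd
      # curled random walk outwards: glycans are floppy, so the chain
      # meanders instead of extending straight from the surface
      gxyz <- matrix(0, site$length, 3L)
      pos <- apos
      for (k in seq_len(site$length)) {
        pos <- pos + geo$glycan_spacing * dir
        gxyz[k, ] <- pos
        dir <- dir + 0.7 * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
      }
      gname <- sprintf("%s.%d", site$site, copy)
      gidx <- add(bead_row(gxyz, "glycan", "G", k, paste0("glycan:", gname),
                           spec$glycan_weight_ratio))
      beads <- rbind(beads, rows[[length(rows)]])
      glycans[[gname]] <- list(idx = gidx, host = host,
                               anchor = anchor_bead, site = site$site)
    }
  }

  structure_model(beads, bodies, linkers, tails, glycans,
                  info = list(spec = spec, mode = mode, arms = arms,
                              geometry = geo))
}
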