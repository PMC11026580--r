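#' Coarse-grained bead model of a macromolecule
#'
#' A `structure_model` holds one bead per residue (protein) or per
#' monosaccharide (glycan), together with the rigid-body / flexible-region
#' topology needed by the conformational sampler. Coordinates are in
#' Angstrom; each bead carries a dimensionless scattering weight `f`
#' (1 for protein beads, `glycan_weight_ratio` for glycan beads).
#'
#' @param beads data.frame with columns `x`, `y`, `z` (Angstrom), `f`
#'   (scattering weight, > 0), `kind` (`"protein"` or `"glycan"`), `chain`
#'   (single-character chain id), `resno` (integer residue index) and
#'   `region` (rigid-body or flexible-segment label).
#' @param bodies named list of integer bead-index vectors, one per rigid
#'   body (e.g. `Fab1`, `Fab2`, `Fc`).
#' @param linkers named list of flexible linkers; each element is a list
#'   with `idx` (ordered bead indices from the anchored end outwards),
#'   `from` (rigid body at the anchored end) and `to` (rigid body at the
#'   far end, or `NA` for a free end).
#' @param tails named list of flexible tails, same layout as `linkers`
#'   with a free far end.
#' @param glycans named list of glycan chains; each element has `idx`
#'   (ordered outwards from the attachment point), `host` (the body or
#'   tail the chain rides on) and `anchor` (index of the bead the chain
#'   is attached to).
#' @param info optional list of builder metadata (kept as an attribute).
#'
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(beads, bodies, linkers = list(), tails = list(),
                            glycans = list(), info = list()) {
  required <- c("x", "y", "z", "f", "kind", "chain", "resno", "region")
  missing <- setdiff(required, names(beads))
  if (length(missing))
    stop("beads is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(beads) < 1L) stop("a structure model needs at least one bead")
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite bead coordinates")
  if (any(!is.finite(beads$f)) || any(beads$f <= 0))
    stop("bead scattering weights must be finite and > 0")
  all_idx <- c(unlist(bodies, use.names = FALSE),
               unlist(lapply(c(linkers, tails, glycans), `[[`, "idx"),
                      use.names = FALSE))
  if (length(all_idx) && (anyDuplicated(all_idx) ||
                          any(all_idx < 1L | all_idx > nrow(beads))))
    stop("every bead must belong to exactly one rigid body or flexible set")
  structure(list(beads = beads, bodies = bodies, linkers = linkers,
                 tails = tails, glycans = glycans, info = info),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nb <- nrow(x$beads)
  ng <- sum(x$beads$kind == "glycan")
  cat(sprintf("structure_model: %d beads (%d protein, %d glycan)\n",
              nb, nb - ng, ng))
  cat(sprintf("  rigid bodies: %s\n", paste(names(x$bodies), collapse = ", ")))
  if (length(x$linkers))
    cat(sprintf("  linkers: %s\n", paste(names(x$linkers), collapse = ", ")))
  if (length(x$tails))
    cat(sprintf("  tails: %s\n", paste(names(x$tails), collapse = ", ")))
  if (length(x$glycans))
    cat(sprintf("  glycan chains: %d\n", length(x$glycans)))
  cat(sprintf("  Rg = %.1f A\n", model_rg(x)))
  invisible(x)
}

#' Bead coordinate matrix
#'
#' @param model a `structure_model`.
#' @return numeric matrix, one row per bead, columns x/y/z (Angstrom).
#' @export
model_xyz <- function(model) {
  as.matrix(model$beads[, c("x", "y", "z")])
}

#' Radius of gyration of a bead model
#'
#' Scattering-weight-weighted root-mean-square distance of the beads from
#' their weighted centroid.
#'
#' @param model a `structure_model`.
#' @return Rg in Angstrom.
#' @export
model_rg <- function(model) {
  xyz <- model_xyz(model)
  w <- model$beads$f
  ctr <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Write a bead model as a PDB file
#'
#' One bead becomes one ATOM record: protein beads are written as CA atoms
#' of ALA, glycan beads as C1 atoms of NAG. The scattering weight goes to
#' the B-factor column so it survives a round trip.
#'
#' @param model a `structure_model`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_model_pdb <- function(model, file) {
  b <- model$beads
  n <- nrow(b)
  elety <- ifelse(b$kind == "glycan", "C1", "CA")
  resid <- ifelse(b$kind == "glycan", "NAG", "ALA")
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(model_xyz(model))),
                   type = rep("ATOM", n),
                   resno = b$resno, resid = resid,
                   eleno = seq_len(n), elety = elety,
                   chain = substr(as.character(b$chain), 1L, 1L),
                   o = rep(1, n), b = b$f)
  invisible(file)
}

#' Read a bead model written by [write_model_pdb()]
#'
#' Topology (rigid bodies, flexible sets) is not encoded in PDB; the
#' returned model carries all beads in a single rigid body `all`, which is
#' sufficient for scattering and distance computations.
#'
#' @param file PDB path.
#' @return a `structure_model`.
#' @export
read_model_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  f <- at$b
  f[!is.finite(f) | f <= 0] <- 1
  beads <- data.frame(x = at$x, y = at$y, z = at$z, f = f,
                      kind = ifelse(at$resid == "NAG", "glycan", "protein"),
                      chain = at$chain, resno = at$resno,
                      region = "all", stringsAsFactors = FALSE)
  structure_model(beads, bodies = list(all = seq_len(nrow(beads))))
}

# rotation matrix about a unit axis (Rodrigues)
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * ux + (1 - c0) * tcrossprod(u)
}

# rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c0 <- sum(a * b)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- c(a[2] * ref[3] - a[3] * ref[2],
              a[3] * ref[1] - a[1] * ref[3],
              a[1] * ref[2] - a[2] * ref[1])
    return(rotation_about(axis, pi))
  }
  rotation_about(v / s, atan2(s, c0))
}
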