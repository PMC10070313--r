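## PDB-facing geometry operations. Parsing goes through bio3d; this file
## only maps atom records onto the package's ring/pigment containers.

## internal: resolve altlocs (highest occupancy, ties -> first encountered)
## and return the atom table of a bio3d pdb restricted to given resids
.pigment_atoms <- function(pdb, resid) {
  at <- pdb$atom
  at <- at[at$resid %in% resid & at$type %in% c("ATOM", "HETATM"), ,
           drop = FALSE]
  if (nrow(at) == 0L)
    stop("no pigment residues named ", paste(resid, collapse = "/"),
         " in structure", call. = FALSE)
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    ## stable order: keep first among max-occupancy duplicates
    ord <- order(key, -occ, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  }
  at
}

## internal: principal ring axis = direction of least variance of centers,
## with a deterministic sign (largest-|component| coordinate positive)
.ring_axis <- function(centers) {
  cc <- sweep(centers, 2, colMeans(centers))
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  ax <- ev$vectors[, 3]
  if (ax[which.max(abs(ax))] < 0) ax <- -ax
  ax
}

#' Extract a pigment ring from a PDB structure
#'
#' Reads a coordinate file in PDB format (ATOM and HETATM records, altloc
#' resolved by highest occupancy) and builds a [ring_geometry()] from the
#' Mg-chelating pigments: each selected residue contributes one pigment
#' whose center is the midpoint between its NB and ND atoms and whose
#' transition-dipole axis is the normalized NB to ND vector. Pigments are
#' ordered by azimuthal angle about the principal axis of the centers, ties
#' broken by axial coordinate.
#'
#' @param path PDB file path.
#' @param resid residue name(s) selecting the pigments (e.g. `"BCL"`).
#' @param atom_names named character vector with entries `nb` and `nd`
#'   (and optionally `mg`, unused for the center) giving the atom names.
#' @param dipole_magnitude Qy transition dipole in Debye, applied to all
#'   pigments.
#' @param symmetry_order number of repeating units n; default one pigment
#'   per unit.
#' @param classes optional length-N character vector of pigment classes
#'   *in ring order*, or a single class for all pigments (default "alpha").
#' @return A `ring_geometry`.
#' @export
extract_ring_from_structure <- function(path, resid = "BCL",
                                        atom_names = c(mg = "MG", nb = "NB",
                                                       nd = "ND"),
                                        dipole_magnitude = 6.3,
                                        symmetry_order = NULL,
                                        classes = "alpha") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- .pigment_atoms(pdb, resid)
  reskey <- paste(at$chain, at$resno, at$insert)
  res_ids <- unique(reskey)
  N <- length(res_ids)
  centers <- matrix(NA_real_, N, 3)
  axes <- matrix(NA_real_, N, 3)
  for (k in seq_len(N)) {
    sub <- at[reskey == res_ids[k], , drop = FALSE]
    nb <- sub[sub$elety == atom_names[["nb"]], c("x", "y", "z")]
    nd <- sub[sub$elety == atom_names[["nd"]], c("x", "y", "z")]
    if (nrow(nb) != 1L || nrow(nd) != 1L)
      stop("residue ", sub$resid[1], " ", res_ids[k], " lacks a unique ",
           atom_names[["nb"]], "/", atom_names[["nd"]], " atom pair",
           call. = FALSE)
    nb <- as.numeric(nb); nd <- as.numeric(nd)
    v <- nd - nb
    if (sqrt(sum(v^2)) == 0)
      stop("zero-length NB-ND vector in residue ", res_ids[k],
           call. = FALSE)
    centers[k, ] <- (nb + nd) / 2
    axes[k, ] <- v / sqrt(sum(v^2))
  }
  ## ring frame and azimuthal ordering
  zax <- .ring_axis(centers)
  cen0 <- sweep(centers, 2, colMeans(centers))
  ref <- cen0[1, ] - sum(cen0[1, ] * zax) * zax
  if (sqrt(sum(ref^2)) < 1e-8) ref <- c(1, 0, 0) - zax[1] * zax
  xax <- ref / sqrt(sum(ref^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  ang <- atan2(cen0 %*% yax, cen0 %*% xax) %% (2 * pi)
  ord <- order(ang, cen0 %*% zax)

  if (is.null(symmetry_order)) symmetry_order <- N
  if (length(classes) == 1L) classes <- rep(classes, N)
  per_unit <- N %/% as.integer(symmetry_order)
  units <- rep(seq_len(as.integer(symmetry_order)), each = per_unit)
  ring_geometry(centers[ord, , drop = FALSE], axes[ord, , drop = FALSE],
                rep(dipole_magnitude, N), classes, units,
                symmetry_order)
}

#' Write a ring geometry as a synthetic PDB fixture
#'
#' Encodes each pigment as a residue with MG (at the center), NB and ND
#' atoms placed at center -/+ the dipole axis (1 Angstrom half-spacing), so
#' that [extract_ring_from_structure()] recovers centers and axes exactly.
#' Intended for tests and for exporting idealized geometries.
#'
#' @param ring a `ring_geometry`.
#' @param path output file path.
#' @param resid residue name to use (default "BCL").
#' @return `path`, invisibly.
#' @export
write_ring_pdb <- function(ring, path, resid = "BCL") {
  N <- n_pigments(ring)
  xyz <- matrix(NA_real_, 3 * N, 3)
  for (i in seq_len(N)) {
    r <- 3L * (i - 1L)
    xyz[r + 1L, ] <- ring$centers[i, ]
    xyz[r + 2L, ] <- ring$centers[i, ] - ring$dipole_axes[i, ]
    xyz[r + 3L, ] <- ring$centers[i, ] + ring$dipole_axes[i, ]
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = rep("HETATM", 3L * N),
                   resno = rep(seq_len(N), each = 3L),
                   resid = rep(resid, 3L * N),
                   elety = rep(c("MG", "NB", "ND"), N),
                   chain = rep("A", 3L * N),
                   o = rep(1, 3L * N), b = rep(0, 3L * N))
  invisible(path)
}

## internal: coerce hbond input to a list of per-frame atom tables with
## columns elety, resno, chain, x, y, z
.as_frames <- function(frames) {
  if (is.character(frames) && length(frames) == 1L) {
    pdb <- bio3d::read.pdb(frames, multi = TRUE, verbose = FALSE)
    nmod <- nrow(pdb$xyz)
    return(lapply(seq_len(nmod), function(m) {
      at <- pdb$atom
      co <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
      at
    }))
  }
  if (is.data.frame(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    f <- as.data.frame(f)
    if (is.null(f$elety) && !is.null(f$name)) f$elety <- f$name
    if (is.null(f$chain)) f$chain <- NA_character_
    if (is.null(f$resno)) f$resno <- NA_integer_
    f
  })
}

## internal: resolve a selector to exactly one atom row
.select_one <- function(frame, sel) {
  keep <- rep(TRUE, nrow(frame))
  for (field in names(sel)) {
    col <- switch(field, name = "elety", field)
    if (is.null(frame[[col]]))
      stop("selector field '", field, "' absent from frame", call. = FALSE)
    keep <- keep & (frame[[col]] %in% sel[[field]])
  }
  hit <- which(keep)
  if (length(hit) != 1L)
    stop("selector {", paste(names(sel), unlist(sel), sep = "=",
                             collapse = ", "), "} matched ",
         length(hit), " atoms (need exactly 1)", call. = FALSE)
  hit
}

#' Per-frame hydrogen-bond distances
#'
#' Measures the O...H distance between a pigment acceptor oxygen and a
#' protein polar hydrogen across a set of frames (e.g. models of a
#' multi-model PDB), preserving frame order.
#'
#' @param frames a multi-model PDB path, a single atom data.frame, or a
#'   list of data.frames with columns `name` (or `elety`), `resno`,
#'   optional `chain`, and `x`, `y`, `z`.
#' @param donor_hydrogen,acceptor_oxygen named lists selecting exactly one
#'   atom each per frame, e.g. `list(resno = 43, name = "HE1")`.
#' @return numeric vector of distances (Angstrom), one per frame.
#' @export
hbond_distances <- function(frames, donor_hydrogen, acceptor_oxygen) {
  fr <- .as_frames(frames)
  vapply(fr, function(f) {
    ih <- .select_one(f, donor_hydrogen)
    io <- .select_one(f, acceptor_oxygen)
    sqrt((f$x[ih] - f$x[io])^2 + (f$y[ih] - f$y[io])^2 +
           (f$z[ih] - f$z[io])^2)
  }, numeric(1))
}

#' Hydrogen-bond occupancy summary
#'
#' Fraction of frames with O...H distance at or below a cutoff. The 2.5 A
#' default is a package convention for summarizing distance distributions,
#' not a universal definition of a hydrogen bond.
#'
#' @param distances numeric vector from [hbond_distances()].
#' @param cutoff distance threshold in Angstrom.
#' @return list with `n_frames`, `occupancy`, `mean_formed` (mean distance
#'   over frames within the cutoff, NA if none).
#' @export
hbond_occupancy <- function(distances, cutoff = 2.5) {
  formed <- distances <= cutoff
  list(n_frames = length(distances),
       occupancy = mean(formed),
       mean_formed = if (any(formed)) mean(distances[formed]) else NA_real_)
}
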