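#' Pigment geometry
#'
#' A single pigment's optical geometry: its center (the NB/ND midpoint for
#' bacteriochlorophylls), its Qy transition-dipole axis (the normalized
#' NB to ND direction) and the dipole magnitude in Debye.
#'
#' @param label character label (e.g. "alpha1", "B800_3").
#' @param class pigment class, one of `"alpha"`, `"beta"`, `"B800"`.
#' @param center numeric length-3, Angstrom.
#' @param dipole_axis numeric length-3; normalized internally, must be
#'   non-zero and finite.
#' @param dipole_magnitude positive scalar, Debye.
#' @return An object of class `pigment_geometry`.
#' @export
pigment_geometry <- function(label, class, center, dipole_axis,
                             dipole_magnitude) {
  .check_finite(center, "center")
  .check_finite(dipole_axis, "dipole_axis")
  .check_finite(dipole_magnitude, "dipole_magnitude")
  if (length(center) != 3L || length(dipole_axis) != 3L)
    stop("center and dipole_axis must be length-3 vectors", call. = FALSE)
  nrm <- sqrt(sum(dipole_axis^2))
  if (nrm == 0) stop("dipole_axis has zero length", call. = FALSE)
  if (dipole_magnitude <= 0)
    stop("dipole_magnitude must be positive", call. = FALSE)
  structure(list(label = as.character(label), class = as.character(class),
                 center = as.numeric(center),
                 dipole_axis = as.numeric(dipole_axis) / nrm,
                 dipole_magnitude = as.numeric(dipole_magnitude)),
            class = "pigment_geometry")
}

#' Ring geometry container
#'
#' Ordered collection of pigments forming a (possibly dimerized) ring with
#' n-fold symmetry. Pigments are stored in ring order (azimuthal angle about
#' the ring axis, ties broken by axial coordinate).
#'
#' @param centers N x 3 matrix, Angstrom.
#' @param dipole_axes N x 3 matrix of unit vectors.
#' @param dipole_magnitudes length-N positive vector, Debye.
#' @param classes length-N character (`"alpha"`, `"beta"`, `"B800"`, ...).
#' @param units length-N integer unit index (1..n).
#' @param symmetry_order n, integer number of repeating units.
#' @param labels optional length-N character labels.
#' @return An object of class `ring_geometry` with fields `centers`,
#'   `dipole_axes`, `dipole_magnitudes`, `classes`, `units`, `labels`,
#'   `symmetry_order`, `pigments_per_unit`.
#' @export
ring_geometry <- function(centers, dipole_axes, dipole_magnitudes, classes,
                          units, symmetry_order, labels = NULL) {
  centers <- as.matrix(centers)
  dipole_axes <- as.matrix(dipole_axes)
  n_pig <- nrow(centers)
  if (nrow(dipole_axes) != n_pig || length(dipole_magnitudes) != n_pig ||
      length(classes) != n_pig || length(units) != n_pig)
    stop("inconsistent pigment counts across fields", call. = FALSE)
  .check_finite(centers, "centers")
  .check_finite(dipole_axes, "dipole_axes")
  nrm <- sqrt(rowSums(dipole_axes^2))
  if (any(abs(nrm - 1) > 1e-10))
    dipole_axes <- dipole_axes / nrm
  if (any(dipole_magnitudes <= 0))
    stop("dipole magnitudes must be positive", call. = FALSE)
  symmetry_order <- as.integer(symmetry_order)
  if (n_pig %% symmetry_order != 0L)
    stop("pigment count ", n_pig, " is not a multiple of symmetry order ",
         symmetry_order, call. = FALSE)
  if (is.null(labels))
    labels <- paste0(classes, units)
  structure(list(centers = centers, dipole_axes = dipole_axes,
                 dipole_magnitudes = as.numeric(dipole_magnitudes),
                 classes = as.character(classes), units = as.integer(units),
                 labels = as.character(labels),
                 symmetry_order = symmetry_order,
                 pigments_per_unit = n_pig %/% symmetry_order),
            class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat("ring_geometry: ", nrow(x$centers), " pigments, C",
      x$symmetry_order, " symmetry, ", x$pigments_per_unit,
      " per unit\n", sep = "")
  cat("classes:", paste(unique(x$classes), collapse = ", "), "\n")
  invisible(x)
}

#' Number of pigments in a ring
#' @param ring a `ring_geometry`.
#' @return integer pigment count.
#' @export
n_pigments <- function(ring) nrow(ring$centers)

#' Extract one pigment from a ring
#' @param ring a `ring_geometry`.
#' @param i pigment index in ring order.
#' @return A `pigment_geometry`.
#' @export
pigment <- function(ring, i) {
  pigment_geometry(ring$labels[i], ring$classes[i], ring$centers[i, ],
                   ring$dipole_axes[i, ], ring$dipole_magnitudes[i])
}

#' Build an ideal Cn-symmetric pigment ring
#'
#' Places `n_units` copies of a repeating unit around the z axis. Each row
#' of `per_unit_spec` describes one pigment of the unit in local cylindrical
#' coordinates: a radial offset added to `radius`, an angular offset (rad)
#' added to the unit angle 2*pi*u/n, an axial (z) offset, and the dipole
#' direction as polar/azimuthal angles in the local frame whose x axis is
#' radial (outward), y axis tangential (direction of increasing angle) and
#' z the ring axis. A purely tangential in-plane dipole is
#' `theta = pi/2, psi = pi/2`.
#'
#' @param n_units integer >= 2.
#' @param per_unit_spec data.frame with columns `radial`, `angle`, `axial`,
#'   `theta`, `psi`, `mag`, and optionally `class` (default "alpha").
#' @param radius ring radius in Angstrom, > 0.
#' @return A `ring_geometry` with exact Cn symmetry, pigments ordered by
#'   azimuthal angle.
#' @export
build_ideal_ring <- function(n_units, per_unit_spec, radius) {
  n_units <- as.integer(n_units)
  if (n_units < 2L) stop("n_units must be >= 2", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("non-finite or non-positive value in 'radius'", call. = FALSE)
  spec <- as.data.frame(per_unit_spec)
  req <- c("radial", "angle", "axial", "theta", "psi", "mag")
  missing_cols <- setdiff(req, names(spec))
  if (length(missing_cols))
    stop("per_unit_spec lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in req) .check_finite(spec[[cc]], paste0("per_unit_spec$", cc))
  if (is.null(spec$class)) spec$class <- "alpha"
  p <- nrow(spec)

  centers <- matrix(0, n_units * p, 3)
  axes <- matrix(0, n_units * p, 3)
  mags <- numeric(n_units * p)
  classes <- character(n_units * p)
  units <- integer(n_units * p)
  ang_all <- numeric(n_units * p)
  idx <- 1L
  for (u in seq_len(n_units)) {
    phi_u <- 2 * pi * (u - 1L) / n_units
    for (s in seq_len(p)) {
      phi <- phi_u + spec$angle[s]
      r <- radius + spec$radial[s]
      rhat <- c(cos(phi), sin(phi), 0)
      that <- c(-sin(phi), cos(phi), 0)
      zhat <- c(0, 0, 1)
      centers[idx, ] <- r * rhat + spec$axial[s] * zhat
      st <- sin(spec$theta[s])
      axes[idx, ] <- st * cos(spec$psi[s]) * rhat +
        st * sin(spec$psi[s]) * that + cos(spec$theta[s]) * zhat
      mags[idx] <- spec$mag[s]
      classes[idx] <- spec$class[s]
      units[idx] <- u
      ang_all[idx] <- phi %% (2 * pi)
      idx <- idx + 1L
    }
  }
  ord <- order(ang_all, centers[, 3])
  ring_geometry(centers[ord, , drop = FALSE], axes[ord, , drop = FALSE],
                mags[ord], classes[ord], units[ord], n_units)
}

#' Center-center distance between two pigments
#' @param p,q `pigment_geometry` objects.
#' @return Euclidean distance in Angstrom.
#' @export
center_distance <- function(p, q) {
  sqrt(sum((p$center - q$center)^2))
}

#' Orientation factor of the dipole-dipole interaction
#'
#' The Foerster orientation factor
#' kappa = mu1.mu2 - 3 (mu1.r)(mu2.r), with unit dipole axes and r the unit
#' center-center vector; kappa lies in \[-2, 2\].
#'
#' @param p,q `pigment_geometry` objects with distinct centers.
#' @return dimensionless kappa.
#' @export
orientation_factor <- function(p, q) {
  rvec <- q$center - p$center
  R <- sqrt(sum(rvec^2))
  if (R == 0) stop("coincident pigment centers", call. = FALSE)
  rhat <- rvec / R
  sum(p$dipole_axis * q$dipole_axis) -
    3 * sum(p$dipole_axis * rhat) * sum(q$dipole_axis * rhat)
}

#' Point-dipole excitonic coupling
#'
#' Ideal-dipole approximation V = C * kappa * mu_p * mu_q / R^3 with mu in
#' Debye, R in Angstrom and C the vacuum dipole-dipole constant
#' 5034.1 cm^-1 A^3 D^-2. No environment screening is applied; screening is
#' an explicit user multiplier via `conversion_constant`.
#'
#' @param p,q `pigment_geometry` objects with distinct centers.
#' @param conversion_constant constant C; defaults to the vacuum value.
#' @return coupling in cm^-1.
#' @export
point_dipole_coupling <- function(p, q,
                                  conversion_constant = .dipole_C) {
  R <- center_distance(p, q)
  if (R == 0) stop("coincident pigment centers", call. = FALSE)
  conversion_constant * orientation_factor(p, q) *
    p$dipole_magnitude * q$dipole_magnitude / R^3
}

#' Geometry table for all pigment pairs of a ring
#'
#' Computes center-center distance, orientation factor and point-dipole
#' coupling for each unordered pigment pair.
#'
#' @param ring a `ring_geometry`.
#' @param conversion_constant passed to [point_dipole_coupling()].
#' @return data.frame with columns `i`, `j`, `pair`, `distance_A`, `kappa`,
#'   `coupling_cm1`.
#' @export
pair_geometry_table <- function(ring, conversion_constant = .dipole_C) {
  N <- n_pigments(ring)
  out <- vector("list", N * (N - 1L) / 2L)
  k <- 1L
  for (i in seq_len(N - 1L)) {
    pi_ <- pigment(ring, i)
    for (j in seq.int(i + 1L, N)) {
      pj <- pigment(ring, j)
      out[[k]] <- data.frame(
        i = i, j = j,
        pair = paste(ring$labels[i], ring$labels[j], sep = "-"),
        distance_A = center_distance(pi_, pj),
        kappa = orientation_factor(pi_, pj),
        coupling_cm1 = point_dipole_coupling(pi_, pj, conversion_constant),
        stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}
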