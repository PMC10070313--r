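#' Site basis for a pigment aggregate
#'
#' @param energies Qy site energies in cm^-1.
#' @param classes per-site class labels ("alpha", "beta", "B800", ...).
#' @param labels optional site labels; default class + index.
#' @return object of class `site_basis`.
#' @export
site_basis <- function(energies, classes, labels = NULL) {
  .check_finite(energies, "site energies")
  if (length(energies) < 1L) stop("need at least one site", call. = FALSE)
  if (length(classes) != length(energies))
    stop("classes/energies length mismatch", call. = FALSE)
  if (is.null(labels)) labels <- paste0(classes, seq_along(energies))
  structure(list(energies = as.numeric(energies),
                 classes = as.character(classes),
                 labels = as.character(labels)),
            class = "site_basis")
}

#' Validate an excitonic coupling matrix
#'
#' @param V square numeric matrix in cm^-1; must be symmetric (to 1e-8)
#'   with zero diagonal.
#' @return the symmetrized matrix with exactly zero diagonal.
#' @export
coupling_matrix <- function(V) {
  V <- as.matrix(V)
  .check_finite(V, "couplings")
  if (nrow(V) != ncol(V)) stop("coupling matrix must be square",
                               call. = FALSE)
  if (max(abs(V - t(V))) > 1e-8)
    stop("coupling matrix asymmetric beyond 1e-8 cm^-1", call. = FALSE)
  if (max(abs(diag(V))) > 1e-8)
    stop("coupling matrix must have zero diagonal", call. = FALSE)
  V <- (V + t(V)) / 2
  diag(V) <- 0
  V
}

#' Charge-transfer manifold
#'
#' CT states between adjacent B850 pigment pairs. Each CT state is attached
#' to one site pair and may couple only to the two Qy states of that pair;
#' CT-CT couplings are zero by construction.
#'
#' @param energies CT state energies in cm^-1 (length M).
#' @param pairs 2-column integer matrix (M rows) of the site indices the
#'   m-th CT state bridges.
#' @param couplings N_p x M matrix of Qy-CT couplings in cm^-1; row i may
#'   be nonzero only if i belongs to the m-th pair.
#' @return object of class `ct_manifold`.
#' @export
ct_manifold <- function(energies, pairs, couplings) {
  .check_finite(energies, "ct energies")
  pairs <- matrix(as.integer(pairs), ncol = 2)
  couplings <- as.matrix(couplings)
  M <- length(energies)
  if (nrow(pairs) != M || ncol(couplings) != M)
    stop("CT manifold dimensions inconsistent", call. = FALSE)
  .check_finite(couplings, "ct couplings")
  for (m in seq_len(M)) {
    bad <- setdiff(which(couplings[, m] != 0), pairs[m, ])
    if (length(bad))
      stop("CT state ", m, " couples to site(s) ",
           paste(bad, collapse = ","), " outside its adjacent pair",
           call. = FALSE)
  }
  structure(list(energies = as.numeric(energies), pairs = pairs,
                 couplings = couplings),
            class = "ct_manifold")
}

#' Assemble the (CT-augmented) exciton Hamiltonian
#'
#' Builds the real symmetric matrix with site energies on the Qy diagonal,
#' excitonic couplings off-diagonal, CT energies on the CT diagonal and
#' Qy-CT couplings in the mixed block. CT-CT couplings are zero. Omitting
#' `ct` gives the standard Frenkel exciton Hamiltonian.
#'
#' @param sites a [site_basis()].
#' @param couplings N_p x N_p coupling matrix (validated via
#'   [coupling_matrix()]).
#' @param ct optional [ct_manifold()].
#' @return object of class `augmented_hamiltonian` with fields `matrix`,
#'   `n_sites`, `n_ct`, `classes`, `labels`.
#' @export
assemble_hamiltonian <- function(sites, couplings, ct = NULL) {
  V <- coupling_matrix(couplings)
  Np <- length(sites$energies)
  if (nrow(V) != Np)
    stop("coupling matrix dimension ", nrow(V),
         " does not match ", Np, " sites", call. = FALSE)
  Nct <- if (is.null(ct)) 0L else length(ct$energies)
  if (!is.null(ct) && nrow(ct$couplings) != Np)
    stop("CT coupling rows do not match site count", call. = FALSE)
  N <- Np + Nct
  H <- matrix(0, N, N)
  H[seq_len(Np), seq_len(Np)] <- V
  diag(H)[seq_len(Np)] <- sites$energies
  labels <- sites$labels
  if (Nct > 0L) {
    ctix <- Np + seq_len(Nct)
    diag(H)[ctix] <- ct$energies
    H[seq_len(Np), ctix] <- ct$couplings
    H[ctix, seq_len(Np)] <- t(ct$couplings)
    labels <- c(labels, paste0("CT", seq_len(Nct)))
  }
  structure(list(matrix = H, n_sites = Np, n_ct = Nct,
                 classes = sites$classes, labels = labels),
            class = "augmented_hamiltonian")
}

#' @export
print.augmented_hamiltonian <- function(x, ...) {
  cat("augmented_hamiltonian:", x$n_sites, "Qy sites,",
      x$n_ct, "CT states\n")
  invisible(x)
}

#' Diagonalize an exciton Hamiltonian
#'
#' Eigenvalues are returned ascending with orthonormal real eigenvectors in
#' a deterministic gauge (the first coefficient exceeding 1e-6 in magnitude
#' is made positive), so degenerate pairs are reproducible.
#'
#' @param H an `augmented_hamiltonian`.
#' @return object of class `exciton_states`: `energies` (ascending, cm^-1),
#'   `coefs` (N x N matrix, column k = state k over sites then CT),
#'   `n_sites`, `n_ct`, plus per-state observables added by
#'   [state_dipoles()], [rotational_strengths()], [k_labels()].
#' @export
diagonalize <- function(H) {
  M <- H$matrix
  .check_finite(M, "Hamiltonian matrix")
  ee <- eigen(M, symmetric = TRUE)
  ord <- order(ee$values)
  vals <- ee$values[ord]
  vecs <- ee$vectors[, ord, drop = FALSE]
  for (k in seq_along(vals)) {
    lead <- which(abs(vecs[, k]) > 1e-6)[1]
    if (!is.na(lead) && vecs[lead, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(energies = vals, coefs = vecs,
                 n_sites = H$n_sites, n_ct = H$n_ct,
                 classes = H$classes, labels = H$labels),
            class = "exciton_states")
}

#' @export
print.exciton_states <- function(x, ...) {
  cat("exciton_states:", length(x$energies), "states (",
      x$n_sites, "Qy +", x$n_ct, "CT basis )\n")
  cat("energy range:", round(min(x$energies), 1), "-",
      round(max(x$energies), 1), "cm^-1\n")
  invisible(x)
}

#' Exciton transition dipoles and dipole strengths
#'
#' mu_k = sum_i c_ki mu_i over Qy sites; CT basis states carry zero
#' transition dipole. With no CT states the total dipole strength is
#' conserved: sum_k |mu_k|^2 = sum_i |mu_i|^2.
#'
#' @param states an `exciton_states`.
#' @param geometry a `ring_geometry` with one pigment per Qy site, in the
#'   same order as the site basis.
#' @return `states` with fields `dipoles` (n_states x 3, Debye) and
#'   `dipole_strengths` (Debye^2).
#' @export
state_dipoles <- function(states, geometry) {
  Np <- states$n_sites
  if (n_pigments(geometry) != Np)
    stop("geometry has ", n_pigments(geometry),
         " pigments but Hamiltonian has ", Np, " Qy sites", call. = FALSE)
  mu_site <- geometry$dipole_axes * geometry$dipole_magnitudes
  csites <- states$coefs[seq_len(Np), , drop = FALSE]
  dip <- t(csites) %*% mu_site           # n_states x 3
  states$dipoles <- dip
  states$dipole_strengths <- rowSums(dip^2)
  states
}

#' Exciton rotational strengths
#'
#' R_k = nu_k * sum over site pairs i<j of c_ki c_kj (r_i - r_j).(mu_i x mu_j),
#' the conservative exciton CD expression (units cm^-1 D^2 A, reported up
#' to a global constant since CD spectra are max-normalized). CT basis
#' states contribute zero. The sum rule sum_k R_k / nu_k = 0 holds exactly.
#'
#' @inheritParams state_dipoles
#' @return `states` with field `rotational_strengths`.
#' @export
rotational_strengths <- function(states, geometry) {
  Np <- states$n_sites
  if (n_pigments(geometry) != Np)
    stop("geometry has ", n_pigments(geometry),
         " pigments but Hamiltonian has ", Np, " Qy sites", call. = FALSE)
  mu <- geometry$dipole_axes * geometry$dipole_magnitudes
  r <- geometry$centers
  ## A_ij = (r_i - r_j) . (mu_i x mu_j), symmetric with zero diagonal;
  ## R_k = nu_k * (1/2) c_k' A c_k
  A <- matrix(0, Np, Np)
  for (i in seq_len(Np)) {
    cr <- cbind(mu[i, 2] * mu[, 3] - mu[i, 3] * mu[, 2],
                mu[i, 3] * mu[, 1] - mu[i, 1] * mu[, 3],
                mu[i, 1] * mu[, 2] - mu[i, 2] * mu[, 1])
    dr <- sweep(-r, 2, -r[i, ])          # r_i - r_j rows
    A[i, ] <- rowSums(dr * cr)
  }
  A <- (A + t(A)) / 2                    # numerical symmetrization
  diag(A) <- 0
  csites <- states$coefs[seq_len(Np), , drop = FALSE]
  quad <- colSums(csites * (A %*% csites)) / 2
  states$rotational_strengths <- states$energies * quad
  states
}

#' Symmetry (k) labels for exciton states of a Cn ring
#'
#' Assigns to each state the dominant discrete-Fourier component of its
#' per-unit Qy coefficient pattern. Components k and n-k are pooled (the
#' degenerate +/-k pair of an ideal ring). States whose dominant component
#' carries less than `threshold` of the total spectral weight are labeled
#' "mixed" (disorder-localized states).
#'
#' @param states an `exciton_states` over a ring-ordered site basis.
#' @param symmetry_order n, number of repeating units.
#' @param pigments_per_unit sites per unit; n * pigments_per_unit must
#'   equal the number of Qy sites.
#' @param threshold dominance threshold (default 0.6).
#' @return `states` with character field `k_labels` ("0", "±1", ...,
#'   or "mixed").
#' @export
k_labels <- function(states, symmetry_order, pigments_per_unit,
                     threshold = 0.6) {
  Np <- states$n_sites
  n <- as.integer(symmetry_order)
  p <- as.integer(pigments_per_unit)
  if (n * p != Np)
    stop("symmetry order ", n, " x ", p,
         " per unit does not match ", Np, " sites", call. = FALSE)
  nk <- n %/% 2L
  labs <- character(length(states$energies))
  phase <- exp(-2i * pi * outer(seq_len(n) - 1L, 0:(n - 1L)) / n) # u x k
  for (st in seq_along(states$energies)) {
    cmat <- matrix(states$coefs[seq_len(Np), st], nrow = p) # p x n
    Fk <- cmat %*% phase                                    # p x k
    w <- colSums(abs(Fk)^2)
    pooled <- numeric(nk + 1L)
    pooled[1] <- w[1]
    for (k in seq_len(nk))
      pooled[k + 1L] <- w[k + 1L] +
        if (k != n - k) w[n - k + 1L] else 0
    tot <- sum(w)
    best <- which.max(pooled) - 1L
    labs[st] <- if (tot == 0 || pooled[best + 1L] / tot < threshold)
      "mixed" else if (best == 0L) "0" else paste0("±", best)
  }
  states$k_labels <- labs
  states
}

#' Band-level summary of exciton states
#'
#' @param states an `exciton_states`; for the bright-state energy it must
#'   carry dipole strengths ([state_dipoles()]).
#' @param qy_threshold minimum total Qy weight for a state to count as
#'   Qy-dominated in the band width (default 0.5).
#' @return list with `bright_energy` (dipole-strength-weighted mean energy
#'   of the two brightest states, cm^-1), `band_width` (max - min energy of
#'   Qy-dominated states, cm^-1), `ipr` (inverse participation ratio
#'   1 / sum c^4 per state).
#' @export
band_summary <- function(states, qy_threshold = 0.5) {
  ipr <- 1 / colSums(states$coefs^4)
  qy_w <- colSums(states$coefs[seq_len(states$n_sites), , drop = FALSE]^2)
  qy_dom <- qy_w >= qy_threshold
  e_qy <- states$energies[qy_dom]
  width <- if (length(e_qy)) max(e_qy) - min(e_qy) else 0
  bright <- NA_real_
  if (!is.null(states$dipole_strengths)) {
    ord <- order(states$dipole_strengths, decreasing = TRUE)
    top <- ord[seq_len(min(2L, length(ord)))]
    d <- states$dipole_strengths[top]
    bright <- if (sum(d) > 0) sum(states$energies[top] * d) / sum(d)
      else mean(states$energies[top])
  }
  list(bright_energy = bright, band_width = width, ipr = ipr)
}
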