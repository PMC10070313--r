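# shared fixtures built in code

# single pigment at the origin, dipole along x
mono_ring <- function(mag = 6.3) {
  ring_geometry(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1),
                mag, "alpha", 1L, 1L)
}

# homogeneous N-ring with tangential in-plane dipoles
tangential_ring <- function(n, radius = 25, mag = 6.3) {
  spec <- data.frame(radial = 0, angle = 0, axial = 0,
                     theta = pi / 2, psi = pi / 2, mag = mag,
                     class = "alpha")
  build_ideal_ring(n, spec, radius)
}

# circulant nearest-neighbor Hamiltonian on n sites
circulant_h <- function(n, eps, V) {
  Vm <- matrix(0, n, n)
  for (u in seq_len(n)) {
    v <- u %% n + 1L
    Vm[u, v] <- Vm[v, u] <- V
  }
  assemble_hamiltonian(site_basis(rep(eps, n), rep("alpha", n)), Vm)
}

# analytic circulant eigenvalues eps + 2 V cos(2 pi k / n), sorted
circulant_eigs <- function(n, eps, V) {
  sort(eps + 2 * V * cos(2 * pi * (0:(n - 1)) / n))
}

# random rigid transform applied to a pigment pair (shared rotation+shift)
rigid_transform_pair <- function(p, q, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3, sd = 10)
  tp <- function(x) pigment_geometry(x$label, x$class,
                                     as.numeric(Q %*% x$center) + shift,
                                     as.numeric(Q %*% x$dipole_axis),
                                     x$dipole_magnitude)
  list(p = tp(p), q = tp(q))
}

# random small exciton problem: geometry + Hamiltonian (seeded)
random_instance <- function(seed, n = 6) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * n, sd = 12), n)
  axes <- matrix(rnorm(3 * n), n)
  axes <- axes / sqrt(rowSums(axes^2))
  geom <- ring_geometry(centers, axes, runif(n, 4, 8),
                        rep("alpha", n), seq_len(n), n)
  V <- matrix(rnorm(n * n, sd = 60), n)
  V <- (V + t(V)) / 2
  diag(V) <- 0
  H <- assemble_hamiltonian(
    site_basis(12000 + rnorm(n, sd = 150), rep("alpha", n)), V)
  list(geom = geom, H = H)
}
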