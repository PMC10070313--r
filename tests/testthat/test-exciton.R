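test_that("Hamiltonian assembly lays out Qy, CT and mixed blocks", {
  sb <- site_basis(c(0, 0), c("alpha", "beta"))
  H <- assemble_hamiltonian(sb, matrix(c(0, 100, 100, 0), 2))
  expect_equal(H$matrix, matrix(c(0, 100, 100, 0), 2))
  ct <- ct_manifold(2000, matrix(c(1L, 2L), 1), matrix(c(300, 300), 2))
  H3 <- assemble_hamiltonian(sb, matrix(c(0, 100, 100, 0), 2), ct)
  expect_equal(H3$matrix,
               rbind(c(0, 100, 300), c(100, 0, 300), c(300, 300, 2000)))
  # CT coupled outside its adjacent pair is rejected
  expect_error(ct_manifold(2000, matrix(c(1L, 2L), 1),
                           matrix(c(300, 300, 5), 3)),
               "outside its adjacent pair")
  expect_error(assemble_hamiltonian(sb, matrix(c(0, 1, 2, 0), 2)),
               "asymmetric")
})

test_that("diagonalization matches closed forms for dimers", {
  sb <- site_basis(c(0, 0), c("alpha", "beta"))
  st <- diagonalize(assemble_hamiltonian(sb, matrix(c(0, 100, 100, 0),
                                                    2)))
  expect_equal(st$energies, c(-100, 100))
  # detuned dimer: splitting sqrt(D^2 + 4 V^2)
  for (case in list(c(250, 80), c(94, 380), c(10, 5))) {
    D <- case[1]; V <- case[2]
    sb2 <- site_basis(c(0, D), c("alpha", "beta"))
    st2 <- diagonalize(assemble_hamiltonian(sb2,
                                            matrix(c(0, V, V, 0), 2)))
    expect_equal(diff(st2$energies), sqrt(D^2 + 4 * V^2),
                 tolerance = 1e-10)
    expect_equal(sum(st2$energies), D, tolerance = 1e-10)
  }
})

test_that("circulant rings reproduce the analytic exciton band", {
  for (n in c(7, 9, 14, 18, 27)) {
    st <- diagonalize(circulant_h(n, 12500, 100))
    expect_equal(st$energies, circulant_eigs(n, 12500, 100),
                 tolerance = 1e-8)
    # orthonormal eigenvectors, trace conservation
    G <- crossprod(st$coefs)
    expect_lt(max(abs(G - diag(n))), 1e-10)
    expect_equal(sum(st$energies), n * 12500, tolerance = 1e-6)
  }
})

test_that("dipole strength concentrates in the k=+/-1 pair of a ring", {
  ring <- tangential_ring(9)
  H <- circulant_h(9, 12500, -250)   # tangential-gauge nearest neighbor
  st <- state_dipoles(diagonalize(H), ring)
  st <- k_labels(st, 9, 1)
  # k = 0 state (symmetric combination) is dark by symmetry
  k0 <- which(st$k_labels == "0")
  expect_lt(max(st$dipole_strengths[k0]), 1e-16 * 9 * 6.3^2)
  bright <- which(st$k_labels == "±1")
  expect_gte(sum(st$dipole_strengths[bright]) /
               sum(st$dipole_strengths), 0.95)
  # total strength conserved (no CT)
  expect_equal(sum(st$dipole_strengths), 9 * 6.3^2, tolerance = 1e-8)
})

test_that("single site exciton inherits the site dipole", {
  ring <- mono_ring()
  st <- state_dipoles(diagonalize(assemble_hamiltonian(
    site_basis(12000, "alpha"), matrix(0, 1, 1))), ring)
  expect_equal(st$dipole_strengths, 6.3^2)
  st <- rotational_strengths(st, ring)
  expect_equal(st$rotational_strengths, 0)
})

test_that("rotational strengths vanish for coplanar parallel dipoles and
           satisfy the conservative sum rule", {
  # two parallel dipoles: mu_i x mu_j = 0 for both states
  geom <- ring_geometry(rbind(c(0, 0, 0), c(9, 0, 0)),
                        rbind(c(0, 0, 1), c(0, 0, 1)), c(6.3, 6.3),
                        c("alpha", "beta"), 1:2, 2)
  st <- rotational_strengths(diagonalize(assemble_hamiltonian(
    site_basis(c(12000, 12000), c("alpha", "beta")),
    matrix(c(0, 100, 100, 0), 2))), geom)
  expect_equal(st$rotational_strengths, c(0, 0), tolerance = 1e-12)
})

test_that("sum rules hold on random geometries and Hamiltonians", {
  for (seed in 1:100) {
    inst <- random_instance(seed)
    st <- state_dipoles(diagonalize(inst$H), inst$geom)
    st <- rotational_strengths(st, inst$geom)
    tot_site <- sum(inst$geom$dipole_magnitudes^2)
    expect_equal(sum(st$dipole_strengths), tot_site,
                 tolerance = 1e-8 * tot_site)
    # conservative CD: sum_k R_k / nu_k = 0 relative to the lobe scale
    scale <- sum(abs(st$rotational_strengths / st$energies))
    expect_lt(abs(sum(st$rotational_strengths / st$energies)),
              1e-8 * max(scale, 1))
  }
})

test_that("k labels resolve circulant symmetry and disorder mixing", {
  st <- k_labels(diagonalize(circulant_h(7, 0, -100)), 7, 1)
  expect_equal(sort(table(st$k_labels), decreasing = TRUE),
               sort(table(c("0", "±1", "±1", "±2", "±2", "±3", "±3")),
                    decreasing = TRUE))
  # ground state of a V<0 ring is the all-positive k=0 combination
  expect_equal(st$k_labels[1], "0")
  expect_error(k_labels(diagonalize(circulant_h(7, 0, -100)), 3, 1),
               "does not match")
  # strong diagonal disorder localizes: most labels become "mixed"
  set.seed(11)
  e <- rnorm(14, 12500, 2000)
  H <- assemble_hamiltonian(site_basis(e, rep("alpha", 14)),
                            circulant_h(14, 0, 20)$matrix)
  stl <- k_labels(diagonalize(H), 7, 2)
  expect_gt(mean(stl$k_labels == "mixed"), 0.5)
})

test_that("band summary: width, IPR and bright energy behave as closed
           forms dictate", {
  # single site: width 0, IPR 1
  st1 <- diagonalize(assemble_hamiltonian(site_basis(12000, "alpha"),
                                          matrix(0, 1, 1)))
  bs1 <- band_summary(state_dipoles(st1, mono_ring()))
  expect_equal(bs1$band_width, 0)
  expect_equal(bs1$ipr, 1)
  # homogeneous ring: width = max-min of the circulant band
  for (n in c(7, 9, 18)) {
    st <- diagonalize(circulant_h(n, 12500, 150))
    bs <- band_summary(st)
    eigs <- circulant_eigs(n, 12500, 150)
    expect_equal(bs$band_width, max(eigs) - min(eigs), tolerance = 1e-8)
    # uniform delocalization: the non-degenerate k=0 state has IPR = n
    ipr_k0 <- bs$ipr[which.max(st$energies)]   # V>0: top is k=0
    expect_equal(ipr_k0, n, tolerance = 1e-6)
  }
})

test_that("CT augmentation perturbs the Qy band as second-order theory
           predicts", {
  sb <- site_basis(c(12000, 12000), c("alpha", "beta"))
  V <- matrix(c(0, 300, 300, 0), 2)
  base <- diagonalize(assemble_hamiltonian(sb, V))
  # zero CT coupling leaves the Qy eigenvalues untouched
  ct0 <- ct_manifold(15000, matrix(c(1L, 2L), 1), matrix(c(0, 0), 2))
  aug0 <- diagonalize(assemble_hamiltonian(sb, V, ct0))
  expect_equal(aug0$energies[1:2], base$energies, tolerance = 1e-10)
  # growing |V_CT| with CT above the band red-shifts the lowest exciton
  lows <- vapply(c(100, 200, 400), function(v) {
    ct <- ct_manifold(15000, matrix(c(1L, 2L), 1), matrix(c(v, -v), 2))
    min(diagonalize(assemble_hamiltonian(sb, V, ct))$energies)
  }, numeric(1))
  expect_true(all(diff(c(base$energies[1], lows)) < 0))
})
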