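# helpers: spectrum FWHM and area on a uniform grid
fwhm_of <- function(omega, y) {
  pk <- max(y)
  diff(range(omega[y >= pk / 2]))
}
area_of <- function(omega, y) sum(y) * (omega[2] - omega[1])

kB <- exciton_constants()$kB_cm1_per_K

test_that("spectral density evaluates as Drude + Brownian oscillators", {
  expect_equal(evaluate_spectral_density(
    spectral_density(0, 50), seq(0, 2000, 10)), rep(0, 201))
  sd1 <- spectral_density(100, 60)
  w <- seq(1, 3000, 0.5)
  J <- evaluate_spectral_density(sd1, w)
  # overdamped term peaks at omega_c with value lambda
  expect_equal(w[which.max(J)], 60, tolerance = 0.02)
  expect_equal(max(J), 100, tolerance = 1e-4)
  expect_error(spectral_density(-1, 50), "lambda_env")
  # quadrature of J / (pi w) recovers lambda_total within 1%
  sd2 <- spectral_density(100, 60,
                          data.frame(lambda = c(30, 45),
                                     omega = c(700, 1400),
                                     gamma = c(15, 15)))
  wq <- seq(0.05, 6e4, 0.1)
  lam <- sum(evaluate_spectral_density(sd2, wq) / wq) * 0.1 / pi
  expect_equal(lam, sd2$lambda_total, tolerance = 0.01)
})

test_that("g(t) limits: zero bath, classical curvature, lambda slope", {
  tgrid <- seq(0, by = 4, length.out = 1024)
  g0 <- lineshape_g(spectral_density(1e-12, 50), 300, tgrid)
  expect_lt(max(Mod(g0$g)), 1e-10)
  # doubling T doubles the early-time curvature of Re g (classical limit)
  sdo <- spectral_density(100, 20)
  g1 <- lineshape_g(sdo, 300, tgrid)
  g2 <- lineshape_g(sdo, 600, tgrid)
  expect_equal(Re(g2$g[3]) / Re(g1$g[3]), 2, tolerance = 0.05)
  # long-time Im g slope -> -2 pi c lambda_total
  c_cmfs <- exciton_constants()$c_cm_per_fs
  slope <- (Im(g1$g[1024]) - Im(g1$g[900])) / (tgrid[1024] - tgrid[900])
  expect_equal(slope / (-2 * pi * c_cmfs), sdo$lambda_total,
               tolerance = 0.02)
  # aliasing time grids are rejected with the required dt
  sdv <- spectral_density(50, 50, data.frame(lambda = 20, omega = 1500,
                                             gamma = 10))
  expect_error(lineshape_g(sdv, 300, seq(0, by = 40, length.out = 64)),
               "need dt")
})

test_that("high-temperature overdamped monomer line is Gaussian with
           sigma^2 = 2 lambda kB T", {
  lam <- 100
  sdo <- spectral_density(lam, 20)
  g <- lineshape_g(sdo, 300, seq(0, by = 4, length.out = 2048))
  st <- state_dipoles(diagonalize(assemble_hamiltonian(
    site_basis(12000, "alpha"), matrix(0, 1, 1))), mono_ring())
  grid <- seq(9000, 15000, 1)
  ab <- homogeneous_absorption(st, g, grid)
  sig <- sqrt(2 * lam * kB * 300)
  expect_equal(fwhm_of(grid, ab$intensity), 2.355 * sig,
               tolerance = 0.05)
})

test_that("zero-coupling spectra are additive over monomers", {
  g <- lineshape_g(spectral_density(80, 60), 300,
                   seq(0, by = 4, length.out = 1024))
  grid <- seq(9000, 16000, 2)
  geom2 <- ring_geometry(rbind(c(0, 0, 0), c(60, 0, 0)),
                         rbind(c(1, 0, 0), c(0, 1, 0)), c(6.3, 5),
                         c("alpha", "alpha"), 1:2, 2)
  H2 <- assemble_hamiltonian(site_basis(c(11800, 12600),
                                        c("alpha", "alpha")),
                             matrix(0, 2, 2))
  st2 <- state_dipoles(diagonalize(H2), geom2)
  tot <- homogeneous_absorption(st2, g, grid)$intensity
  mono <- function(e, i) {
    geom1 <- ring_geometry(geom2$centers[i, , drop = FALSE],
                           geom2$dipole_axes[i, , drop = FALSE],
                           geom2$dipole_magnitudes[i], "alpha", 1L, 1L)
    st <- state_dipoles(diagonalize(assemble_hamiltonian(
      site_basis(e, "alpha"), matrix(0, 1, 1))), geom1)
    homogeneous_absorption(st, g, grid)$intensity
  }
  parts <- mono(11800, 1) + mono(12600, 2)
  expect_lt(max(abs(tot - parts)) / max(parts), 1e-6)
})

test_that("per-state absorption area scales with dipole strength", {
  g <- lineshape_g(spectral_density(80, 60), 300,
                   seq(0, by = 4, length.out = 1024))
  grid <- seq(8000, 16000, 2)
  area_for <- function(mag, e) {
    geom <- ring_geometry(matrix(0, 1, 3), matrix(c(1, 0, 0), 1), mag,
                          "alpha", 1L, 1L)
    st <- state_dipoles(diagonalize(assemble_hamiltonian(
      site_basis(e, "alpha"), matrix(0, 1, 1))), geom)
    area_of(grid, homogeneous_absorption(st, g, grid)$intensity)
  }
  a1 <- area_for(3, 12000)
  a2 <- area_for(6, 12050)   # 4x dipole strength, nearly same energy
  expect_equal(a2 / a1, 4, tolerance = 0.02)
})

test_that("CD of a chiral dimer is conservative and the spectrum vanishes
           without rotational strength", {
  g <- lineshape_g(spectral_density(60, 60), 300,
                   seq(0, by = 2, length.out = 2048))
  grid <- seq(8000, 16000, 2)
  # single pigment: zero CD everywhere
  st1 <- rotational_strengths(state_dipoles(diagonalize(
    assemble_hamiltonian(site_basis(12000, "alpha"),
                         matrix(0, 1, 1))), mono_ring()), mono_ring())
  cd1 <- homogeneous_cd(st1, g, grid)
  expect_equal(max(abs(cd1$intensity)), 0)
  # chiral degenerate dimer: equal and opposite lobes integrate to ~0
  geom <- ring_geometry(rbind(c(0, 0, 0), c(12, 0, 0)),
                        rbind(c(0, 1, 0), c(0, 0.5, sqrt(0.75))),
                        c(6.3, 6.3), c("alpha", "beta"), 1:2, 2)
  H <- assemble_hamiltonian(site_basis(c(12000, 12000),
                                       c("alpha", "beta")),
                            matrix(c(0, 150, 150, 0), 2))
  st <- rotational_strengths(state_dipoles(diagonalize(H), geom), geom)
  # exact conservative sum rule on the strengths themselves
  expect_lt(abs(sum(st$rotational_strengths / st$energies)),
            1e-10 * sum(abs(st$rotational_strengths / st$energies)))
  # an ideal +/-R couplet integrates to zero within 1% of the lobe area
  ideal <- st
  R0 <- mean(abs(st$rotational_strengths))
  ideal$rotational_strengths <- c(R0, -R0)
  cdi <- homogeneous_cd(ideal, g, grid)$intensity
  expect_lt(abs(area_of(grid, cdi)) / area_of(grid, pmax(cdi, 0)), 0.01)
  # the physical couplet is conservative up to the splitting/energy ratio
  # (R_k carries the transition-frequency factor)
  cd <- homogeneous_cd(st, g, grid)$intensity
  resid <- abs(area_of(grid, cd)) / area_of(grid, pmax(cd, 0))
  ratio <- diff(st$energies) / mean(st$energies)
  expect_lt(resid, 2 * ratio)
})

test_that("exchange narrowing: the bright ring state is narrower than the
           monomer and narrows with ring size", {
  lam <- 150
  g <- lineshape_g(spectral_density(lam, 30), 300,
                   seq(0, by = 4, length.out = 2048))
  grid <- seq(8000, 16000, 1)
  widths <- vapply(c(1, 4, 9), function(n) {
    ring <- tangential_ring(max(n, 2), radius = 4 * n)
    if (n == 1) {
      st <- state_dipoles(diagonalize(assemble_hamiltonian(
        site_basis(12000, "alpha"), matrix(0, 1, 1))), mono_ring())
    } else {
      st <- state_dipoles(diagonalize(circulant_h(n, 12000, -1)), ring)
    }
    # keep only the brightest state to isolate its homogeneous width
    keep <- which.max(st$dipole_strengths)
    st$dipole_strengths[-keep] <- 0
    fwhm_of(grid, homogeneous_absorption(st, g, grid)$intensity)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # delocalization over n sites reduces sum c^4 to 1/n: Gaussian width
  # shrinks roughly as 1/sqrt(n)
  expect_equal(widths[3] / widths[1], sqrt(1 / 9), tolerance = 0.15)
})

test_that("redfield lifetimes are finite only where decay channels
           exist and broaden the lowest line", {
  sdo <- spectral_density(80, 60)
  st <- diagonalize(circulant_h(5, 12000, -150))
  lt <- redfield_lifetimes(st, sdo, 300)
  expect_true(all(lt > 0))
  expect_true(all(is.finite(lt[-1])))   # excited states decay downhill
})
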