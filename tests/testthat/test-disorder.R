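test_that("static site energies follow the env/vac decomposition", {
  rec <- disorder_record(E_env = 13700, E_vac = 13600,
                         classes = "alpha",
                         mean_vac = c(alpha = 13650))
  expect_equal(as.numeric(static_site_energy(rec)), 13750)
  # E_env = E_vac collapses to the class vacuum mean
  rec2 <- disorder_record(E_env = 13580, E_vac = 13580,
                          classes = "alpha",
                          mean_vac = c(alpha = 13650))
  expect_equal(as.numeric(static_site_energy(rec2)), 13650)
  expect_error(static_site_energy(
    disorder_record(13700, 13600, "beta", mean_vac = c(alpha = 1))),
    "beta")
})

test_that("static energies keep the env mean and the env-vac spread", {
  set.seed(3)
  n <- 1e4
  E_vac <- matrix(13500 + rnorm(n, sd = 120), ncol = 1)  # intramolecular
  E_env <- E_vac + rnorm(n, -250, 60)                    # env shift
  rec <- disorder_record(E_env, E_vac, "alpha")
  Es <- static_site_energy(rec)
  expect_equal(mean(Es), mean(E_env), tolerance = 1e-10)
  expect_equal(sd(Es), sd(E_env - E_vac), tolerance = 0.02 * sd(Es))
})

test_that("additional-disorder sampling is calibrated and reproducible", {
  H <- circulant_h(4, 12500, 100)
  m0 <- disorder_model(sigma_add = c(alpha = 0), seed = 5)
  same <- sample_realizations(H, m0, 3)
  for (h in same$hamiltonians) expect_identical(h$matrix, H$matrix)

  m <- disorder_model(sigma_add = c(alpha = 100), seed = 5)
  n <- 5000
  ens <- sample_realizations(H, m, n)
  E1 <- vapply(ens$hamiltonians, function(h) h$matrix[1, 1], numeric(1))
  expect_equal(sd(E1), 100, tolerance = 3 / sqrt(2 * n) * 3)
  # couplings untouched
  expect_equal(ens$hamiltonians[[17]]$matrix[1, 2], 100)
  # bitwise reproducibility from the seed
  ens2 <- sample_realizations(H, m, n)
  expect_identical(ens$hamiltonians[[n]]$matrix,
                   ens2$hamiltonians[[n]]$matrix)
  expect_error(sample_realizations(H, m, 0), ">= 1")
})

test_that("MD-like synthesis hits the class means and coupling spread", {
  purp <- load_bundle("LH2purp")
  geom <- bundle_geometry(purp, "full")
  Vbase <- average_hamiltonian(purp, "full")$matrix[1:21, 1:21]
  diag(Vbase) <- 0
  n <- 5000
  model <- disorder_model(sigma_static = c(alpha = 60, beta = 60,
                                           B800 = 120),
                          sigma_coupling = 10, seed = 9)
  ens <- synthesize_md_like_ensemble(geom, purp$site_energies, model, n,
                                     couplings = Vbase)
  est <- estimate_disorder(ens)
  for (cl in c("alpha", "beta", "B800")) {
    sig <- model$sigma_static[[cl]]
    n_sites <- sum(geom$classes == cl) * n
    expect_equal(est$sites$mean[est$sites$class == cl],
                 unname(purp$site_energies[cl]),
                 tolerance = 3 * sig / sqrt(n_sites) /
                   purp$site_energies[cl])
  }
  # the 166 cm^-1 inter-dimer coupling fluctuates with sd 10 +/- 0.5
  inter <- est$couplings[abs(est$couplings$mean - 166) < 3, ]
  expect_gt(nrow(inter), 0)
  expect_true(all(abs(inter$sd - 10) < 0.5))
  # sigma = 0 everywhere reproduces the averages exactly
  m0 <- disorder_model(seed = 2)
  ens0 <- synthesize_md_like_ensemble(geom, purp$site_energies, m0, 3,
                                      couplings = Vbase)
  expect_identical(ens0$hamiltonians[[1]]$matrix,
                   ens0$hamiltonians[[3]]$matrix)
})

test_that("disorder parameters are recovered within 5% at n = 2000", {
  geom <- tangential_ring(7)
  for (sig in c(20, 60, 120)) {
    model <- disorder_model(sigma_static = c(alpha = sig),
                            seed = 1000 + sig)
    ens <- synthesize_md_like_ensemble(
      geom, c(alpha = 12500), model, 2000,
      couplings = circulant_h(7, 0, 100)$matrix)
    est <- estimate_disorder(ens)
    expect_equal(est$sites$sd, sig, tolerance = 0.05)
  }
  expect_error(estimate_disorder(hamiltonian_ensemble(
    list(circulant_h(3, 0, 1)))), "at least 2")
})

test_that("constant ensembles estimate zero disorder", {
  H <- circulant_h(5, 12000, 50)
  ens <- hamiltonian_ensemble(list(H, H, H))
  est <- estimate_disorder(ens)
  expect_equal(est$sites$sd, 0)
  expect_true(all(est$couplings$sd == 0))
})

test_that("ensembles serialize to text and round-trip bitwise", {
  dir <- withr::local_tempdir()
  H <- circulant_h(4, 12500, 100)
  model <- disorder_model(sigma_add = c(alpha = 80), seed = 21)
  ens <- sample_realizations(H, model, 5)
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  expect_equal(length(back), 5L)
  for (i in 1:5)
    expect_equal(back$hamiltonians[[i]]$matrix,
                 ens$hamiltonians[[i]]$matrix, tolerance = 1e-14)
  # manifest alone regenerates the identical ensemble
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  model2 <- disorder_model(sigma_static = unlist(man$model$sigma_static),
                           sigma_add = unlist(man$model$sigma_add),
                           sigma_coupling = man$model$sigma_coupling,
                           seed = man$model$seed)
  regen <- sample_realizations(H, model2, 5)
  expect_identical(regen$hamiltonians[[5]]$matrix,
                   ens$hamiltonians[[5]]$matrix)
})
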