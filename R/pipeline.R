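## Ensemble-averaged spectra, band peak readout, mixed-model decomposition
## of bright-state shifts, and the CT-inclusion comparison.

#' Default lineshape configuration
#'
#' Packaged spectral density (Drude-Lorentz environmental part plus four
#' underdamped intramolecular BChl modes), 300 K, an 8 fs x 512 point time
#' grid and a 9000-18000 cm^-1 output grid. All parameters are plain list
#' entries and freely overridable.
#'
#' @param temperature K.
#' @return list with `sd`, `temperature`, `t_grid`, `omega_grid`,
#'   `use_lifetimes`.
#' @export
default_lineshape_config <- function(temperature = 300) {
  vib <- data.frame(lambda = c(25, 35, 30, 40),
                    omega = c(560, 750, 1110, 1520),
                    gamma = c(20, 20, 20, 20))
  list(sd = spectral_density(lambda_env = 80, omega_c = 60,
                             vib_modes = vib),
       temperature = temperature,
       t_grid = seq(0, by = 8, length.out = 512L),
       omega_grid = seq(9000, 18000, by = 5),
       use_lifetimes = FALSE)
}

#' Ensemble-averaged absorption and CD spectra
#'
#' Computes the homogeneous absorption and CD of every disorder
#' realization in the exciton basis, averages them, applies the global
#' frequency shift once to the output axis, and normalizes (absorption to
#' its maximum, CD to the largest band, positive or negative).
#'
#' @param ensemble a `hamiltonian_ensemble`.
#' @param geometry a `ring_geometry` matching the Qy sites.
#' @param lineshape_cfg list as from [default_lineshape_config()].
#' @param global_shift shift added to the frequency axis, cm^-1 (e.g. a
#'   negative value correcting a systematic quantum-chemistry error).
#' @return object of class `spectrum_result`: `omega` (shifted axis,
#'   cm^-1), `absorption`, `cd` (both normalized), `global_shift`,
#'   `n_realizations`, `provenance` (ensemble seed/model).
#' @export
ensemble_spectra <- function(ensemble, geometry,
                             lineshape_cfg = default_lineshape_config(),
                             global_shift = 0) {
  hs <- ensemble$hamiltonians
  if (!length(hs)) stop("empty ensemble", call. = FALSE)
  cfg <- lineshape_cfg
  g <- lineshape_g(cfg$sd, cfg$temperature, cfg$t_grid)
  grid <- cfg$omega_grid
  absor <- numeric(length(grid))
  cd <- numeric(length(grid))
  for (h in hs) {
    st <- diagonalize(h)
    st <- state_dipoles(st, geometry)
    st <- rotational_strengths(st, geometry)
    lt <- if (isTRUE(cfg$use_lifetimes))
      redfield_lifetimes(st, cfg$sd, cfg$temperature) else NULL
    absor <- absor + homogeneous_absorption(st, g, grid, lt)$intensity
    cd <- cd + homogeneous_cd(st, g, grid, lt)$intensity
  }
  absor <- absor / length(hs)
  cd <- cd / length(hs)
  if (max(absor) > 0) absor <- absor / max(absor)
  if (max(abs(cd)) > 0) cd <- cd / max(abs(cd))
  structure(list(omega = grid + global_shift, absorption = absor,
                 cd = cd, global_shift = global_shift,
                 n_realizations = length(hs),
                 provenance = list(seed = ensemble$seed,
                                   model = ensemble$model)),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("spectrum_result:", length(x$omega), "points,",
      x$n_realizations, "realization(s), global shift",
      x$global_shift, "cm^-1\n")
  invisible(x)
}

#' Band peak positions
#'
#' Argmax of a spectrum within named band windows, reported in cm^-1 and
#' nm (nm = 1e7 / cm^-1). Windows refer to the spectrum's own (already
#' shifted) axis.
#'
#' @param spectrum a `spectrum_result` (absorption channel) or a
#'   data.frame with columns `omega`, `intensity`.
#' @param windows named list of `c(lo, hi)` windows in cm^-1.
#' @param channel for `spectrum_result` inputs: `"absorption"` or `"cd"`
#'   (the CD peak is the largest |intensity|).
#' @return data.frame with columns `band`, `omega_cm1`, `nm`.
#' @export
peak_positions <- function(spectrum, windows,
                           channel = c("absorption", "cd")) {
  channel <- match.arg(channel)
  if (inherits(spectrum, "spectrum_result")) {
    omega <- spectrum$omega
    intensity <- spectrum[[channel]]
    if (channel == "cd") intensity <- abs(intensity)
  } else {
    omega <- spectrum$omega
    intensity <- spectrum$intensity
  }
  out <- lapply(names(windows), function(bn) {
    w <- windows[[bn]]
    sel <- omega >= w[1] & omega <= w[2]
    if (!any(sel))
      stop("band window '", bn, "' outside the spectrum grid",
           call. = FALSE)
    ii <- intensity[sel]
    if (max(ii) == min(ii))
      stop("flat spectrum in band window '", bn, "'", call. = FALSE)
    pk <- omega[sel][which.max(ii)]
    data.frame(band = bn, omega_cm1 = pk, nm = 1e7 / pk)
  })
  do.call(rbind, out)
}

## internal: bright-state energy of a B850-ring Hamiltonian
.bright_energy <- function(H, geometry) {
  st <- diagonalize(H)
  st <- state_dipoles(st, geometry)
  band_summary(st)$bright_energy
}

#' Mixed-model decomposition of the bright-state shift
#'
#' Substitutes parameters of a base ring model with those of another and
#' reports the resulting change of the bright-state energy (the
#' dipole-strength-weighted mean of the two brightest k = +/-1 states) on
#' the disorder-free average B850 Hamiltonian. Modes: `"site"` swaps the
#' alpha/beta site energies, `"coup"` swaps the B850 couplings
#' (intra-/inter-dimer, alpha-alpha, beta-beta), `"site_plus_coup"` both,
#' `"full"` compares the complete B850 models including ring size.
#'
#' @param bundle_a base [load_bundle()] bundle.
#' @param bundle_b bundle supplying substituted parameters.
#' @param mode substitution mode.
#' @return signed energy change in cm^-1 (mixed minus base; negative =
#'   red shift).
#' @export
mixed_model_shift <- function(bundle_a, bundle_b,
                              mode = c("site", "coup", "site_plus_coup",
                                       "full")) {
  mode <- match.arg(mode)
  if (mode != "full") {
    need <- c("intra_dimer", "inter_dimer", "alpha_alpha", "beta_beta")
    if (!all(need %in% names(bundle_b$couplings)) ||
        !all(c("alpha", "beta") %in% names(bundle_b$site_energies)))
      stop("bundles are not parameter-compatible; only mode='full' ",
           "compares unrelated topologies", call. = FALSE)
  }
  geom_a <- bundle_geometry(bundle_a, "B850")
  e_base <- .bright_energy(average_hamiltonian(bundle_a, "B850"), geom_a)
  mixed <- bundle_a
  if (mode == "full") {
    geom_b <- bundle_geometry(bundle_b, "B850")
    e_mix <- .bright_energy(average_hamiltonian(bundle_b, "B850"),
                            geom_b)
    return(e_mix - e_base)
  }
  if (mode %in% c("site", "site_plus_coup"))
    mixed$site_energies[c("alpha", "beta")] <-
      bundle_b$site_energies[c("alpha", "beta")]
  if (mode %in% c("coup", "site_plus_coup"))
    mixed$couplings[c("intra_dimer", "inter_dimer", "alpha_alpha",
                      "beta_beta")] <-
      bundle_b$couplings[c("intra_dimer", "inter_dimer", "alpha_alpha",
                           "beta_beta")]
  e_mix <- .bright_energy(average_hamiltonian(mixed, "B850"), geom_a)
  e_mix - e_base
}

#' Effect of charge-transfer states on the spectrum
#'
#' Runs two identical spectra pipelines differing only in the inclusion of
#' the bundle's CT manifold and reports the signed shift of the B850
#' absorption peak (with CT minus without; negative = CT red shift). The
#' B850 peak is located around the maximum of the no-CT spectrum
#' (window +/- `window_halfwidth`).
#'
#' @param bundle a [load_bundle()] bundle with CT parameters.
#' @param geometry optional `ring_geometry` (default the bundle's full
#'   idealized geometry).
#' @param n_frames disorder realizations (1 = average Hamiltonian only).
#' @param seed RNG seed for the disorder ensemble.
#' @param use_disorder draw static disorder around the class means;
#'   FALSE gives the deterministic average-Hamiltonian comparison.
#' @param lineshape_cfg list as from [default_lineshape_config()].
#' @param global_shift applied to both spectra, cm^-1.
#' @param window_halfwidth half width of the B850 peak search window,
#'   cm^-1.
#' @return list with `with_ct`, `without_ct` (both `spectrum_result`),
#'   `b850_shift` (cm^-1).
#' @export
ct_effect <- function(bundle, geometry = NULL, n_frames = 1L, seed = 1L,
                      use_disorder = FALSE,
                      lineshape_cfg = default_lineshape_config(),
                      global_shift = 0, window_halfwidth = 800) {
  if (is.null(bundle$ct))
    stop("bundle '", bundle$name, "' has no CT parameters", call. = FALSE)
  if (is.null(geometry)) geometry <- bundle_geometry(bundle, "full")
  ctm <- bundle_ct_manifold(bundle)
  model <- disorder_model(
    sigma_static = if (use_disorder)
      vapply(bundle$disorder$sigma_static[c("alpha", "beta", "B800")],
             as.numeric, numeric(1))
      else c(alpha = 0, beta = 0, B800 = 0),
    sigma_coupling = 0, seed = seed)
  base_H <- average_hamiltonian(bundle, "full")
  V <- base_H$matrix[seq_len(base_H$n_sites), seq_len(base_H$n_sites)]
  diag(V) <- 0
  cls_means <- bundle$site_energies[c("alpha", "beta", "B800")]
  ens_no <- synthesize_md_like_ensemble(geometry, cls_means, model,
                                        n_frames, couplings = V)
  ## same seed, same Qy draws: pipelines differ only in the CT manifold
  ctm_full <- ct_manifold(ctm$energies, ctm$pairs,
                          rbind(ctm$couplings,
                                matrix(0, bundle$n_units,
                                       length(ctm$energies))))
  ens_ct <- synthesize_md_like_ensemble(geometry, cls_means, model,
                                        n_frames, couplings = V,
                                        ct = ctm_full)
  sp_no <- ensemble_spectra(ens_no, geometry, lineshape_cfg, global_shift)
  sp_ct <- ensemble_spectra(ens_ct, geometry, lineshape_cfg, global_shift)
  ref <- sp_no$omega[which.max(sp_no$absorption)]
  win <- list(B850 = c(ref - window_halfwidth, ref + window_halfwidth))
  pk_no <- peak_positions(sp_no, win)$omega_cm1
  pk_ct <- peak_positions(sp_ct, win)$omega_cm1
  list(with_ct = sp_ct, without_ct = sp_no,
       b850_shift = pk_ct - pk_no)
}
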