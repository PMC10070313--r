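#' Composite spectral density
#'
#' J(w) = J_env(w) + J_vib(w): an overdamped Drude-Lorentz environmental
#' part, 2 lambda_env w w_c / (w^2 + w_c^2), plus a sum of underdamped
#' Brownian-oscillator intramolecular modes,
#' 2 lambda_j w_j^2 w gamma_j / ((w^2 - w_j^2)^2 + w^2 gamma_j^2).
#' Each term contributes its lambda to the total reorganization energy
#' lambda_total = (1/pi) * integral of J(w)/w.
#'
#' @param lambda_env environmental reorganization energy, cm^-1, >= 0.
#' @param omega_c Drude cutoff frequency, cm^-1, > 0.
#' @param vib_modes data.frame with columns `lambda`, `omega`, `gamma`
#'   (all cm^-1) or NULL for no vibrational modes.
#' @return object of class `spectral_density` with field `lambda_total`.
#' @export
spectral_density <- function(lambda_env, omega_c, vib_modes = NULL) {
  if (lambda_env < 0 || omega_c <= 0)
    stop("lambda_env must be >= 0 and omega_c > 0", call. = FALSE)
  if (!is.null(vib_modes)) {
    vib_modes <- as.data.frame(vib_modes)
    if (any(vib_modes$lambda < 0) || any(vib_modes$omega <= 0) ||
        any(vib_modes$gamma <= 0))
      stop("vibrational modes need lambda >= 0, omega > 0, gamma > 0",
           call. = FALSE)
  }
  structure(list(lambda_env = lambda_env, omega_c = omega_c,
                 vib_modes = vib_modes,
                 lambda_total = lambda_env +
                   if (is.null(vib_modes)) 0 else sum(vib_modes$lambda)),
            class = "spectral_density")
}

#' Evaluate a spectral density on a frequency grid
#'
#' @param sd a [spectral_density()].
#' @param omega frequency grid, cm^-1, >= 0.
#' @return J(omega) in cm^-1 (same length as `omega`).
#' @export
evaluate_spectral_density <- function(sd, omega) {
  if (any(omega < 0)) stop("omega grid must be >= 0", call. = FALSE)
  J <- 2 * sd$lambda_env * omega * sd$omega_c / (omega^2 + sd$omega_c^2)
  if (!is.null(sd$vib_modes)) {
    for (j in seq_len(nrow(sd$vib_modes))) {
      lj <- sd$vib_modes$lambda[j]
      wj <- sd$vib_modes$omega[j]
      gj <- sd$vib_modes$gamma[j]
      J <- J + 2 * lj * wj^2 * omega * gj /
        ((omega^2 - wj^2)^2 + omega^2 * gj^2)
    }
  }
  J
}

## internal: default quadrature grid for g(t): fine enough to resolve the
## narrowest Lorentzian and the Drude cutoff
.sd_quad_grid <- function(sd) {
  wid <- sd$omega_c
  wmax <- 6 * sd$omega_c
  if (!is.null(sd$vib_modes) && nrow(sd$vib_modes)) {
    wid <- min(wid, min(sd$vib_modes$gamma))
    wmax <- max(wmax, 1.5 * max(sd$vib_modes$omega))
  }
  dw <- min(1, wid / 6)
  wmax <- max(wmax, 3000)
  seq(dw / 2, wmax, by = dw)
}

#' Second-order cumulant lineshape function g(t)
#'
#' g(t) = (1/pi) * integral over w of J(w)/w^2 *
#' \[coth(w / 2 kB T) (1 - cos(2 pi c w t)) + i (sin(2 pi c w t) - 2 pi c w t)\]
#' with w in cm^-1 and t in fs (detailed balance through the coth factor).
#' The long-time slope of Im g is -2 pi c lambda_total (a lambda_total
#' red shift of the line).
#'
#' @param sd a [spectral_density()].
#' @param temperature K, > 0.
#' @param t_grid uniform time grid starting at 0, fs. The spacing must
#'   resolve the highest vibrational mode (2 c w_max dt < 1), else an
#'   error names the required dt.
#' @param omega_quad optional quadrature grid (cm^-1); a mode-resolving
#'   default is built from the spectral density.
#' @return object of class `lineshape_function`: fields `t` (fs), `g`
#'   (complex), `temperature`, `sd`, `lambda_total`.
#' @export
lineshape_g <- function(sd, temperature, t_grid, omega_quad = NULL) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (length(t_grid) < 2L || t_grid[1] != 0)
    stop("t_grid must start at 0 with at least 2 points", call. = FALSE)
  dt <- t_grid[2] - t_grid[1]
  if (dt <= 0) stop("t_grid spacing must be positive", call. = FALSE)
  wmax_mode <- sd$omega_c
  if (!is.null(sd$vib_modes) && nrow(sd$vib_modes))
    wmax_mode <- max(wmax_mode, max(sd$vib_modes$omega))
  dt_req <- 1 / (2 * .c_cmfs * wmax_mode)
  if (dt > dt_req)
    stop(sprintf(
      "t grid spacing %.3g fs aliases the %.0f cm^-1 mode; need dt <= %.3g fs",
      dt, wmax_mode, dt_req), call. = FALSE)
  if (is.null(omega_quad)) omega_quad <- .sd_quad_grid(sd)
  w <- omega_quad
  dw <- c(diff(w)[1], diff(w))     # uniform default grid
  J <- evaluate_spectral_density(sd, w)
  coth <- 1 / tanh(w / (2 * .kB * temperature))
  w_re <- dw / pi * J / w^2 * coth
  w_im <- dw / pi * J / w^2
  nt <- length(t_grid)
  g <- complex(length.out = nt)
  chunk <- 256L
  for (i0 in seq(1L, nt, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nt)
    th <- outer(2 * pi * .c_cmfs * w, t_grid[i0:i1])   # w x t
    re <- colSums(w_re * (1 - cos(th)))
    im <- colSums(w_im * (sin(th) - th))
    g[i0:i1] <- complex(real = re, imaginary = im)
  }
  structure(list(t = t_grid, g = g, temperature = temperature, sd = sd,
                 lambda_total = sd$lambda_total),
            class = "lineshape_function")
}

## internal: half-Fourier transform of f(t) on g's uniform grid by FFT with
## trapezoid end correction; returns list(omega_rel cm^-1 ascending, re)
.half_fourier <- function(tgrid, f) {
  N <- length(tgrid)
  dt <- tgrid[2] - tgrid[1]
  wts <- rep(1, N); wts[c(1L, N)] <- 0.5
  F <- stats::fft(wts * f, inverse = TRUE) * dt
  m <- seq_len(N) - 1L
  nu <- (m - N * (m >= N / 2)) / (N * dt * .c_cmfs)
  ord <- order(nu)
  list(omega_rel = nu[ord], re = Re(F)[ord])
}

## internal: exciton-basis homogeneous spectrum with per-state weights
.exciton_spectrum <- function(states, g, weights, omega_grid,
                              lifetimes = NULL, prefactor = TRUE) {
  if (length(g$t) < 2L || (g$t[2] - g$t[1]) <= 0)
    stop("lineshape time grid spacing must be positive", call. = FALSE)
  Np <- states$n_sites
  csites <- states$coefs[seq_len(Np), , drop = FALSE]
  shape_factor <- colSums(csites^4)      # sum_i c_ki^4 per state
  ns <- length(states$energies)
  if (is.null(lifetimes)) lifetimes <- rep(Inf, ns)
  ## coverage check: Gaussian-like width from the overdamped part only
  ## (vibrational modes add discrete sidebands, not quasi-static width),
  ## applied to states carrying >= 1% of the largest weight
  lam_env <- if (!is.null(g$sd$lambda_env)) g$sd$lambda_env
    else g$lambda_total
  sigma_est <- sqrt(2 * lam_env * .kB * g$temperature)
  margin <- 5 * 2.355 * max(sigma_est, 1)
  main <- abs(weights) >= 0.01 * max(abs(weights))
  span_lo <- min(states$energies[main], Inf) - margin
  span_hi <- max(states$energies[main], -Inf) + margin
  if (is.finite(span_lo) &&
      (min(omega_grid) > span_lo || max(omega_grid) < span_hi))
    warning("omega grid does not cover state energies +/- 5 FWHM",
            call. = FALSE)
  out <- numeric(length(omega_grid))
  for (k in seq_len(ns)) {
    if (weights[k] == 0) next
    damp <- if (is.finite(lifetimes[k])) g$t / (2 * lifetimes[k]) else 0
    f <- exp(-shape_factor[k] * g$g - damp)
    hf <- .half_fourier(g$t, f)
    sk <- stats::approx(hf$omega_rel + states$energies[k], hf$re,
                        xout = omega_grid, rule = 1)$y
    sk[is.na(sk)] <- 0
    out <- out + weights[k] * sk
  }
  if (prefactor) out <- out * omega_grid
  out
}

#' Homogeneous absorption spectrum in the exciton basis
#'
#' Second-order cumulant absorption for one disorder realization:
#' A(w) is proportional to w * sum_k |mu_k|^2 *
#' Re integral exp(i(w - w_k) t - g_k(t) - t / (2 tau_k)) dt with the
#' exchange-narrowed exciton lineshape g_k(t) = (sum_i c_ki^4) g(t)
#' (all Qy sites share the site spectral density; CT coefficients do not
#' add bath coupling). Lifetime broadening through optional per-state
#' lifetimes (e.g. from [redfield_lifetimes()]).
#'
#' @param states an `exciton_states` carrying dipole strengths.
#' @param g a [lineshape_g()] result.
#' @param omega_grid output frequency grid, cm^-1; should cover the state
#'   energies plus/minus 5 homogeneous FWHM (warning otherwise).
#' @param lifetimes optional per-state lifetimes in fs (Inf = none).
#' @return data.frame with columns `omega` (cm^-1) and `intensity`
#'   (arbitrary units).
#' @export
homogeneous_absorption <- function(states, g, omega_grid,
                                   lifetimes = NULL) {
  if (is.null(states$dipole_strengths))
    stop("states carry no dipole strengths; run state_dipoles() first",
         call. = FALSE)
  data.frame(omega = omega_grid,
             intensity = .exciton_spectrum(states, g,
                                           states$dipole_strengths,
                                           omega_grid, lifetimes))
}

#' Homogeneous circular dichroism spectrum in the exciton basis
#'
#' As [homogeneous_absorption()] with the (signed) rotational strengths
#' R_k in place of the dipole strengths. Because R_k already carries the
#' transition-frequency factor, no additional omega prefactor is applied;
#' this keeps the integrated exciton CD conservative (equal and opposite
#' lobes).
#'
#' @inheritParams homogeneous_absorption
#' @return data.frame with columns `omega` and `intensity` (signed).
#' @export
homogeneous_cd <- function(states, g, omega_grid, lifetimes = NULL) {
  if (is.null(states$rotational_strengths))
    stop("states carry no rotational strengths; run",
         " rotational_strengths() first", call. = FALSE)
  data.frame(omega = omega_grid,
             intensity = .exciton_spectrum(states, g,
                                           states$rotational_strengths,
                                           omega_grid, lifetimes,
                                           prefactor = FALSE))
}

#' Secular Redfield lifetime estimates
#'
#' Population relaxation rates between exciton states from the site
#' spectral density, k(k -> l) = 2 pi c p_kl * 2 J(|D|) * \[n(|D|) + 1\]
#' downhill and 2 pi c p_kl * 2 J(|D|) n(|D|) uphill, with
#' p_kl = sum_i c_ki^2 c_li^2, D = E_k - E_l and n the Bose occupation.
#' The state lifetime is the inverse total outgoing rate, used only for
#' lifetime broadening of the homogeneous lines.
#'
#' @param states an `exciton_states`.
#' @param sd a [spectral_density()].
#' @param temperature K.
#' @return per-state lifetimes in fs (Inf where no decay channel).
#' @export
redfield_lifetimes <- function(states, sd, temperature) {
  E <- states$energies
  ns <- length(E)
  Np <- states$n_sites
  csq <- states$coefs[seq_len(Np), , drop = FALSE]^2
  overlap <- crossprod(csq)              # p_kl
  rates <- matrix(0, ns, ns)
  for (k in seq_len(ns)) for (l in seq_len(ns)) {
    if (k == l) next
    D <- E[k] - E[l]
    aD <- abs(D)
    if (aD < 1e-6) next                  # degenerate: no secular rate
    Jv <- evaluate_spectral_density(sd, aD)
    nB <- 1 / (exp(aD / (.kB * temperature)) - 1)
    occ <- if (D > 0) nB + 1 else nB
    rates[k, l] <- 2 * pi * .c_cmfs * overlap[k, l] * 2 * Jv * occ
  }
  tot <- rowSums(rates)
  ifelse(tot > 0, 1 / tot, Inf)
}
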