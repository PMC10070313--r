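# Physical constants in the package's fixed unit system:
# energies in cm^-1, distances in Angstrom, dipoles in Debye,
# temperatures in K, times in fs.

## Boltzmann constant, cm^-1 / K
.kB <- 0.695034800

## speed of light, cm / fs (converts wavenumber * time to phase: 2*pi*c*nu*t)
.c_cmfs <- 2.99792458e-5

## vacuum dipole-dipole interaction constant, cm^-1 Angstrom^3 / Debye^2.
## V = C * kappa * mu1 * mu2 / R^3, no environment screening.
.dipole_C <- 5034.1

#' Physical constants used by excitonring
#'
#' Returns the constants fixed throughout the package: the Boltzmann
#' constant in cm^-1/K, the speed of light in cm/fs, and the vacuum
#' dipole-dipole coupling constant in cm^-1 A^3 D^-2. Units are never
#' configurable (cm^-1, Angstrom, Debye, K, fs everywhere) to avoid
#' silent unit errors.
#'
#' @return Named list with elements `kB_cm1_per_K`, `c_cm_per_fs`,
#'   `dipole_coupling_C`.
#' @export
exciton_constants <- function() {
  list(kB_cm1_per_K = .kB,
       c_cm_per_fs = .c_cmfs,
       dipole_coupling_C = .dipole_C)
}

## internal: stop unless all values finite, naming the offending field
.check_finite <- function(x, field) {
  if (!all(is.finite(x)))
    stop("non-finite value in '", field, "'", call. = FALSE)
  invisible(x)
}
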