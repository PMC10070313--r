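## Packaged parameter bundles: named site energies, couplings and ring
## topology for LH2 variants, with per-value provenance flags separating
## transcribed published values from package defaults.

.required_couplings <- c("intra_dimer", "inter_dimer", "alpha_alpha",
                         "beta_beta", "b800_b800", "inter_ring")

## internal: pull {value, provenance} nodes into a value vector + flags
.unpack_values <- function(node, section) {
  vals <- list(); prov <- character()
  for (key in names(node)) {
    entry <- node[[key]]
    if (is.list(entry) && !is.null(entry$value)) {
      vals[[key]] <- entry$value
      prov[paste(section, key, sep = ".")] <-
        if (is.null(entry$provenance)) "default" else entry$provenance
    } else if (key != "provenance") {
      vals[[key]] <- entry
      prov[paste(section, key, sep = ".")] <- "default"
    }
  }
  list(values = vals, provenance = prov)
}

#' Load a parameter bundle
#'
#' Bundles carry the average site energies (cm^-1) of the alpha, beta and
#' B800 bacteriochlorophyll classes, the named excitonic couplings
#' (intra-/inter-dimer alpha-beta, alpha-alpha, beta-beta, B800-B800,
#' inter-ring), ring topology, CT-state parameters and disorder defaults.
#' Each value is flagged `published` (transcribed published value) or
#' `default` (package placeholder for unprinted/supplementary data); the
#' flags are surfaced in run manifests.
#'
#' @param name a packaged bundle name (`"LH2purp"`, `"LH2acid"`) or a path
#'   to a bundle YAML file.
#' @return object of class `parameter_bundle`.
#' @export
load_bundle <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "bundles", paste0(name, ".yaml"),
                package = "excitonring")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown bundle '", name, "'", call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (sec in c("ring", "site_energies", "couplings"))
    if (is.null(raw[[sec]]))
      stop("bundle file malformed: missing section '", sec, "'",
           call. = FALSE)
  ring <- .unpack_values(raw$ring, "ring")
  sites <- .unpack_values(raw$site_energies, "site_energies")
  coups <- .unpack_values(raw$couplings, "couplings")
  missing_c <- setdiff(.required_couplings, names(coups$values))
  if (length(missing_c))
    stop("bundle missing required coupling(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  missing_s <- setdiff(c("alpha", "beta", "B800"), names(sites$values))
  if (length(missing_s))
    stop("bundle missing site energy class(es): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  ct <- if (!is.null(raw$ct)) .unpack_values(raw$ct, "ct") else NULL
  dis <- raw$disorder
  prov <- c(ring$provenance, sites$provenance, coups$provenance,
            if (!is.null(ct)) ct$provenance)
  structure(list(name = raw$name,
                 n_units = as.integer(ring$values$n_units),
                 ring = ring$values,
                 site_energies = unlist(sites$values),
                 couplings = unlist(coups$values),
                 ct = if (is.null(ct)) NULL else unlist(ct$values),
                 disorder = dis,
                 provenance = data.frame(parameter = names(prov),
                                         provenance = unname(prov)),
                 path = path),
            class = "parameter_bundle")
}

#' @export
print.parameter_bundle <- function(x, ...) {
  cat("parameter_bundle:", x$name, "-", x$n_units, "repeating units\n")
  cat("site energies (cm^-1):",
      paste(names(x$site_energies), x$site_energies, sep = "=",
            collapse = ", "), "\n")
  cat("couplings (cm^-1):",
      paste(names(x$couplings), x$couplings, sep = "=",
            collapse = ", "), "\n")
  ndef <- sum(x$provenance$provenance != "published")
  cat(ndef, "parameter(s) are package defaults (see $provenance)\n")
  invisible(x)
}

#' Idealized ring geometry from a bundle
#'
#' Builds the Cn-symmetric pigment geometry a bundle describes. The B850
#' ring holds an alpha/beta pigment pair per unit with nearly tangential,
#' alternating transition dipoles (a small out-of-plane tilt provides the
#' chirality seen in CD); the B800 ring holds one in-plane pigment per
#' unit on a wider circle below the B850 plane. For `ring = "full"` the
#' B850 sites come first (ring-ordered) followed by the B800 sites, the
#' site order used by [average_hamiltonian()].
#'
#' @param bundle a [load_bundle()] result.
#' @param ring `"full"`, `"B850"` or `"B800"`.
#' @return a `ring_geometry`.
#' @export
bundle_geometry <- function(bundle, ring = c("full", "B850", "B800")) {
  ring <- match.arg(ring)
  rp <- bundle$ring
  n <- bundle$n_units
  tilt <- rp$dipole_tilt
  mag <- rp$dipole_magnitude
  b850_spec <- data.frame(
    radial = 0, angle = c(0, rp$beta_angle_offset), axial = 0,
    theta = c(pi / 2 - tilt, pi / 2 + tilt),
    psi = c(pi / 2, 3 * pi / 2),
    mag = mag, class = c("alpha", "beta"))
  b800_spec <- data.frame(
    radial = 0, angle = 0, axial = rp$b800_z,
    theta = pi / 2, psi = rp$b800_psi, mag = mag, class = "B800")
  b850 <- build_ideal_ring(n, b850_spec, rp$b850_radius)
  b800 <- build_ideal_ring(n, b800_spec, rp$b800_radius)
  if (ring == "B850") return(b850)
  if (ring == "B800") return(b800)
  ring_geometry(rbind(b850$centers, b800$centers),
                rbind(b850$dipole_axes, b800$dipole_axes),
                c(b850$dipole_magnitudes, b800$dipole_magnitudes),
                c(b850$classes, b800$classes),
                c(b850$units, b800$units), n,
                labels = c(b850$labels, b800$labels))
}

## internal: B850 coupling matrix for alternating alpha,beta ring order.
## Nearest-neighbor couplings are positive in the alternating-dipole gauge
## (bright k = +/-1 pair near the bottom of the exciton band); the weaker
## second-neighbor alpha-alpha / beta-beta couplings are signed as given.
.b850_couplings <- function(n, cp) {
  N <- 2L * n
  V <- matrix(0, N, N)
  a <- function(u) 2L * ((u - 1L) %% n) + 1L   # alpha site of unit u
  b <- function(u) 2L * ((u - 1L) %% n) + 2L
  for (u in seq_len(n)) {
    V[a(u), b(u)] <- V[b(u), a(u)] <- cp[["intra_dimer"]]
    V[b(u), a(u + 1L)] <- V[a(u + 1L), b(u)] <- cp[["inter_dimer"]]
    V[a(u), a(u + 1L)] <- V[a(u + 1L), a(u)] <- cp[["alpha_alpha"]]
    V[b(u), b(u + 1L)] <- V[b(u + 1L), b(u)] <- cp[["beta_beta"]]
  }
  V
}

#' Average exciton Hamiltonian of a bundle
#'
#' Assembles the disorder-free Hamiltonian at the bundle's class-mean site
#' energies and named couplings. Site order: alpha1, beta1, alpha2, ...
#' around the B850 ring, then B800 sites; for `ring = "B850"` or
#' `"B800"` only that sub-ring is built.
#'
#' @param bundle a [load_bundle()] result.
#' @param ring `"full"`, `"B850"` or `"B800"`.
#' @param ct include the bundle's CT manifold (B850 adjacent pairs);
#'   requires CT parameters in the bundle.
#' @return an `augmented_hamiltonian`.
#' @export
average_hamiltonian <- function(bundle, ring = c("full", "B850", "B800"),
                                ct = FALSE) {
  ring <- match.arg(ring)
  n <- bundle$n_units
  cp <- bundle$couplings
  se <- bundle$site_energies
  if (ring == "B800") {
    N <- n
    V <- matrix(0, N, N)
    for (u in seq_len(n)) {
      v <- u %% n + 1L
      V[u, v] <- V[v, u] <- cp[["b800_b800"]]
    }
    sb <- site_basis(rep(se[["B800"]], N), rep("B800", N))
    return(assemble_hamiltonian(sb, V))
  }
  Vb850 <- .b850_couplings(n, cp)
  e850 <- rep(c(se[["alpha"]], se[["beta"]]), n)
  cls850 <- rep(c("alpha", "beta"), n)
  ctm <- NULL
  if (ct) {
    if (is.null(bundle$ct))
      stop("bundle '", bundle$name, "' has no CT parameters",
           call. = FALSE)
    ctm <- bundle_ct_manifold(bundle)
  }
  if (ring == "B850") {
    sb <- site_basis(e850, cls850)
    return(assemble_hamiltonian(sb, Vb850, ctm))
  }
  N <- 3L * n
  V <- matrix(0, N, N)
  V[seq_len(2L * n), seq_len(2L * n)] <- Vb850
  for (u in seq_len(n)) {
    v <- u %% n + 1L
    i8 <- 2L * n + u
    V[i8, 2L * n + v] <- V[2L * n + v, i8] <- cp[["b800_b800"]]
    ## inter-ring: each B800 couples to the alpha/beta pair of its unit
    V[i8, 2L * (u - 1L) + 1L] <- V[2L * (u - 1L) + 1L, i8] <-
      cp[["inter_ring"]]
    V[i8, 2L * (u - 1L) + 2L] <- V[2L * (u - 1L) + 2L, i8] <-
      cp[["inter_ring"]]
  }
  sb <- site_basis(c(e850, rep(se[["B800"]], n)),
                   c(cls850, rep("B800", n)))
  if (!is.null(ctm) && nrow(ctm$couplings) == 2L * n) {
    ## pad CT coupling rows for the B800 sites (zero CT coupling)
    ctm <- ct_manifold(ctm$energies, ctm$pairs,
                       rbind(ctm$couplings,
                             matrix(0, n, length(ctm$energies))))
  }
  assemble_hamiltonian(sb, V, ctm)
}

#' CT manifold of a bundle
#'
#' One CT state per adjacent B850 pigment pair: intra-dimer pairs at
#' `energy_intra` coupled by `coupling_intra` to both pair sites, and
#' inter-dimer pairs at `energy_inter` coupled by `coupling_inter`. Site
#' indices refer to the B850 ring order (alpha1, beta1, alpha2, ...).
#'
#' @param bundle a [load_bundle()] result with CT parameters.
#' @param scale multiplier applied to all CT couplings (0 switches the CT
#'   interaction off while keeping the states).
#' @return a [ct_manifold()].
#' @export
bundle_ct_manifold <- function(bundle, scale = 1) {
  if (is.null(bundle$ct))
    stop("bundle '", bundle$name, "' has no CT parameters", call. = FALSE)
  n <- bundle$n_units
  ctp <- bundle$ct
  Np <- 2L * n
  M <- 2L * n
  energies <- numeric(M); pairs <- matrix(0L, M, 2)
  couplings <- matrix(0, Np, M)
  for (u in seq_len(n)) {
    ia <- 2L * (u - 1L) + 1L; ib <- ia + 1L
    ia_next <- 2L * (u %% n) + 1L
    ## sign pattern (+, -) on the pair: in the alternating-dipole gauge
    ## of the B850 basis this couples the CT state to the antisymmetric
    ## pair combination carried by the low-energy (bright) exciton band
    m1 <- 2L * (u - 1L) + 1L               # intra-dimer CT
    energies[m1] <- ctp[["energy_intra"]]
    pairs[m1, ] <- c(ia, ib)
    couplings[ia, m1] <- scale * ctp[["coupling_intra"]]
    couplings[ib, m1] <- -scale * ctp[["coupling_intra"]]
    m2 <- m1 + 1L                          # inter-dimer CT
    energies[m2] <- ctp[["energy_inter"]]
    pairs[m2, ] <- c(ib, ia_next)
    couplings[ib, m2] <- scale * ctp[["coupling_inter"]]
    couplings[ia_next, m2] <- -scale * ctp[["coupling_inter"]]
  }
  ct_manifold(energies, pairs, couplings)
}

#' Bundle disorder model
#'
#' Builds a [disorder_model()] from a bundle's disorder section.
#'
#' @param bundle a [load_bundle()] result.
#' @param seed RNG seed.
#' @param use_additional use `sigma_add` (TRUE) or zero additional
#'   disorder.
#' @return a `disorder_model`.
#' @export
bundle_disorder_model <- function(bundle, seed = 1L,
                                  use_additional = TRUE) {
  d <- bundle$disorder
  pick <- function(node) {
    v <- unlist(node[setdiff(names(node), "provenance")])
    v[c("alpha", "beta", "B800")]
  }
  disorder_model(
    sigma_static = pick(d$sigma_static),
    sigma_add = if (use_additional) pick(d$sigma_add)
      else c(alpha = 0, beta = 0, B800 = 0),
    sigma_coupling = d$sigma_coupling$value,
    seed = seed)
}
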