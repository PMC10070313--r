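## Static-disorder machinery: the Eq.-style environment/vacuum split of
## site energies, Gaussian diagonal disorder, and MD-like synthetic
## Hamiltonian ensembles standing in for per-frame QM/MM output.

## internal: run expr with a fixed RNG seed, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-frame site-energy record (environment/vacuum decomposition)
#'
#' Holds site energies computed for one or more frames both in the protein
#' environment (`E_env`) and in vacuum (`E_vac`), together with the
#' per-class vacuum average used to remove intramolecular (dynamic)
#' fluctuations from the static-disorder coordinate.
#'
#' @param E_env,E_vac numeric vectors or matrices (frames x sites), cm^-1.
#' @param classes per-site class labels.
#' @param mean_vac named per-class vacuum averages; by default computed
#'   from `E_vac` over all sites of each class (symmetry-equivalent
#'   pigments pooled).
#' @return object of class `disorder_record`.
#' @export
disorder_record <- function(E_env, E_vac, classes, mean_vac = NULL) {
  E_env <- rbind(E_env); E_vac <- rbind(E_vac)
  .check_finite(E_env, "E_env"); .check_finite(E_vac, "E_vac")
  if (!identical(dim(E_env), dim(E_vac)))
    stop("E_env and E_vac dimensions differ", call. = FALSE)
  if (length(classes) != ncol(E_env))
    stop("classes length must match site count", call. = FALSE)
  if (is.null(mean_vac)) {
    mean_vac <- vapply(split(as.numeric(E_vac),
                             rep(classes, each = nrow(E_vac))),
                       mean, numeric(1))
  }
  structure(list(E_env = E_env, E_vac = E_vac,
                 classes = as.character(classes), mean_vac = mean_vac),
            class = "disorder_record")
}

#' Static site energies from the environment/vacuum decomposition
#'
#' E_static = E_env - E_vac + <E_vac>_class: the environment effect is
#' attributed to static disorder while intramolecular fluctuations are
#' removed. Over an ensemble, E_static keeps the mean of E_env and the
#' standard deviation of E_env - E_vac.
#'
#' @param record a [disorder_record()].
#' @return matrix (frames x sites) of static site energies, cm^-1.
#' @export
static_site_energy <- function(record) {
  miss <- setdiff(unique(record$classes), names(record$mean_vac))
  if (length(miss))
    stop("no vacuum class mean for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  shift <- record$mean_vac[record$classes]
  out <- record$E_env - record$E_vac +
    matrix(shift, nrow(record$E_env), ncol(record$E_env), byrow = TRUE)
  dimnames(out) <- dimnames(record$E_env)
  out
}

#' Gaussian disorder model
#'
#' @param sigma_static named per-class standard deviations (cm^-1) of the
#'   frame-to-frame (environmental) site-energy disorder.
#' @param sigma_add named per-class standard deviations of the additional
#'   diagonal disorder layered on each frame.
#' @param sigma_coupling standard deviation (cm^-1) of coupling
#'   fluctuations, applied to nonzero couplings.
#' @param seed integer RNG seed; mandatory for reproducible ensembles.
#' @param correlation optional site-site correlation matrix for the
#'   static energies (default independent sites).
#' @return object of class `disorder_model`.
#' @export
disorder_model <- function(sigma_static = c(alpha = 0, beta = 0, B800 = 0),
                           sigma_add = c(alpha = 0, beta = 0, B800 = 0),
                           sigma_coupling = 0, seed = 1L,
                           correlation = NULL) {
  if (any(sigma_static < 0) || any(sigma_add < 0) || sigma_coupling < 0)
    stop("disorder standard deviations must be >= 0", call. = FALSE)
  structure(list(sigma_static = sigma_static, sigma_add = sigma_add,
                 sigma_coupling = sigma_coupling, seed = as.integer(seed),
                 correlation = correlation),
            class = "disorder_model")
}

#' Ensemble of exciton Hamiltonian realizations
#'
#' @param hamiltonians list of `augmented_hamiltonian` objects sharing
#'   dimensions and labels.
#' @param model the generating [disorder_model()] (provenance), or NULL.
#' @param seed the seed used (provenance), or NA.
#' @return object of class `hamiltonian_ensemble`.
#' @export
hamiltonian_ensemble <- function(hamiltonians, model = NULL, seed = NA) {
  if (!length(hamiltonians)) stop("empty ensemble", call. = FALSE)
  dims <- vapply(hamiltonians, function(h) c(h$n_sites, h$n_ct),
                 integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ensemble realizations differ in dimension", call. = FALSE)
  structure(list(hamiltonians = hamiltonians, model = model, seed = seed),
            class = "hamiltonian_ensemble")
}

#' @export
print.hamiltonian_ensemble <- function(x, ...) {
  cat("hamiltonian_ensemble:", length(x$hamiltonians), "realizations,",
      x$hamiltonians[[1]]$n_sites, "Qy sites,",
      x$hamiltonians[[1]]$n_ct, "CT states\n")
  invisible(x)
}

#' @export
length.hamiltonian_ensemble <- function(x) length(x$hamiltonians)

## internal: draw one site-energy perturbation vector given per-class sigma
.site_noise <- function(classes, sigma, correlation = NULL) {
  miss <- setdiff(unique(classes), names(sigma))
  if (length(miss))
    stop("no disorder sigma for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  s <- as.numeric(sigma[classes])
  z <- stats::rnorm(length(classes))
  if (!is.null(correlation)) {
    L <- chol(correlation)
    z <- as.numeric(t(L) %*% z)
  }
  s * z
}

#' Sample additional diagonal-disorder realizations
#'
#' Layers i.i.d. Gaussian perturbations (per-class sigma_add) on the site
#' energies of each base Hamiltonian; couplings and CT blocks are left
#' untouched. For a base ensemble of F frames, returns F x n realizations
#' (n per frame). Fully reproducible from the model's seed.
#'
#' @param base an `augmented_hamiltonian` or `hamiltonian_ensemble`.
#' @param model a [disorder_model()]; only `sigma_add`, `correlation` and
#'   `seed` are used.
#' @param n realizations per base frame, >= 1.
#' @return a `hamiltonian_ensemble`.
#' @export
sample_realizations <- function(base, model, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  frames <- if (inherits(base, "hamiltonian_ensemble")) base$hamiltonians
    else list(base)
  .with_seed(model$seed, {
    out <- vector("list", length(frames) * n)
    k <- 1L
    for (h in frames) {
      for (r in seq_len(n)) {
        hh <- h
        noise <- .site_noise(h$classes, model$sigma_add,
                             model$correlation)
        ix <- seq_len(h$n_sites)
        diag(hh$matrix)[ix] <- diag(h$matrix)[ix] + noise
        out[[k]] <- hh
        k <- k + 1L
      }
    }
    hamiltonian_ensemble(out, model = model, seed = model$seed)
  })
}

#' Synthesize an MD-like Hamiltonian ensemble
#'
#' Generates per-frame Hamiltonians emulating the statistical structure of
#' frame-by-frame QM/MM output: site energies drawn as
#' Normal(class mean, sigma_static(class)) and couplings as the base
#' coupling matrix plus Normal(0, sigma_coupling) on nonzero entries
#' (symmetrically). The CT manifold, when given, is copied unchanged into
#' every frame.
#'
#' @param geometry a `ring_geometry` providing classes and site order.
#' @param class_means named per-class mean site energies, cm^-1.
#' @param model a [disorder_model()].
#' @param n_frames number of frames, >= 1.
#' @param couplings base N x N coupling matrix; default point-dipole
#'   couplings from the geometry.
#' @param ct optional [ct_manifold()] included in every frame.
#' @return a `hamiltonian_ensemble`.
#' @export
synthesize_md_like_ensemble <- function(geometry, class_means, model,
                                        n_frames, couplings = NULL,
                                        ct = NULL) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  classes <- geometry$classes
  miss <- setdiff(unique(classes), names(class_means))
  if (length(miss))
    stop("no class mean for class(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(couplings)) {
    couplings <- matrix(0, n_pigments(geometry), n_pigments(geometry))
    tab <- pair_geometry_table(geometry)
    couplings[cbind(tab$i, tab$j)] <- tab$coupling_cm1
    couplings <- couplings + t(couplings)
  }
  couplings <- coupling_matrix(couplings)
  mask <- couplings != 0
  mask[lower.tri(mask, diag = TRUE)] <- FALSE
  means <- as.numeric(class_means[classes])
  .with_seed(model$seed, {
    out <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      e <- means + .site_noise(classes, model$sigma_static,
                               model$correlation)
      V <- couplings
      if (model$sigma_coupling > 0 && any(mask)) {
        dV <- stats::rnorm(sum(mask), 0, model$sigma_coupling)
        V[mask] <- V[mask] + dV
        V[lower.tri(V)] <- t(V)[lower.tri(V)]
      }
      out[[f]] <- assemble_hamiltonian(
        site_basis(e, classes, geometry$labels), V, ct)
    }
    hamiltonian_ensemble(out, model = model, seed = model$seed)
  })
}

#' Estimate disorder parameters from an ensemble
#'
#' Unbiased per-class sample mean and standard deviation of site energies,
#' and per-pair mean and standard deviation of couplings (pairs whose
#' coupling is nonzero in any realization).
#'
#' @param ensemble a `hamiltonian_ensemble` with >= 2 realizations.
#' @return list with data.frames `sites` (class, mean, sd) and `couplings`
#'   (i, j, mean, sd).
#' @export
estimate_disorder <- function(ensemble) {
  hs <- ensemble$hamiltonians
  if (length(hs) < 2L)
    stop("need at least 2 realizations to estimate disorder",
         call. = FALSE)
  Np <- hs[[1]]$n_sites
  E <- t(vapply(hs, function(h) diag(h$matrix)[seq_len(Np)], numeric(Np)))
  classes <- hs[[1]]$classes
  sites <- do.call(rbind, lapply(unique(classes), function(cl) {
    vals <- as.numeric(E[, classes == cl])
    data.frame(class = cl, mean = mean(vals), sd = stats::sd(vals))
  }))
  Vsum <- matrix(0, Np, Np); Vsq <- matrix(0, Np, Np)
  nz <- matrix(FALSE, Np, Np)
  for (h in hs) {
    V <- h$matrix[seq_len(Np), seq_len(Np)]
    diag(V) <- 0
    Vsum <- Vsum + V; Vsq <- Vsq + V^2
    nz <- nz | (V != 0)
  }
  F <- length(hs)
  mu <- Vsum / F
  sdv <- sqrt(pmax((Vsq - F * mu^2) / (F - 1), 0))
  ij <- which(nz & upper.tri(nz), arr.ind = TRUE)
  couplings <- data.frame(i = ij[, 1], j = ij[, 2],
                          mean = mu[ij], sd = sdv[ij])
  list(sites = sites, couplings = couplings)
}
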