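## Plain-text serialization: Hamiltonians, state tables, spectra,
## ensembles, run configs and run manifests. All files are tab- or
## whitespace-separated text; manifests make runs reproducible.

#' Write an exciton Hamiltonian as plain text
#'
#' Header lines give the Qy/CT dimensions and basis labels, followed by
#' whitespace-separated matrix rows (cm^-1, full precision).
#'
#' @param H an `augmented_hamiltonian`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hamiltonian <- function(H, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# excitonring hamiltonian",
               paste("N_p", H$n_sites, "N_CT", H$n_ct),
               paste("classes", paste(H$classes, collapse = " ")),
               paste("labels", paste(H$labels, collapse = " "))), con)
  utils::write.table(format(H$matrix, digits = 17, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an exciton Hamiltonian written by [write_hamiltonian()]
#'
#' @param path file path.
#' @return an `augmented_hamiltonian`.
#' @export
read_hamiltonian <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "# excitonring hamiltonian")
    stop("not an excitonring hamiltonian file: ", path, call. = FALSE)
  hdr <- strsplit(lines[2], "\\s+")[[1]]
  Np <- as.integer(hdr[2]); Nct <- as.integer(hdr[4])
  classes <- strsplit(lines[3], "\\s+")[[1]][-1]
  labels <- strsplit(lines[4], "\\s+")[[1]][-1]
  N <- Np + Nct
  M <- as.matrix(utils::read.table(text = lines[5:(4 + N)]))
  dimnames(M) <- NULL
  structure(list(matrix = M, n_sites = Np, n_ct = Nct,
                 classes = classes, labels = labels),
            class = "augmented_hamiltonian")
}

#' Write a per-state observables table
#'
#' Tab-separated table of energy, dipole strength, rotational strength,
#' k label and inverse participation ratio (fields present only if
#' computed).
#'
#' @param states an `exciton_states`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  df <- data.frame(state = seq_along(states$energies),
                   energy_cm1 = states$energies)
  if (!is.null(states$dipole_strengths))
    df$dipole_strength_D2 <- states$dipole_strengths
  if (!is.null(states$rotational_strengths))
    df$rotational_strength <- states$rotational_strengths
  if (!is.null(states$k_labels)) df$k <- states$k_labels
  df$ipr <- 1 / colSums(states$coefs^4)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a Hamiltonian ensemble to a directory
#'
#' Writes one matrix file per realization plus a YAML manifest recording
#' the seed and disorder-model parameters; the manifest alone suffices to
#' regenerate a bitwise-identical ensemble with the generating function.
#'
#' @param ensemble a `hamiltonian_ensemble`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- max(4L, nchar(length(ensemble$hamiltonians)))
  for (i in seq_along(ensemble$hamiltonians))
    write_hamiltonian(ensemble$hamiltonians[[i]],
                      file.path(dir, sprintf(paste0("H%0", nd, "d.txt"),
                                             i)))
  model <- ensemble$model
  manifest <- list(
    n_realizations = length(ensemble$hamiltonians),
    seed = if (is.null(ensemble$seed)) NA else ensemble$seed,
    model = if (is.null(model)) NULL else
      list(sigma_static = as.list(model$sigma_static),
           sigma_add = as.list(model$sigma_add),
           sigma_coupling = model$sigma_coupling,
           seed = model$seed))
  mf <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  invisible(mf)
}

#' Load a Hamiltonian ensemble written by [save_ensemble()]
#'
#' @param dir ensemble directory.
#' @return a `hamiltonian_ensemble`.
#' @export
load_ensemble <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", dir, call. = FALSE)
  man <- yaml::read_yaml(mf)
  files <- sort(list.files(dir, pattern = "^H\\d+\\.txt$",
                           full.names = TRUE))
  hs <- lapply(files, read_hamiltonian)
  model <- if (!is.null(man$model))
    disorder_model(sigma_static = unlist(man$model$sigma_static),
                   sigma_add = unlist(man$model$sigma_add),
                   sigma_coupling = man$model$sigma_coupling,
                   seed = man$model$seed)
  hamiltonian_ensemble(hs, model = model, seed = man$seed)
}

#' Read a declarative run configuration
#'
#' YAML with keys `bundle` (name or path), optional `geometry` (ideal-ring
#' parameters or a PDB path), `disorder`, `lineshape`, `global_shift`,
#' `seed`, `output_dir`. A seed is mandatory whenever disorder is
#' requested.
#'
#' @param path YAML file.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$bundle))
    stop("config must name a parameter bundle", call. = FALSE)
  wants_disorder <- !is.null(cfg$disorder) &&
    !isTRUE(cfg$disorder$disabled)
  if (wants_disorder && is.null(cfg$seed))
    stop("config requests disorder but gives no seed", call. = FALSE)
  if (!is.null(cfg$geometry$pdb) && !file.exists(cfg$geometry$pdb))
    stop("geometry PDB path does not exist: ", cfg$geometry$pdb,
         call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Write spectra and a reproducibility manifest
#'
#' Writes `absorption.tsv` and `cd.tsv` (two-column, cm^-1 and normalized
#' intensity), a `summary.tsv` of band peaks when windows are given, and
#' `manifest.txt` recording the seed, global shift, realization count and
#' an MD5 hash of the configuration; reruns with the same config and seed
#' reproduce all files bitwise.
#'
#' @param result a `spectrum_result`.
#' @param outdir output directory (created if needed).
#' @param config optional configuration list echoed (YAML) into the
#'   manifest hash.
#' @param windows optional named band windows for the peak summary.
#' @return the manifest path, invisibly.
#' @export
write_outputs <- function(result, outdir, config = NULL, windows = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ",
                                outdir, call. = FALSE)
  wr <- function(x, y, f)
    utils::write.table(data.frame(omega_cm1 = x, intensity = y),
                       file.path(outdir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wr(result$omega, result$absorption, "absorption.tsv")
  wr(result$omega, result$cd, "cd.tsv")
  if (!is.null(windows)) {
    pk <- peak_positions(result, windows)
    utils::write.table(pk, file.path(outdir, "summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tf <- tempfile()
    yaml::write_yaml(config, tf)
    cfg_hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  manifest <- c(
    "# excitonring run manifest",
    paste("global_shift_cm1:", result$global_shift),
    paste("n_realizations:", result$n_realizations),
    paste("seed:", if (is.null(result$provenance$seed)) NA
          else result$provenance$seed),
    paste("config_md5:", cfg_hash))
  mf <- file.path(outdir, "manifest.txt")
  writeLines(manifest, mf)
  invisible(mf)
}

#' Write a pair-geometry table as tab-separated text
#'
#' @param table data.frame from [pair_geometry_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geometry_table <- function(table, path) {
  utils::write.table(table[, c("pair", "distance_A", "kappa",
                               "coupling_cm1")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
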