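# Configuration parsing (YAML), log serialization, and STRUCTURE-format
# genotype export with patch-stratified resampling.

config_top_keys <- c(
  "dispersal", "selection", "gap_permeability", "horizon", "epochs",
  "gap_edges", "autocorrelation", "habitat_A", "habitat_B",
  "snapshot_steps", "allele_log_every", "replicates", "base_seed",
  "demography", "loci", "patches"
)

#' Read a simulation configuration from a YAML file
#'
#' Unspecified keys fall back to the built-in default scenario; an empty file
#' yields the full default configuration. Unknown keys are rejected with
#' their key paths.
#'
#' @param path Path to a YAML configuration file.
#' @return A `hexpop_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  bad <- setdiff(names(y), config_top_keys)
  if (length(bad)) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(bad, collapse = ", ")))
  }
  args <- list()
  scalar <- c("selection", "gap_permeability", "horizon", "gap_edges",
              "autocorrelation", "allele_log_every", "replicates", "base_seed")
  for (k in scalar) if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  for (k in c("habitat_A", "habitat_B", "snapshot_steps")) {
    if (!is.null(y[[k]])) args[[k]] <- as.integer(unlist(y[[k]]))
  }
  if (!is.null(y$dispersal)) {
    args$dispersal <- if (is.character(y$dispersal)) y$dispersal
                      else as.integer(unlist(y$dispersal))
  }
  if (!is.null(y$demography)) {
    dm <- y$demography
    bad <- setdiff(names(dm), names(formals(demography_params)))
    if (length(bad)) {
      abort(paste0("Unknown configuration key(s): ",
                   paste0("demography.", bad, collapse = ", ")))
    }
    args$demography <- do.call(demography_params, dm)
  }
  for (k in c("epochs", "loci", "patches")) {
    if (!is.null(y[[k]])) args[[k]] <- dplyr::bind_rows(lapply(y[[k]], as_tibble))
  }
  do.call(sim_config, args)
}

#' Write a simulation configuration to YAML
#'
#' @param config A `hexpop_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  y <- list(
    dispersal = as.integer(config$dispersal$range),
    autocorrelation = config$dispersal$autocorrelation,
    selection = config$selection,
    gap_permeability = config$gap_permeability,
    horizon = config$horizon,
    gap_edges = config$gap_edges,
    habitat_A = as.integer(config$habitat_A),
    habitat_B = as.integer(config$habitat_B),
    snapshot_steps = config$snapshot_steps,
    allele_log_every = config$allele_log_every,
    replicates = config$replicates,
    base_seed = config$base_seed,
    demography = unclass(config$demography),
    epochs = purrr::transpose(as.list(config$epochs)),
    loci = purrr::transpose(as.list(config$loci)),
    patches = purrr::transpose(as.list(config$patches))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Export a genotype snapshot in STRUCTURE format
#'
#' Writes one row per individual (individual id, population label, then two
#' integer allele columns per locus; no header) or the two-row dialect.
#' Patches holding fewer than `per_patch_n` individuals are topped up by
#' resampling with replacement until the quota is met; extinct patches are
#' skipped with a warning.
#'
#' @param snapshot A snapshot from [get_snapshot()].
#' @param path Output file path.
#' @param per_patch_n Individuals per patch (default 25).
#' @param missing_code Missing-data code (default -9; unused by complete
#'   snapshots but part of the dialect).
#' @param two_row Write two rows per individual (one allele column per locus)
#'   instead of the default one-row format.
#' @return Invisibly, the tibble of exported rows (id, patch).
#' @export
export_structure <- function(snapshot, path, per_patch_n = 25,
                             missing_code = -9, two_row = FALSE) {
  if (per_patch_n < 1) abort("`per_patch_n` must be >= 1.")
  patches <- sort(unique(snapshot$patch))
  if (!length(snapshot$id)) abort("Snapshot holds no individuals.")
  picks <- integer(0)
  for (p in patches) {
    in_p <- which(snapshot$patch == p)
    if (!length(in_p)) next
    take <- if (length(in_p) >= per_patch_n) {
      sample(in_p, per_patch_n)
    } else {
      c(in_p, sample(in_p, per_patch_n - length(in_p), replace = TRUE))
    }
    picks <- c(picks, take)
  }
  skipped <- setdiff(seq_len(max(snapshot$patch)), patches)
  if (length(skipped)) {
    warn(paste0("Patch(es) with zero individuals skipped: ",
                paste(skipped, collapse = ", ")))
  }
  g <- snapshot$geno[picks, , drop = FALSE]
  g[is.na(g)] <- as.integer(missing_code)
  ids <- snapshot$id[picks]
  pops <- snapshot$patch[picks]
  if (two_row) {
    nl <- ncol(g) %/% 2L
    a <- g[, 2L * seq_len(nl) - 1L, drop = FALSE]
    b <- g[, 2L * seq_len(nl), drop = FALSE]
    out <- matrix(0L, 2L * nrow(g), nl)
    out[seq(1, 2 * nrow(g), by = 2), ] <- a
    out[seq(2, 2 * nrow(g), by = 2), ] <- b
    df <- data.frame(id = rep(ids, each = 2), pop = rep(pops, each = 2), out)
  } else {
    df <- data.frame(id = ids, pop = pops, g)
  }
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(tibble(id = ids, patch = pops))
}

#' Write simulation logs as tidy CSV files
#'
#' One CSV per metric family with deterministic column order and formatting,
#' plus a JSON manifest recording the seed, step count, configuration hash,
#' and file list. Two runs of the same (config, seed) produce byte-identical
#' outputs.
#'
#' @param sim A `hexpop_sim`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_metrics <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    census = sim$census,
    events = sim$events,
    demography = sim$demography,
    first_breeding = sim$first_breeding,
    dispersal_kernels = sim$kernels,
    allele_counts = sim$allele_counts
  )
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE, quote = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(
    seed = sim$seed,
    steps = sim$steps,
    config_hash = rlang::hash(sim$config),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Serialize a landscape as CSV
#'
#' Writes the cell table (axial and offset coordinates, patch, habitat type)
#' and the inter-patch edge overrides (permeability and gap flags) for the
#' landscape's current epoch.
#'
#' @param landscape A `hexpop_landscape`.
#' @param out_dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_landscape <- function(landscape, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- landscape$cells
  cells$habitat_type <- c("none", "A", "B")[landscape$habitat + 1L]
  fc <- file.path(out_dir, "cells.csv")
  utils::write.csv(cells, fc, row.names = FALSE, quote = FALSE)
  ip <- landscape$interpatch
  ip$permeability <- landscape$perm[cbind(ip$from, ip$dir)]
  fe <- file.path(out_dir, "edges.csv")
  utils::write.csv(ip[c("from", "to", "patch_from", "patch_to", "iface",
                        "is_gap", "permeability")],
                   fe, row.names = FALSE, quote = FALSE)
  invisible(c(fc, fe))
}
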