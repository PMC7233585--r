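# End-to-end orchestration of the synthetic preset / user inputs:
# structures -> energetics -> frustration -> profiles -> clustering
# (plus evolutionary trace when an alignment is available), with a
# deterministic run manifest.

#' Assemble a pipeline configuration
#'
#' All thresholds and generator settings in one place; every default is
#' recorded in the run manifest so divergences are auditable.
#'
#' @param out_dir Output directory (created; refuses to overwrite files).
#' @param seed Integer seed passed to every synthetic generator.
#' @param pdb Optional path to a complex PDB; `NULL` generates the synthetic
#'   complex preset.
#' @param ligand_chain Ligand chain identifier (default "C").
#' @param receptor_chain Receptor chain identifier (default "A").
#' @param groove_positions Groove positions for the synthetic complex.
#' @param receptor_length Receptor length for the synthetic complex.
#' @param params An [energy_params()] object.
#' @param cutoff,min_seq_sep Contact-map settings.
#' @param neutral_band Length-2 numeric, frustration classification band.
#' @param variation_threshold Minimum per-position SRFI variation.
#' @param cluster_k Number of clusters to extract.
#' @param srfi_matrix_file Optional precomputed SRFI matrix TSV; `NULL`
#'   generates the planted-group synthetic matrix.
#' @param msa_file Optional aligned FASTA; `NULL` generates the synthetic
#'   alignment.
#' @param include_pair Compute per-contact pair indices too (slower).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, pdb = NULL,
                            ligand_chain = "C", receptor_chain = "A",
                            groove_positions = c(7L, 8L, 9L),
                            receptor_length = 30L,
                            params = energy_params(),
                            cutoff = 9.5, min_seq_sep = 3L,
                            neutral_band = c(-1, 1),
                            variation_threshold = 0.5,
                            cluster_k = 3L,
                            srfi_matrix_file = NULL, msa_file = NULL,
                            include_pair = FALSE) {
  if (!(neutral_band[1] < neutral_band[2])) {
    stop("neutral_band must be ordered", call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), pdb = pdb,
                 ligand_chain = ligand_chain,
                 receptor_chain = receptor_chain,
                 groove_positions = as.integer(groove_positions),
                 receptor_length = as.integer(receptor_length),
                 params = params, cutoff = cutoff,
                 min_seq_sep = as.integer(min_seq_sep),
                 neutral_band = neutral_band,
                 variation_threshold = variation_threshold,
                 cluster_k = as.integer(cluster_k),
                 srfi_matrix_file = srfi_matrix_file, msa_file = msa_file,
                 include_pair = isTRUE(include_pair)),
            class = "pipeline_config")
}

.out_path <- function(config, name) file.path(config$out_dir, name)

#' Run the full analysis pipeline
#'
#' Executes structure parsing / generation, contact mapping, frustration
#' profiling of the ligand-loaded and ligand-stripped structure, the
#' binding-delta profile, SRFI-matrix position filtering and single-linkage
#' clustering, and (when an alignment is available) the per-position
#' conservation / rvET table. Writes all tables as TSV plus a manifest
#' recording the configuration, per-stage row counts and output file
#' checksums. Identical configurations yield byte-identical outputs and an
#' identical manifest hash.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  # --- structures ---
  if (is.null(config$pdb)) {
    cx <- make_complex(receptor_length = config$receptor_length,
                       groove_positions = config$groove_positions,
                       cutoff = config$cutoff,
                       min_seq_sep = config$min_seq_sep,
                       seed = config$seed)
    model <- cx$model
    writeLines(cx$pdb, .out_path(config, "complex.pdb"))
  } else {
    model <- contact_map(read_structure(config$pdb),
                         cutoff = config$cutoff,
                         min_seq_sep = config$min_seq_sep)
  }
  .write_tsv(contacts_table(model), .out_path(config, "contacts.tsv"))
  counts$residues <- nrow(model$residues)
  counts$contacts <- nrow(model$contacts)

  # --- frustration: loaded and ligand-free ---
  low <- config$neutral_band[1]
  high <- config$neutral_band[2]
  loaded <- srfi_profile(model, config$params,
                         include_pair = config$include_pair,
                         low = low, high = high)
  free_model <- strip_ligand(model, config$ligand_chain)
  free <- srfi_profile(free_model, config$params,
                       include_pair = config$include_pair,
                       low = low, high = high)
  write_profile(loaded, .out_path(config, "profile_loaded.tsv"),
                if (config$include_pair)
                  .out_path(config, "contact_index_loaded.tsv"))
  write_profile(free, .out_path(config, "profile_free.tsv"))

  # --- profiles: binding delta over receptor positions ---
  loaded_med <- median_srfi(list(loaded), chain = config$receptor_chain)
  dsrfi <- delta_srfi(loaded_med, free, chain = config$receptor_chain)
  .write_tsv(data.frame(position = as.integer(names(dsrfi)),
                        delta_srfi = as.numeric(dsrfi)),
             .out_path(config, "delta_srfi.tsv"))
  counts$delta_positions <- length(dsrfi)

  # --- SRFI matrix, filter, clustering ---
  if (is.null(config$srfi_matrix_file)) {
    sm <- make_srfi_matrix(seed = config$seed)
    mat <- sm$matrix
  } else {
    mat <- read_srfi_matrix(config$srfi_matrix_file)
  }
  write_srfi_matrix(mat, .out_path(config, "srfi_matrix.tsv"))
  kept <- variation_filter(mat, threshold = config$variation_threshold)
  writeLines(kept, .out_path(config, "kept_positions.txt"))
  counts$kept_positions <- length(kept)
  cl <- cluster_profiles(mat, k = config$cluster_k, positions = kept)
  write_merge_table(cl$tree, .out_path(config, "merge_table.tsv"))
  write_dendrogram_newick(cl$tree, .out_path(config, "dendrogram.nwk"))
  .write_tsv(data.frame(allele = names(cl$assignment),
                        cluster = as.integer(cl$assignment)),
             .out_path(config, "clusters.tsv"))
  counts$alleles <- nrow(mat)

  # --- evolution ---
  aln <- if (is.null(config$msa_file)) {
    make_msa(seed = config$seed)$msa
  } else {
    read_msa(config$msa_file)
  }
  trace <- evolutionary_trace(aln)
  .write_tsv(trace, .out_path(config, "trace.tsv"))
  counts$trace_positions <- nrow(trace)

  # --- manifest ---
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- list(
    package = "locfrust",
    version = as.character(utils::packageVersion("locfrust")),
    config = .manifest_config(config),
    stage_counts = counts,
    files = stats::setNames(unname(sums), files),
    manifest_hash = .md5_string(paste(files, unname(sums), collapse = "\n"))
  )
  jsonlite::write_json(manifest, .out_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.manifest_config <- function(config) {
  cfg <- unclass(config)
  cfg$params <- list(r_full = config$params$r_full,
                     r_cut = config$params$r_cut,
                     k_elect = config$params$k_elect,
                     debye_length = config$params$debye_length,
                     electrostatics_on = config$params$electrostatics_on,
                     contact_matrix_md5 =
                       .md5_string(paste(config$params$contact_matrix,
                                         collapse = ",")))
  cfg
}

.md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}
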