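#' Load and validate a run configuration
#'
#' YAML configuration with blocks `design`, `layout`, `photo`, `chem`,
#' `analysis` and a top-level `seed`; unknown keys are rejected. Every key
#' maps to an argument of [design_spec()], [build_layout()],
#' [photochem_params()], [chem_params()] or the analysis thresholds of
#' [error_profile()] / [feature_profiles()].
#'
#' @param file YAML path, or a list already in memory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(file) {
  cfg <- if (is.character(file)) yaml::read_yaml(file) else file
  known_top <- c("design", "layout", "photo", "chem", "analysis", "seed")
  .reject_unknown(cfg, known_top, "top level")
  .reject_unknown(cfg$design,
                  c("n_oligos", "oligo_len", "k", "min_oligo_coverage",
                    "max_homopolymer", "fixed_5p", "fixed_3p"), "design")
  .reject_unknown(cfg$layout,
                  c("design", "rows", "cols", "mirror_pitch", "mirror_gap",
                    "n_features", "cb_full", "n_areas"), "layout")
  .reject_unknown(cfg$photo, names(formals(photochem_params)), "photo")
  .reject_unknown(cfg$chem, names(formals(chem_params)), "chem")
  .reject_unknown(cfg$analysis, c("min_identity", "min_reads"), "analysis")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

.reject_unknown <- function(x, known, where) {
  if (is.null(x)) return(invisible(TRUE))
  bad <- setdiff(names(x), known)
  if (length(bad) > 0)
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Run the full synthesis-and-profiling pipeline
#'
#' design -> layout -> masks -> simulate -> profile -> spatial, writing the
#' panel FASTA, layout TSV, optional PBM masks, FASTQ reads plus truth TSV,
#' an error-rate report, the matrices and profiles as TSV, the spatial
#' summaries, and a manifest echoing the resolved configuration and seed.
#' Two runs with the same config and seed produce identical outputs.
#'
#' @param config A [run_config()] (or path to one).
#' @param out_dir Output directory (created).
#' @param write_mask_files Also write the per-cycle PBM masks (default
#'   FALSE; they are bulky).
#' @return Invisibly, a list with the main in-memory objects (`library`,
#'   `layout`, `stack`, `reads`, `profile`, `map`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, write_mask_files = FALSE) {
  if (is.character(config)) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  t0 <- proc.time()[3]
  stage <- function(name) message(sprintf("[%s] %.1fs", name,
                                          proc.time()[3] - t0))

  d <- config$design
  spec <- do.call(design_spec, c(d, list(seed = seed)))
  lib <- design_library(spec)
  write_panel_fasta(lib, file.path(out_dir, "panel.fasta"))
  stage("design")

  lc <- config$layout
  geom <- dmd_geometry(rows = lc$rows %||% 768L, cols = lc$cols %||% 1024L,
                       mirror_pitch = lc$mirror_pitch %||% 14,
                       mirror_gap = lc$mirror_gap %||% 1)
  layout <- build_layout(lc$design %||% "2SZ", geom,
                         n_features = lc$n_features %||% spec$n_oligos,
                         oligo_ids = lib$id[seq_len(lc$n_features %||%
                                                      spec$n_oligos)],
                         seed = seed, cb_full = isTRUE(lc$cb_full),
                         n_areas = lc$n_areas %||% 4L)
  write_layout_tsv(layout, file.path(out_dir, "layout.tsv"))
  stage("layout")

  stack <- generate_masks(layout, lib)
  if (write_mask_files)
    write_masks(stack, layout, file.path(out_dir, "masks"))
  stage("masks")

  photo <- do.call(photochem_params, config$photo %||% list())
  chem <- do.call(chem_params, .restore_chem(config$chem))
  reads <- simulate_synthesis(lib, layout, stack, photo, chem, seed = seed)
  write_reads_fastq(reads, file.path(out_dir, "reads.fastq"))
  tt <- truth_table(reads, layout)
  utils::write.table(tt, file.path(out_dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stage("simulate")

  an <- config$analysis %||% list()
  prof <- error_profile(reads, lib, layout = layout,
                        min_identity = an$min_identity %||% 0.5)
  .write_profile_tsvs(prof, out_dir)
  stage("profile")

  map <- feature_profiles(prof, layout, min_reads = an$min_reads %||% 5L)
  utils::write.table(as.data.frame(map),
                     file.path(out_dir, "spatial_map.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(area_summary(map),
                     file.path(out_dir, "area_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stage("spatial")

  manifest <- list(config = .unclass_deep(config), seed = seed,
                   n_reads = nrow(reads),
                   package_version = as.character(utils::packageVersion("lithoseq")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(library = lib, layout = layout, stack = stack,
                 reads = reads, profile = prof, map = map,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## YAML flattens the named coupling_efficiency vector into a list; restore.
.restore_chem <- function(chem) {
  if (is.null(chem)) return(list())
  if (!is.null(chem$coupling_efficiency))
    chem$coupling_efficiency <- unlist(chem$coupling_efficiency)
  chem
}

.unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, .unclass_deep) else x
}

.write_profile_tsvs <- function(prof, out_dir) {
  rates <- data.frame(metric = names(prof$rates), percent_per_bp = prof$rates)
  runs <- prof$deletion_runs$bases
  report <- data.frame(
    total = prof$rates["total"], deletion = prof$rates["deletion"],
    insertion = prof$rates["insertion"],
    substitution = prof$rates["substitution"],
    substitution_GT = prof$substitution_matrix["G", "T"],
    deletion_x1 = runs["x1"], deletion_x2 = runs["x2"],
    deletion_x3 = runs["x3"], row.names = NULL)
  utils::write.table(report, file.path(out_dir, "error_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(prof$substitution_matrix),
                     file.path(out_dir, "substitution_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(as.data.frame(prof$match_matrix),
                     file.path(out_dir, "match_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(prof$per_cycle, file.path(out_dir, "per_cycle.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(prof$per_position))
    utils::write.table(prof$per_position,
                       file.path(out_dir, "per_position.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rates)
}
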