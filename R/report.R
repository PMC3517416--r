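#' Early/late marker-panel overlap
#'
#' Intersects two sequenced marker panels by exact modification-coded
#' sequence identity (the published marker lists treat modification variants
#' as separate markers); set `mod_sensitive = FALSE` to intersect on
#' uppercased sequences instead.
#'
#' @param early_panel,late_panel marker-panel data.frames with a `sequence`
#'   column.
#' @param mod_sensitive compare modification-coded sequences (default TRUE).
#' @return list with `n_early`, `n_late`, `n_shared`, `pct_early_shared`
#'   (percentage of the early panel found in the late panel) and `shared`
#'   (character vector of shared sequences).
#' @export
overlap_report <- function(early_panel, late_panel, mod_sensitive = TRUE) {
  key <- function(p) {
    s <- unique(p$sequence)
    if (mod_sensitive) s else unique(toupper(s))
  }
  e <- key(early_panel); l <- key(late_panel)
  shared <- intersect(e, l)
  list(n_early = length(e), n_late = length(l), n_shared = length(shared),
       pct_early_shared = if (length(e)) 100 * length(shared) / length(e)
       else 0,
       shared = sort(shared))
}

pipeline_config_defaults <- list(alpha = 0.05, freq_threshold = 0.70,
                                 case_label = "case",
                                 control_label = "control")

#' Run the full cross-species analysis pipeline
#'
#' Executes feature clustering, marker statistics, sequencing QC and
#' mapping, orthology comparison and protease-activity tallies from a single
#' configuration, and writes every stage output plus a structured run
#' manifest to the output directory. Re-running the same configuration
#' reproduces the outputs.
#'
#' @param config named list or path to a key:value text file with fields:
#'   `fasta` (precursor FASTA), `ortholog_map` (TSV), per species `<sp>` in
#'   `species`: `peaks_<sp>`, `groups_<sp>`, `panel_<sp>`; optional
#'   `motif_db` (TSV, default bundled), `standard_masses` (numeric vector;
#'   when present peak amplitudes are normalized against them),
#'   `protein_filter` (precursor restriction for the protease tally),
#'   `alpha`, `freq_threshold`, `out_dir`.
#' @return list with per-species `consensus`, `markers`, `panel` (after QC
#'   and context extraction), plus `comparison` (orthology),
#'   `activity` (per species protease tallies) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  cfg <- utils::modifyList(pipeline_config_defaults, config)
  for (field in c("fasta", "ortholog_map")) {
    if (is.null(cfg[[field]])) {
      stop("pipeline config error: missing field '", field, "'",
           call. = FALSE)
    }
    if (!file.exists(cfg[[field]])) {
      stop("pipeline config error: field '", field, "' points to a missing ",
           "file: ", cfg[[field]], call. = FALSE)
    }
  }
  species <- cfg$species
  if (is.null(species)) species <- c("rat", "human")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  proteins <- read_fasta(cfg$fasta)
  omap <- read_ortholog_map(cfg$ortholog_map)
  db <- if (is.null(cfg$motif_db)) load_motif_db() else
    load_motif_db(cfg$motif_db)

  manifest <- list(package = "pepclip",
                   version = as.character(utils::packageVersion("pepclip")),
                   alpha = cfg$alpha, freq_threshold = cfg$freq_threshold,
                   species = species, stages = list())
  res <- list(consensus = list(), markers = list(), panel = list(),
              activity = list())

  for (sp in species) {
    pk_path <- cfg[[paste0("peaks_", sp)]]
    gr_path <- cfg[[paste0("groups_", sp)]]
    pn_path <- cfg[[paste0("panel_", sp)]]
    for (p in c(pk_path, gr_path, pn_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("pipeline config error [", sp, "]: missing input file",
             call. = FALSE)
      }
    }
    features <- read_peak_list(pk_path)
    groups <- read_groups(gr_path)
    n_in <- nrow(features)
    if (!is.null(cfg$standard_masses)) {
      norm <- normalize_amplitudes(features, cfg$standard_masses)
      features <- norm$features
    }
    consensus <- cluster_features(features)
    mk <- call_markers(consensus, groups, cfg$case_label, cfg$control_label,
                       alpha = cfg$alpha,
                       freq_threshold = cfg$freq_threshold)
    panel <- read_panel(pn_path)
    panel <- qc_markers(panel, proteins)
    panel <- cleavage_contexts(panel)
    act <- tally_activity(panel[panel$mapped & !is.na(panel$regulation), ,
                                drop = FALSE],
                          db, protein_filter = cfg$protein_filter)
    res$consensus[[sp]] <- consensus
    res$markers[[sp]] <- mk
    res$panel[[sp]] <- panel
    res$activity[[sp]] <- act
    manifest$stages[[sp]] <- list(
      features_in = n_in, samples = ncol(consensus$amplitude),
      consensus_peptides = nrow(consensus$clusters),
      frequency_retained = nrow(mk), significant = sum(mk$significant),
      panel_markers = nrow(panel), panel_mapped = sum(panel$mapped),
      tally_groups = nrow(act$tally))
    if (!is.null(out_dir)) {
      utils::write.table(mk, file.path(out_dir,
                                       paste0("markers_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(panel, file.path(out_dir,
                                          paste0("panel_qc_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(act$tally,
                         file.path(out_dir, paste0("tally_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  comparison <- NULL
  if (length(species) >= 2 && nrow(omap)) {
    rat_sp <- species[1]; hum_sp <- species[2]
    ok <- function(p) p[p$mapped & !is.na(p$regulation), , drop = FALSE]
    comparison <- compare_panels(ok(res$panel[[rat_sp]]),
                                 ok(res$panel[[hum_sp]]), omap)
    manifest$stages$comparison <- list(
      tier_counts = as.list(comparison$tier_counts),
      n_matches = nrow(comparison$matches))
    if (!is.null(out_dir)) {
      utils::write.table(comparison$matches,
                         file.path(out_dir, "orthology_matches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  c(res, list(comparison = comparison, manifest = manifest))
}
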