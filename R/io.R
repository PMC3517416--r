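#' Read precursor protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write protein sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a per-sample peak list
#'
#' Tab-separated with header columns sample_id, mass_da, migration_min,
#' amplitude; one row per detected polypeptide per sample.
#'
#' @param path TSV path.
#' @return validated peak-feature data.frame.
#' @export
read_peak_list <- function(path) {
  f <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_features(f)
  f
}

#' @rdname read_peak_list
#' @param features peak-feature data.frame.
#' @export
write_peak_list <- function(features, path) {
  validate_features(features)
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

PANEL_REQUIRED <- c("sequence", "protein_name", "start", "stop", "p_adjusted",
                    "mean_amp_case", "mean_amp_control", "regulation")

#' Read a sequenced marker-panel table
#'
#' Tab-separated with the supplementary-table column set: sequence
#' (modification-coded: p = hydroxyproline, k = hydroxylysine, m = oxidized
#' methionine), protein_name, start, stop, p_adjusted, mean_amp_case,
#' mean_amp_control, regulation; optional protein_id, species, mass_da,
#' migration_min. When protein_id is absent it is taken equal to
#' protein_name.
#'
#' @param path TSV path.
#' @return marker-panel data.frame.
#' @export
read_panel <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(PANEL_REQUIRED, names(p))
  if (length(miss)) {
    stop("panel lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"protein_id" %in% names(p)) p$protein_id <- p$protein_name
  bad <- p$stop - p$start + 1L != nchar(p$sequence)
  if (any(bad)) {
    stop("panel row(s) ", paste(which(bad), collapse = ", "),
         ": stop - start + 1 must equal sequence length", call. = FALSE)
  }
  p
}

#' @rdname read_panel
#' @param panel marker-panel data.frame.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group membership file
#' @param path TSV with columns sample_id, group.
#' @return named character vector: sample_id -> group.
#' @export
read_groups <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(g)))
  stats::setNames(g$group, g$sample_id)
}

#' Read a declared ortholog map
#'
#' Tab-separated columns rat_id, human_id and optional offset (human start =
#' rat start + offset for collinear precursors; default 0). Each protein may
#' appear in at most one pair.
#'
#' @param path TSV path.
#' @return data.frame rat_id, human_id, offset.
#' @export
read_ortholog_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rat_id", "human_id") %in% names(m)))
  if (!"offset" %in% names(m)) m$offset <- 0L
  m$offset[is.na(m$offset)] <- 0L
  if (anyDuplicated(m$rat_id) || anyDuplicated(m$human_id)) {
    stop("a protein may appear in at most one ortholog pair", call. = FALSE)
  }
  m
}

#' Read/write a flat key:value configuration file
#'
#' One `key: value` pair per line; values are parsed as numeric when
#' possible, comma-separated values become vectors.
#'
#' @param path text file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1]); val <- trimws(p[2])
    vals <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, ": ", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
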