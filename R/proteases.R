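#' Load a protease cleavage-motif database
#'
#' The database is a local table (no live MEROPS/CutDB queries) with one
#' 6-residue cleavage context per row — 3 residues before and 3 after the
#' scissile bond — and the proteases known to cut there. The bundled default
#' transcribes the 14 collagen alpha-1(I) cleavage-site motifs curated from
#' MEROPS/CutDB; users may extend it with their own rows. Duplicate contexts
#' are merged with protease lists unioned.
#'
#' @param path TSV with columns context6, proteases (comma-separated) and
#'   optional source; default is the bundled table.
#' @return object of class `motif_db`: data.frame with context6, proteases
#'   (list column) and source.
#' @export
load_motif_db <- function(path = system.file("extdata",
                                             "cleavage_motifs.tsv",
                                             package = "pepclip")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("context6", "proteases") %in% names(tab)))
  if (!"source" %in% names(tab)) tab$source <- "custom"
  bad <- which(nchar(tab$context6) != 6L |
                 grepl(paste0("[^", paste(names(MONO_RESIDUE_MASS),
                                          collapse = ""), "]"),
                       tab$context6))
  if (length(bad)) {
    stop("motif DB row ", bad[1], ": context '", tab$context6[bad[1]],
         "' is not a 6-residue uppercase motif", call. = FALSE)
  }
  plists <- lapply(strsplit(as.character(tab$proteases), ","), trimws)
  plists <- lapply(plists, function(x) x[!is.na(x) & nzchar(x)])
  if (any(lengths(plists) == 0L)) {
    stop("motif DB: empty protease list", call. = FALSE)
  }
  # merge duplicate contexts, unioning protease lists
  ctx <- unique(tab$context6)
  merged <- data.frame(context6 = ctx, stringsAsFactors = FALSE)
  merged$proteases <- lapply(ctx, function(c6) {
    sort(unique(unlist(plists[tab$context6 == c6])))
  })
  merged$source <- vapply(ctx, function(c6) {
    paste(unique(tab$source[tab$context6 == c6]), collapse = ";")
  }, character(1))
  structure(merged, class = c("motif_db", "data.frame"))
}

#' Match a cleavage-site context against the motif database
#'
#' Strict matching is exact string equality; the relaxed search tolerates up
#' to `max_mismatches` substitutions (Hamming distance). Only complete
#' 6-residue contexts may be queried; incomplete contexts from protein
#' termini are skipped upstream.
#'
#' @param context6 a single 6-residue uppercase context.
#' @param db a `motif_db` from [load_motif_db()].
#' @param max_mismatches 0 for strict (default), up to 2 for the relaxed
#'   search.
#' @return data.frame with motif, protease, mismatches and mode
#'   ("strict"/"relaxed"), sorted by mismatch count then protease name;
#'   zero rows when nothing matches.
#' @export
match_site <- function(context6, db, max_mismatches = 0L) {
  stopifnot(inherits(db, "motif_db"), length(context6) == 1L)
  context6 <- toupper(context6)
  if (nchar(context6) != 6L) {
    stop("context must be exactly 6 residues", call. = FALSE)
  }
  q <- strsplit(context6, "")[[1]]
  dist <- vapply(db$context6, function(m) {
    sum(strsplit(m, "")[[1]] != q)
  }, integer(1), USE.NAMES = FALSE)
  hit <- which(dist <= max_mismatches)
  if (!length(hit)) {
    return(data.frame(motif = character(), protease = character(),
                      mismatches = integer(), mode = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(hit, function(i) {
    data.frame(motif = db$context6[i], protease = db$proteases[[i]],
               mismatches = dist[i],
               mode = if (dist[i] == 0L) "strict" else "relaxed",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$mismatches, out$protease), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default protease grouping: MMP family, ADAMTS5, CTSK/F2
#'
#' Collapses individual protease names into the reported families: every
#' MMP isoform into "MMP"; CTSK and F2 (thrombin) into "CTSK/F2"; anything
#' else keeps its own name.
#'
#' @param protease character vector of protease names.
#' @return character vector of group names.
#' @export
default_protease_grouping <- function(protease) {
  out <- protease
  out[grepl("^MMP", protease)] <- "MMP"
  out[protease %in% c("CTSK", "F2")] <- "CTSK/F2"
  out
}

#' Tally protease-specific cleavage sites on up- vs down-regulated fragments
#'
#' For every marker with a regulation sign, both terminal cleavage contexts
#' are matched against the motif database (strict first, relaxed fallback up
#' to `max_mismatches`). Each matched site increments, on the side of the
#' marker's regulation, the tally of every protease group its motif maps to;
#' a site matching motifs of two groups increments both. Sites are
#' deduplicated per marker at the context-string level, so a peptide mapping
#' to several identical positions in a repetitive precursor counts once per
#' distinct context. The inferred direction of a group's activity is
#' "increased" when more of its sites sit on up-regulated fragments than on
#' down-regulated ones, "decreased" for the converse, "unclear" on a tie.
#'
#' @param panel marker panel after [qc_markers()] and [cleavage_contexts()].
#' @param db a `motif_db`.
#' @param protein_filter optional protein_id/protein_name to restrict to
#'   (e.g. the dominant collagen precursor); NULL = whole panel.
#' @param grouping function collapsing protease names to group names;
#'   default [default_protease_grouping()].
#' @param max_mismatches relaxed-search fallback limit, default 2.
#' @return list with `tally` (data.frame: protease_group, n_sites_up,
#'   n_sites_down, direction) and `provenance` (data.frame: marker row,
#'   terminus, context, motif, proteases, mismatches, regulation).
#' @export
tally_activity <- function(panel, db, protein_filter = NULL,
                           grouping = default_protease_grouping,
                           max_mismatches = 2L) {
  if (!is.null(protein_filter)) {
    panel <- panel[panel$protein_id %in% protein_filter |
                     panel$protein_name %in% protein_filter, , drop = FALSE]
  }
  panel <- panel[!is.na(panel$regulation), , drop = FALSE]
  empty_tally <- data.frame(protease_group = character(),
                            n_sites_up = integer(), n_sites_down = integer(),
                            direction = character(), stringsAsFactors = FALSE)
  prov <- data.frame(marker_row = integer(), terminus = character(),
                     context = character(), motif = character(),
                     proteases = character(), mismatches = integer(),
                     regulation = character(), stringsAsFactors = FALSE)
  if (!nrow(panel)) {
    warning("tally_activity: empty panel after filtering")
    return(list(tally = empty_tally, provenance = prov))
  }
  up <- list(); down <- list()  # group -> count
  bump <- function(env, g) {
    env[[g]] <- (if (is.null(env[[g]])) 0L else env[[g]]) + 1L
    env
  }
  for (i in seq_len(nrow(panel))) {
    contexts <- unique(stats::na.omit(c(
      if (isTRUE(panel$n_complete[i])) panel$n_context6[i] else NA,
      if (isTRUE(panel$c_complete[i])) panel$c_context6[i] else NA)))
    for (ctx in contexts) {
      hits <- match_site(ctx, db, max_mismatches = 0L)
      if (!nrow(hits)) hits <- match_site(ctx, db, max_mismatches)
      if (!nrow(hits)) next
      # a strict hit pre-empts relaxed ones; otherwise nearest mismatch wins
      hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
      groups <- unique(grouping(hits$protease))
      for (g in groups) {
        if (panel$regulation[i] == "up") up <- bump(up, g)
        else down <- bump(down, g)
      }
      terminus <- if (identical(ctx, panel$n_context6[i])) "N" else "C"
      prov <- rbind(prov, data.frame(
        marker_row = i, terminus = terminus, context = ctx,
        motif = paste(unique(hits$motif), collapse = ";"),
        proteases = paste(unique(hits$protease), collapse = ","),
        mismatches = min(hits$mismatches),
        regulation = panel$regulation[i], stringsAsFactors = FALSE))
    }
  }
  groups <- sort(unique(c(names(up), names(down))))
  if (!length(groups)) {
    return(list(tally = empty_tally, provenance = prov))
  }
  n_up <- vapply(groups, function(g) {
    if (is.null(up[[g]])) 0L else up[[g]]
  }, integer(1))
  n_down <- vapply(groups, function(g) {
    if (is.null(down[[g]])) 0L else down[[g]]
  }, integer(1))
  tally <- data.frame(
    protease_group = groups, n_sites_up = n_up, n_sites_down = n_down,
    direction = ifelse(n_up > n_down, "increased",
                       ifelse(n_up < n_down, "decreased", "unclear")),
    stringsAsFactors = FALSE)
  rownames(tally) <- NULL
  list(tally = tally, provenance = prov)
}
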