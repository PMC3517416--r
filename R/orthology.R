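#' Extract terminal cleavage-site contexts for mapped markers
#'
#' For each mapped marker the two proteolytic cleavage sites are described by
#' six residues each: the N-terminal context is the 3 protein residues before
#' the peptide start followed by the first 3 peptide residues; the C-terminal
#' context is the last 3 peptide residues followed by the 3 protein residues
#' after the peptide stop. Contexts are uppercased (modification codes carry
#' no information about the cut) and flagged incomplete when the peptide
#' abuts a protein terminus.
#'
#' @param panel marker panel after [qc_markers()] (needs map_start, map_stop,
#'   n_flank, c_flank, sequence).
#' @return the panel with added columns n_context6, c_context6,
#'   n_complete, c_complete.
#' @export
cleavage_contexts <- function(panel) {
  need <- c("sequence", "mapped", "n_flank", "c_flank")
  stopifnot(all(need %in% names(panel)))
  up <- toupper(panel$sequence)
  first3 <- substr(up, 1L, 3L)
  last3 <- substr(up, pmax(1L, nchar(up) - 2L), nchar(up))
  n_ctx <- paste0(toupper(panel$n_flank), first3)
  c_ctx <- paste0(last3, toupper(panel$c_flank))
  n_ctx[!panel$mapped] <- NA_character_
  c_ctx[!panel$mapped] <- NA_character_
  panel$n_context6 <- n_ctx
  panel$c_context6 <- c_ctx
  panel$n_complete <- panel$mapped & nchar(n_ctx) == 6L & nchar(up) >= 3L
  panel$c_complete <- panel$mapped & nchar(c_ctx) == 6L & nchar(up) >= 3L
  panel
}

# A context comparison counts as identical only when both contexts are
# complete 6-mers and equal.
ctx_identical <- function(a, a_ok, b, b_ok) {
  isTRUE(a_ok) && isTRUE(b_ok) && !is.na(a) && !is.na(b) && a == b
}

#' Orthology tier of a rat/human marker pair
#'
#' Tiers, from strictest to most relaxed: 1 = identical fragment (identical
#' uppercased sequence and both cleavage-site contexts identical); 2 = at
#' least one identical cleavage-site context; 3 = same protein region,
#' coordinate overlap of >= 2 residues (after the ortholog map's per-pair
#' offset). A pair qualifies only when both markers carry the same regulation
#' direction; the highest satisfied tier is returned, NA when none is.
#'
#' @param rat,human single-row marker entries (lists or one-row data.frames)
#'   with sequence, protein_id, regulation, map_start, map_stop, n_context6,
#'   c_context6, n_complete, c_complete.
#' @param ortholog_map data.frame from [read_ortholog_map()].
#' @return integer tier (1, 2, 3) or NA.
#' @export
tier_match <- function(rat, human, ortholog_map) {
  pair <- ortholog_map[ortholog_map$rat_id == rat$protein_id &
                         ortholog_map$human_id == human$protein_id, ]
  if (!nrow(pair)) return(NA_integer_)
  if (is.na(rat$regulation) || is.na(human$regulation) ||
      rat$regulation != human$regulation) {
    return(NA_integer_)
  }
  if (is.na(rat$map_start) || is.na(human$map_start)) return(NA_integer_)
  n_id <- ctx_identical(rat$n_context6, rat$n_complete,
                        human$n_context6, human$n_complete)
  c_id <- ctx_identical(rat$c_context6, rat$c_complete,
                        human$c_context6, human$c_complete)
  seq_id <- toupper(rat$sequence) == toupper(human$sequence)
  if (n_id && c_id && seq_id) return(1L)
  if (n_id || c_id) return(2L)
  off <- pair$offset[1]
  lo <- max(rat$map_start + off, human$map_start)
  hi <- min(rat$map_stop + off, human$map_stop)
  if (hi - lo + 1L >= 2L) return(3L)
  NA_integer_
}

#' Select the n most significant markers of a panel
#'
#' Orders by adjusted p-value; ties are broken by larger absolute log fold
#' change of the group means and then by sequence, so the selection is
#' deterministic.
#'
#' @param panel marker panel with p_adjusted, mean_amp_case,
#'   mean_amp_control, sequence.
#' @param n number of markers to keep, default 50.
#' @return the selected subset, ordered.
#' @export
select_top_markers <- function(panel, n = 50L) {
  if (n > nrow(panel)) {
    warning("requested ", n, " markers but panel has only ", nrow(panel))
    n <- nrow(panel)
  }
  lfc <- abs(log(pmax(panel$mean_amp_case, .Machine$double.eps) /
                   pmax(panel$mean_amp_control, .Machine$double.eps)))
  o <- order(panel$p_adjusted, -lfc, panel$sequence)
  out <- panel[o[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-species panel comparison
#'
#' Matches every rat marker against the human panel under the three-tier
#' orthology rules. Each rat marker contributes at most one match: its best
#' human partner (highest tier; ties resolved by the human marker's lowest
#' adjusted p-value, then sequence), so tier totals are disjoint counts.
#' Per-precursor regulation summaries (markers up/down per species) are
#' reported alongside for panel-level concordance reading.
#'
#' @param rat_panel,human_panel marker panels after [qc_markers()] and
#'   [cleavage_contexts()]; must carry regulation and p_adjusted.
#' @param ortholog_map data.frame from [read_ortholog_map()].
#' @return list with `matches` (data.frame: rat_row, human_row,
#'   rat_sequence, human_sequence, protein pair, tier), `tier_counts`
#'   (named integer vector for tiers 1-3) and `regulation_summary`
#'   (per protein_name per species: n_up, n_down).
#' @export
compare_panels <- function(rat_panel, human_panel, ortholog_map) {
  reg_summary <- function(panel, species) {
    if (!nrow(panel)) {
      return(data.frame(species = character(), protein_name = character(),
                        n_up = integer(), n_down = integer()))
    }
    agg <- lapply(split(panel, panel$protein_name), function(p) {
      data.frame(species = species, protein_name = p$protein_name[1],
                 n_up = sum(p$regulation == "up", na.rm = TRUE),
                 n_down = sum(p$regulation == "down", na.rm = TRUE))
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out
  }
  summary <- rbind(reg_summary(rat_panel, "rat"),
                   reg_summary(human_panel, "human"))

  matches <- data.frame(rat_row = integer(), human_row = integer(),
                        rat_sequence = character(),
                        human_sequence = character(),
                        rat_protein = character(), human_protein = character(),
                        tier = integer(), stringsAsFactors = FALSE)
  if (nrow(rat_panel) && nrow(human_panel)) {
    for (i in seq_len(nrow(rat_panel))) {
      r <- rat_panel[i, ]
      best_tier <- NA_integer_; best_j <- NA_integer_
      for (j in seq_len(nrow(human_panel))) {
        h <- human_panel[j, ]
        t <- tier_match(r, h, ortholog_map)
        if (is.na(t)) next
        better <- is.na(best_tier) || t < best_tier ||
          (t == best_tier &&
             (human_panel$p_adjusted[j] < human_panel$p_adjusted[best_j] ||
                (human_panel$p_adjusted[j] == human_panel$p_adjusted[best_j] &&
                   human_panel$sequence[j] < human_panel$sequence[best_j])))
        if (better) { best_tier <- t; best_j <- j }
      }
      if (!is.na(best_tier)) {
        matches <- rbind(matches, data.frame(
          rat_row = i, human_row = best_j,
          rat_sequence = r$sequence,
          human_sequence = human_panel$sequence[best_j],
          rat_protein = r$protein_id,
          human_protein = human_panel$protein_id[best_j],
          tier = best_tier, stringsAsFactors = FALSE))
      }
    }
  }
  tier_counts <- vapply(1:3, function(t) sum(matches$tier == t), integer(1))
  names(tier_counts) <- paste0("tier", 1:3)
  list(matches = matches, tier_counts = tier_counts,
       regulation_summary = summary)
}
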