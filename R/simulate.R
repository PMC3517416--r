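# Run expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration of a synthetic two-species case/control peptide study
#'
#' Describes the world the generator emulates: collagen-like precursor
#' proteins carrying protease cleavage motifs at known positions, urinary
#' fragments cut at those motifs, log-normal per-sample amplitudes with
#' planted case/control fold changes, logistic detection in log-amplitude,
#' and ppm-scale mass plus minute-scale migration-time measurement noise.
#' Defaults mirror a late-stage rodent cohort (10 cases vs 7 controls)
#' compared against a human study (10 vs 10), fold-4 planted markers with
#' log-scale noise SD 0.5, and protease cleavage-rate asymmetries that raise
#' ADAMTS5- and MMP-generated fragments in cases while lowering CTSK/F2 ones.
#'
#' @param seed integer RNG seed; a fixed config is reproduced exactly.
#' @param n_case,n_control named integer vectors of group sizes per species.
#' @param n_proteins number of precursor proteins.
#' @param protein_length residues per precursor.
#' @param motifs character vector of 6-residue cleavage contexts to plant;
#'   default all bundled motifs.
#' @param cuts_per_protein planted cleavage sites per precursor.
#' @param motif_positions optional data.frame (protein, position, motif)
#'   overriding automatic placement; position is the residue index after
#'   which the cut falls, so the 6-mer occupies positions pos-2..pos+3.
#' @param planted_fold n_planted markers receive this case/control fold.
#' @param n_planted number of planted differential markers.
#' @param planted_protease_weights named numeric: protease group ->
#'   case/control cleavage-rate ratio applied to fragments whose terminal
#'   motifs belong to the group (N- and C-side weights multiply).
#' @param lambda_base mean cleavage count per fragment per sample (the
#'   Poisson layer scaling cleavage events into amplitudes).
#' @param base_amplitude typical fragment amplitude (arbitrary units).
#' @param amplitude_noise_sigma log-scale SD of per-sample amplitudes.
#' @param sample_bias_sigma log-scale SD of the per-sample instrument factor
#'   removed by internal-standard normalization.
#' @param detection_midpoint,detection_slope logistic detection-probability
#'   parameters on the log-amplitude scale.
#' @param mass_error_ppm_sigma,mt_error_min_sigma measurement-noise scales.
#' @param hydroxy_prob probability that a proline in a fragment is emitted as
#'   hydroxyproline (lowercase p).
#' @param standard_masses internal polypeptide standard masses spiked into
#'   every sample at constant pre-bias amplitude.
#' @return validated object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_case = c(rat = 10L, human = 10L),
                              n_control = c(rat = 7L, human = 10L),
                              n_proteins = 3L,
                              protein_length = 600L,
                              motifs = NULL,
                              cuts_per_protein = 8L,
                              motif_positions = NULL,
                              planted_fold = 4,
                              n_planted = 8L,
                              planted_protease_weights =
                                c(ADAMTS5 = 3, MMP = 2, "CTSK/F2" = 1 / 3),
                              lambda_base = 20,
                              base_amplitude = 1000,
                              amplitude_noise_sigma = 0.5,
                              sample_bias_sigma = 0.2,
                              detection_midpoint = log(100),
                              detection_slope = 1.5,
                              mass_error_ppm_sigma = 10,
                              mt_error_min_sigma = 0.25,
                              hydroxy_prob = 0.3,
                              standard_masses = c(1100.25, 2200.5, 3300.75)) {
  if (is.null(motifs)) motifs <- load_motif_db()$context6
  species <- union(names(n_case), names(n_control))
  stopifnot(length(species) >= 1, all(species %in% names(n_case)),
            all(species %in% names(n_control)))
  cfg <- list(seed = as.integer(seed), n_case = n_case, n_control = n_control,
              species = species, n_proteins = as.integer(n_proteins),
              protein_length = as.integer(protein_length), motifs = motifs,
              cuts_per_protein = as.integer(cuts_per_protein),
              motif_positions = motif_positions, planted_fold = planted_fold,
              n_planted = as.integer(n_planted),
              planted_protease_weights = planted_protease_weights,
              lambda_base = lambda_base, base_amplitude = base_amplitude,
              amplitude_noise_sigma = amplitude_noise_sigma,
              sample_bias_sigma = sample_bias_sigma,
              detection_midpoint = detection_midpoint,
              detection_slope = detection_slope,
              mass_error_ppm_sigma = mass_error_ppm_sigma,
              mt_error_min_sigma = mt_error_min_sigma,
              hydroxy_prob = hydroxy_prob,
              standard_masses = standard_masses)
  if (any(c(cfg$n_case, cfg$n_control, cfg$n_proteins, cfg$protein_length,
            cfg$cuts_per_protein) < 1)) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  if (cfg$planted_fold <= 0 || any(cfg$planted_protease_weights <= 0)) {
    stop("fold changes and protease weights must be positive", call. = FALSE)
  }
  if (cfg$amplitude_noise_sigma < 0 || cfg$mass_error_ppm_sigma < 0 ||
      cfg$mt_error_min_sigma < 0 || cfg$sample_bias_sigma < 0) {
    stop("noise sigmas must be non-negative", call. = FALSE)
  }
  if (any(nchar(cfg$motifs) != 6L)) {
    stop("motifs must be 6-residue contexts", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Collagen-like Gly-X-Y backbone with seeded X/Y composition.
collagen_backbone <- function(length, seed) {
  with_seed(seed, {
    xy <- c("P", "A", "E", "R", "S", "Q", "K", "L", "D", "F", "G")
    wt <- c(5, 3, 2, 2, 2, 2, 2, 1, 1, 1, 1)
    n_triplet <- ceiling(length / 3)
    x <- sample(xy, n_triplet, replace = TRUE, prob = wt)
    y <- sample(xy, n_triplet, replace = TRUE, prob = wt)
    substr(paste(rbind("G", x, y), collapse = ""), 1L, length)
  })
}

#' Generate reference precursor proteins with planted cleavage motifs
#'
#' Builds collagen-like Gly-X-Y precursors and overwrites 6-residue cleavage
#' motifs at known cut positions, so that fragment generation can cut at
#' protease-specific sites. Rat and human orthologs are emitted as identical
#' sequences under species-suffixed identifiers, together with the ortholog
#' map. Positions are recorded as ground truth.
#'
#' @param config a [simulation_config()].
#' @return list with `proteins` (named character, FASTA-writable), `cuts`
#'   (data.frame: base_protein, position, motif), `ortholog_map` and
#'   `protein_names` (base_protein -> display name).
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$protein_length
  K <- config$cuts_per_protein
  cuts_list <- list()
  base_seqs <- character(config$n_proteins)
  for (pi in seq_len(config$n_proteins)) {
    prot <- collagen_backbone(L, config$seed + 1000L + pi)
    if (!is.null(config$motif_positions)) {
      mp <- config$motif_positions
      mp <- mp[mp$protein == pi, , drop = FALSE]
      pos <- mp$position
      mot <- mp$motif
    } else {
      # evenly spaced cut positions; motifs cycle with a per-protein stride
      # so that a few proteins jointly cover the whole motif set
      pos <- round(seq_len(K) * L / (K + 1))
      mot <- config$motifs[(seq_len(K) - 1L + (pi - 1L) * K) %%
                             length(config$motifs) + 1L]
    }
    if (length(pos)) {
      if (any(pos < 4L) || any(pos > L - 3L)) {
        stop("configuration error: cut position outside residues 4..",
             L - 3, call. = FALSE)
      }
      if (length(pos) > 1 && any(diff(sort(pos)) < 6L)) {
        stop("configuration error: protein too short to host ", length(pos),
             " non-overlapping motifs", call. = FALSE)
      }
      for (j in seq_along(pos)) {
        substr(prot, pos[j] - 2L, pos[j] + 3L) <- mot[j]
      }
      cuts_list[[pi]] <- data.frame(base_protein = pi, position = pos,
                                    motif = mot, stringsAsFactors = FALSE)
    }
    base_seqs[pi] <- prot
  }
  cuts <- do.call(rbind, cuts_list)
  proteins <- character(0)
  om_rows <- list()
  ids <- function(sp) paste0("PROT", seq_len(config$n_proteins), "_",
                             toupper(sp))
  for (sp in config$species) {
    proteins[ids(sp)] <- base_seqs
  }
  if (all(c("rat", "human") %in% config$species)) {
    om_rows <- data.frame(rat_id = ids("rat"), human_id = ids("human"),
                          offset = 0L, stringsAsFactors = FALSE)
  } else {
    om_rows <- data.frame(rat_id = character(), human_id = character(),
                          offset = integer())
  }
  list(proteins = proteins, cuts = cuts, ortholog_map = om_rows,
       protein_names = paste0("synthetic collagen-like protein ",
                              seq_len(config$n_proteins)))
}

# Protease groups a 6-mer motif belongs to, per the motif DB and grouping.
motif_groups <- function(motif, db, grouping = default_protease_grouping) {
  i <- match(motif, db$context6)
  if (is.na(i)) return(character(0))
  unique(grouping(db$proteases[[i]]))
}

#' Derive the urinary fragment set and its ground truth
#'
#' Fragments are substrings cut exactly at planted motif midpoints: every
#' pair of adjacent cut sites, and every pair one site apart, yields one
#' fragment per precursor. Each fragment's true case/control fold change is
#' the product of its terminal motifs' planted protease weights (cleavage at
#' both termini is needed to release the fragment) times the planted marker
#' fold for the seeded subset of marker fragments. Prolines are emitted as
#' hydroxyproline (code p) with the configured probability.
#'
#' @param refs output of [generate_references()].
#' @param config the [simulation_config()].
#' @param db motif database used to resolve motif -> protease groups.
#' @return data.frame ground truth: fragment_id, base_protein, start, stop,
#'   sequence (modification-coded), n_motif, c_motif, groups, true_fold,
#'   regulation, planted_marker, base_amplitude.
#' @export
simulate_fragments <- function(refs, config, db = load_motif_db()) {
  cuts <- refs$cuts
  frags <- list()
  for (pi in unique(cuts$base_protein)) {
    cc <- cuts[cuts$base_protein == pi, ]
    cc <- cc[order(cc$position), ]
    prot <- refs$proteins[[paste0("PROT", pi, "_",
                                  toupper(config$species[1]))]]
    pairs <- rbind(
      if (nrow(cc) >= 2) cbind(seq_len(nrow(cc) - 1), seq_len(nrow(cc) - 1) + 1),
      if (nrow(cc) >= 3) cbind(seq_len(nrow(cc) - 2), seq_len(nrow(cc) - 2) + 2))
    if (is.null(pairs)) next
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      start <- cc$position[i] + 1L
      stop_ <- cc$position[j]
      frags[[length(frags) + 1L]] <- data.frame(
        base_protein = pi, start = start, stop = stop_,
        sequence = substr(prot, start, stop_),
        n_motif = cc$motif[i], c_motif = cc$motif[j],
        stringsAsFactors = FALSE)
    }
  }
  tr <- do.call(rbind, frags)
  tr <- tr[!duplicated(tr$sequence), , drop = FALSE]  # repetitive backbones
  tr$fragment_id <- paste0("F", seq_len(nrow(tr)))

  w <- config$planted_protease_weights
  weight_of <- function(motif) {
    g <- motif_groups(motif, db)
    g <- g[g %in% names(w)]
    if (!length(g)) 1 else prod(w[g])
  }
  tr$groups <- vapply(tr$c_motif, function(m) {
    paste(motif_groups(m, db), collapse = ";")
  }, character(1))
  tr$true_fold <- vapply(tr$n_motif, weight_of, numeric(1)) *
    vapply(tr$c_motif, weight_of, numeric(1))

  with_seed(config$seed + 2000L, {
    n_pl <- min(config$n_planted, nrow(tr))
    planted <- sample(seq_len(nrow(tr)), n_pl)
    tr$planted_marker <- seq_len(nrow(tr)) %in% planted
    tr$true_fold[planted] <- tr$true_fold[planted] * config$planted_fold
    # per-fragment typical abundance and hydroxyproline emission
    tr$base_amplitude <- config$base_amplitude *
      exp(stats::rnorm(nrow(tr), 0, 0.5))
    tr$sequence <- vapply(tr$sequence, function(s) {
      ch <- strsplit(s, "")[[1]]
      isP <- ch == "P"
      ch[isP & stats::runif(length(ch)) < config$hydroxy_prob] <- "p"
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  tr$regulation <- ifelse(tr$true_fold > 1, "up",
                          ifelse(tr$true_fold < 1, "down", NA))
  rownames(tr) <- NULL
  tr[, c("fragment_id", "base_protein", "start", "stop", "sequence",
         "n_motif", "c_motif", "groups", "true_fold", "regulation",
         "planted_marker", "base_amplitude")]
}

#' Draw per-sample peak lists from the fragment ground truth
#'
#' For each species and sample, every fragment's cleavage-event count is
#' Poisson with rate `lambda_base` times the fragment's fold change in cases
#' (1 in controls); the amplitude is the fragment's typical abundance scaled
#' by the relative count, log-normal noise and a per-sample instrument
#' factor. A fragment is detected when at least one cleavage event occurred
#' and a logistic coin in its log-amplitude lands heads. Measured mass is
#' the theoretical mass perturbed by ppm-scale noise; measured migration
#' time is the charge-model prediction perturbed by minute-scale noise.
#' Internal standards are spiked into every sample.
#'
#' @param fragments ground-truth table from [simulate_fragments()].
#' @param config the [simulation_config()].
#' @param model [migration_model()] used for the true migration times.
#' @return named list per species, each with `features` (peak-list
#'   data.frame incl. standards), `amplitude` (fragment x sample matrix of
#'   true-scale detected amplitudes, NA = not detected), `groups` (named
#'   vector sample_id -> "case"/"control"), `measured` (per-fragment mean
#'   measured mass/time over detected samples).
#' @export
simulate_samples <- function(fragments, config, model = migration_model()) {
  theo_mass <- theoretical_mass(fragments$sequence)
  theo_time <- predict_migration_time(fragments$sequence, model)
  nf <- nrow(fragments)
  out <- list()
  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    n_ca <- config$n_case[[sp]]; n_co <- config$n_control[[sp]]
    ids <- c(sprintf("%s_case_%02d", sp, seq_len(n_ca)),
             sprintf("%s_ctrl_%02d", sp, seq_len(n_co)))
    grp <- stats::setNames(rep(c("case", "control"), c(n_ca, n_co)), ids)
    ns <- length(ids)
    amp <- matrix(NA_real_, nf, ns,
                  dimnames = list(fragments$fragment_id, ids))
    rows <- list()
    with_seed(config$seed + 3000L + si, {
      bias <- exp(stats::rnorm(ns, 0, config$sample_bias_sigma))
      for (j in seq_len(ns)) {
        fold <- if (grp[j] == "case") fragments$true_fold else rep(1, nf)
        counts <- stats::rpois(nf, config$lambda_base * fold)
        a_true <- fragments$base_amplitude * counts / config$lambda_base *
          exp(stats::rnorm(nf, 0, config$amplitude_noise_sigma))
        p_det <- stats::plogis(config$detection_slope *
                                 (log(pmax(a_true, 1e-12)) -
                                    config$detection_midpoint))
        det <- counts > 0 & stats::runif(nf) < p_det
        amp[det, j] <- a_true[det]
        if (any(det)) {
          mass <- theo_mass[det] *
            (1 + stats::rnorm(sum(det), 0, config$mass_error_ppm_sigma) * 1e-6)
          mt <- pmax(1, theo_time[det] +
                       stats::rnorm(sum(det), 0, config$mt_error_min_sigma))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = ids[j], mass_da = mass, migration_min = mt,
            amplitude = a_true[det] * bias[j], stringsAsFactors = FALSE)
        }
        # internal standards: constant pre-bias amplitude, fixed times
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = ids[j], mass_da = config$standard_masses,
          migration_min = seq(20, 30,
                              length.out = length(config$standard_masses)),
          amplitude = 1000 * bias[j], stringsAsFactors = FALSE)
      }
    })
    features <- do.call(rbind, rows)
    rownames(features) <- NULL
    detected <- !is.na(amp)
    measured <- data.frame(
      fragment_id = fragments$fragment_id,
      mass_da = theo_mass, migration_min = theo_time,
      n_detected = rowSums(detected))
    out[[sp]] <- list(features = features, amplitude = amp, groups = grp,
                      measured = measured)
  }
  out
}

# Marker-panel table (supplementary-style schema) computed from a simulated
# species' fragment amplitude matrix with the package's own statistics.
panel_from_amplitudes <- function(species_sim, fragments, refs, species,
                                  alpha = 0.05, freq_threshold = 0.70) {
  amp <- species_sim$amplitude
  grp <- species_sim$groups
  cs <- names(grp)[grp == "case"]; ts <- names(grp)[grp == "control"]
  freq_case <- rowMeans(!is.na(amp[, cs, drop = FALSE]))
  freq_control <- rowMeans(!is.na(amp[, ts, drop = FALSE]))
  keep <- pmax(freq_case, freq_control) >= freq_threshold
  idx <- which(keep)
  a0 <- amp; a0[is.na(a0)] <- 0
  p_raw <- vapply(idx, function(i) ranksum_test(a0[i, cs], a0[i, ts]),
                  numeric(1))
  p_adj <- bh_adjust(p_raw)
  mean_ca <- rowMeans(a0[idx, cs, drop = FALSE])
  mean_co <- rowMeans(a0[idx, ts, drop = FALSE])
  fr <- fragments[idx, , drop = FALSE]
  panel <- data.frame(
    sequence = fr$sequence,
    protein_name = refs$protein_names[fr$base_protein],
    protein_id = paste0("PROT", fr$base_protein, "_", toupper(species)),
    start = fr$start, stop = fr$stop,
    p_raw = p_raw, p_adjusted = p_adj,
    mean_amp_case = mean_ca, mean_amp_control = mean_co,
    regulation = ifelse(mean_ca > mean_co, "up",
                        ifelse(mean_ca < mean_co, "down", NA)),
    freq_case = freq_case[idx], freq_control = freq_control[idx],
    mass_da = species_sim$measured$mass_da[idx],
    migration_min = species_sim$measured$migration_min[idx],
    significant = p_adj < alpha,
    species = species, stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  panel
}

#' Run the full synthetic-study generator
#'
#' @param config a [simulation_config()].
#' @param alpha,freq_threshold parameters of the marker statistics used to
#'   build the sequenced panel tables.
#' @return list with `config`, `refs` (proteins, cuts, ortholog_map),
#'   `truth` (fragment ground truth; a sidecar never consumed by the
#'   analysis stages), `samples` (per species: features/amplitude/groups)
#'   and `panels` (per species: supplementary-style marker tables over all
#'   frequency-passing fragments, with a `significant` column).
#' @export
simulate_study <- function(config = simulation_config(), alpha = 0.05,
                           freq_threshold = 0.70) {
  refs <- generate_references(config)
  truth <- simulate_fragments(refs, config)
  samples <- simulate_samples(truth, config)
  panels <- lapply(config$species, function(sp) {
    panel_from_amplitudes(samples[[sp]], truth, refs, sp,
                          alpha = alpha, freq_threshold = freq_threshold)
  })
  names(panels) <- config$species
  list(config = config, refs = refs, truth = truth, samples = samples,
       panels = panels)
}

#' Serialize a synthetic study to a directory of plain-text artifacts
#'
#' Writes the reference FASTA, per-species peak lists and group files, panel
#' tables, the ortholog map and the ground-truth sidecar.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return dir, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$refs$proteins, file.path(dir, "references.fasta"))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$refs$ortholog_map,
                     file.path(dir, "ortholog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sp in study$config$species) {
    write_peak_list(study$samples[[sp]]$features,
                    file.path(dir, paste0("peaks_", sp, ".tsv")))
    grp <- study$samples[[sp]]$groups
    utils::write.table(data.frame(sample_id = names(grp), group = grp),
                       file.path(dir, paste0("groups_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_panel(study$panels[[sp]],
                file.path(dir, paste0("panel_", sp, ".tsv")))
  }
  invisible(dir)
}
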