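#' Mass-dependent clustering tolerance, in ppm
#'
#' CE-MS peak features from different samples are considered the same
#' polypeptide when their deconvoluted masses agree within a mass-dependent
#' window: +/-50 ppm below 4000 Da, increasing linearly to +/-150 ppm at
#' 6000 Da, and +/-150 ppm above that.
#'
#' @param mass numeric vector of neutral monoisotopic masses in Da; must be
#'   positive.
#' @return numeric vector of half-window widths in ppm.
#' @seealso [time_tolerance()], [cluster_features()]
#' @export
#' @examples
#' mass_tolerance(c(3000, 5000, 7000))  # 50, 100, 150
mass_tolerance <- function(mass) {
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be positive and finite", call. = FALSE)
  }
  ppm <- 50 + (150 - 50) * (mass - 4000) / (6000 - 4000)
  pmin(pmax(ppm, 50), 150)
}

#' Migration-time-dependent clustering tolerance, in minutes
#'
#' The acceptable migration-time deviation is +/-1.0 min up to 19 min,
#' increasing linearly to +/-2.5 min at 50 min, and +/-2.5 min beyond.
#'
#' @param migration_time numeric vector of normalized CE migration times in
#'   minutes; must be positive.
#' @return numeric vector of half-window widths in minutes.
#' @export
#' @examples
#' time_tolerance(c(19, 34.5, 50))  # 1.0, 1.75, 2.5
time_tolerance <- function(migration_time) {
  if (!is.numeric(migration_time) || any(!is.finite(migration_time)) ||
      any(migration_time <= 0)) {
    stop("migration_time must be positive and finite", call. = FALSE)
  }
  tol <- 1.0 + (2.5 - 1.0) * (migration_time - 19) / (50 - 19)
  pmin(pmax(tol, 1.0), 2.5)
}

#' Validate a peak-feature table
#'
#' A peak-feature table holds one row per detected polypeptide per sample with
#' columns `sample_id`, `mass_da`, `migration_min`, `amplitude`. Masses are
#' restricted to the analyzed 0.8-25 kDa range.
#'
#' @param features data.frame with the four peak-list columns.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_features <- function(features) {
  req <- c("sample_id", "mass_da", "migration_min", "amplitude")
  miss <- setdiff(req, names(features))
  if (length(miss)) {
    stop("peak-feature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(features)) {
    if (any(features$mass_da < 800 | features$mass_da > 25000)) {
      stop("mass_da outside the accepted 800-25000 Da range", call. = FALSE)
    }
    if (any(features$migration_min <= 0)) {
      stop("migration_min must be positive", call. = FALSE)
    }
    if (any(features$amplitude < 0)) {
      stop("amplitude must be non-negative", call. = FALSE)
    }
  }
  invisible(features)
}

#' Normalize amplitudes against internal polypeptide standards
#'
#' Each sample's amplitudes are rescaled so that the median amplitude of the
#' features matching the internal-standard masses (within the mass tolerance
#' window) equals a common reference level. Samples in which no standard is
#' detected cannot be scaled and are dropped, with a message; silently
#' unscaled amplitudes would corrupt the downstream rank tests.
#'
#' @param features peak-feature table (see [validate_features()]).
#' @param standard_masses numeric vector of internal-standard masses (Da).
#' @param reference reference level the standards are scaled to; default is
#'   the grand median of the per-sample standard medians, so a study already
#'   on a common scale is left unchanged.
#' @return list with `features` (scaled table, flagged samples removed),
#'   `scale_factors` (named vector) and `excluded_samples` (character).
#' @export
normalize_amplitudes <- function(features, standard_masses, reference = NULL) {
  validate_features(features)
  stopifnot(is.numeric(standard_masses), length(standard_masses) >= 1)
  samples <- unique(features$sample_id)
  tol_da <- standard_masses * mass_tolerance(standard_masses) * 1e-6
  std_median <- vapply(samples, function(s) {
    f <- features[features$sample_id == s, ]
    hit <- vapply(seq_along(standard_masses), function(i) {
      any(abs(f$mass_da - standard_masses[i]) <= tol_da[i])
    }, logical(1))
    amps <- unlist(lapply(which(hit), function(i) {
      f$amplitude[abs(f$mass_da - standard_masses[i]) <= tol_da[i]]
    }))
    if (length(amps)) stats::median(amps) else NA_real_
  }, numeric(1))
  names(std_median) <- samples
  excluded <- samples[is.na(std_median)]
  if (length(excluded)) {
    message("normalize_amplitudes: no internal standard matched in sample(s) ",
            paste(excluded, collapse = ", "), "; excluded from clustering")
  }
  kept <- setdiff(samples, excluded)
  if (!length(kept)) {
    stop("no sample contains a matchable internal standard", call. = FALSE)
  }
  if (is.null(reference)) reference <- stats::median(std_median[kept])
  scale <- reference / std_median[kept]
  out <- features[features$sample_id %in% kept, , drop = FALSE]
  out$amplitude <- out$amplitude * scale[as.character(out$sample_id)]
  rownames(out) <- NULL
  list(features = out, scale_factors = scale, excluded_samples = excluded)
}

#' Cluster peak features across samples into consensus peptides
#'
#' Greedy incremental clustering: features are visited in order of descending
#' amplitude; each feature joins the nearest existing cluster whose
#' representative lies within both the mass and the migration-time tolerance
#' windows (distance = |dmass|/mass window + |dtime|/time window, each
#' component required to be <= 1), otherwise it founds a new cluster. A
#' cluster holds at most one feature per sample: when a second feature of the
#' same sample would join, the nearer of the two stays and the other founds a
#' new cluster. Representatives are running means of the members' masses and
#' times.
#'
#' @param features normalized peak-feature table.
#' @return an object of class `consensus_set`: list with `clusters`
#'   (data.frame: cluster_id, mass_da, migration_min, n_members), `amplitude`
#'   (clusters x samples matrix, NA = not detected) and `members` (feature
#'   table with a cluster_id column).
#' @export
cluster_features <- function(features) {
  validate_features(features)
  samples <- sort(unique(as.character(features$sample_id)))
  n <- nrow(features)
  if (n == 0) {
    return(structure(list(
      clusters = data.frame(cluster_id = integer(), mass_da = numeric(),
                            migration_min = numeric(), n_members = integer()),
      amplitude = matrix(NA_real_, 0, length(samples),
                         dimnames = list(NULL, samples)),
      members = cbind(features, cluster_id = integer(0))),
      class = "consensus_set"))
  }
  ord <- order(-features$amplitude, features$mass_da, features$migration_min)
  f <- features[ord, , drop = FALSE]

  # growable cluster state; reps are running means
  cap <- n
  rep_mass <- numeric(cap); rep_time <- numeric(cap); rep_n <- integer(cap)
  assign_cluster <- integer(n)
  # per-cluster map sample -> row index in f (for the one-per-sample rule)
  occupant <- vector("list", cap)
  k <- 0L

  dist_to <- function(i, cl) {
    dm <- abs(f$mass_da[i] - rep_mass[cl]) /
      (rep_mass[cl] * mass_tolerance(rep_mass[cl]) * 1e-6)
    dt <- abs(f$migration_min[i] - rep_time[cl]) / time_tolerance(rep_time[cl])
    if (dm <= 1 && dt <= 1) dm + dt else Inf
  }

  new_cluster <- function(i) {
    k <<- k + 1L
    rep_mass[k] <<- f$mass_da[i]; rep_time[k] <<- f$migration_min[i]
    rep_n[k] <<- 1L
    occupant[[k]] <<- stats::setNames(i, as.character(f$sample_id[i]))
    assign_cluster[i] <<- k
  }

  join <- function(i, cl) {
    rep_n[cl] <<- rep_n[cl] + 1L
    rep_mass[cl] <<- rep_mass[cl] + (f$mass_da[i] - rep_mass[cl]) / rep_n[cl]
    rep_time[cl] <<- rep_time[cl] +
      (f$migration_min[i] - rep_time[cl]) / rep_n[cl]
    occ <- occupant[[cl]]
    occ[as.character(f$sample_id[i])] <- i
    occupant[[cl]] <<- occ
    assign_cluster[i] <<- cl
  }

  for (i in seq_len(n)) {
    if (k == 0L) { new_cluster(i); next }
    kk <- seq_len(k)
    dm <- abs(f$mass_da[i] - rep_mass[kk]) /
      (rep_mass[kk] * mass_tolerance(rep_mass[kk]) * 1e-6)
    dt <- abs(f$migration_min[i] - rep_time[kk]) / time_tolerance(rep_time[kk])
    d <- ifelse(dm <= 1 & dt <= 1, dm + dt, Inf)
    best <- which.min(d)
    if (!is.finite(d[best])) { new_cluster(i); next }
    sid <- as.character(f$sample_id[i])
    prev <- occupant[[best]][sid]
    if (!is.na(prev)) {
      # same-sample collision: nearer feature keeps the slot
      if (dist_to(prev, best) <= d[best]) { new_cluster(i); next }
      # evict the previous occupant to its own singleton cluster (no rep
      # rewind: drift stays bounded and the membership invariant is checked
      # post hoc)
      join(i, best)
      pk <- k + 1L
      k <- pk
      rep_mass[pk] <- f$mass_da[prev]; rep_time[pk] <- f$migration_min[prev]
      rep_n[pk] <- 1L
      occupant[[pk]] <- stats::setNames(prev, as.character(f$sample_id[prev]))
      assign_cluster[prev] <- pk
    } else {
      join(i, best)
    }
  }

  keep <- seq_len(k)
  clusters <- data.frame(cluster_id = keep, mass_da = rep_mass[keep],
                         migration_min = rep_time[keep],
                         n_members = rep_n[keep])
  amp <- matrix(NA_real_, k, length(samples),
                dimnames = list(as.character(keep), samples))
  for (i in seq_len(n)) {
    amp[assign_cluster[i], as.character(f$sample_id[i])] <- f$amplitude[i]
  }
  members <- cbind(f, cluster_id = assign_cluster)
  rownames(members) <- NULL
  structure(list(clusters = clusters, amplitude = amp, members = members),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat("consensus_set:", nrow(x$clusters), "consensus peptides across",
      ncol(x$amplitude), "samples\n")
  invisible(x)
}

#' Per-group detection frequencies of consensus peptides
#'
#' @param consensus a `consensus_set` from [cluster_features()].
#' @param groups named character vector mapping sample_id to group label.
#' @return data.frame: cluster_id plus one `freq_<group>` column per group.
#' @export
detection_frequencies <- function(consensus, groups) {
  stopifnot(inherits(consensus, "consensus_set"))
  samples <- colnames(consensus$amplitude)
  if (!all(samples %in% names(groups))) {
    stop("groups is missing sample(s): ",
         paste(setdiff(samples, names(groups)), collapse = ", "),
         call. = FALSE)
  }
  glab <- groups[samples]
  out <- data.frame(cluster_id = consensus$clusters$cluster_id)
  for (g in unique(glab)) {
    cols <- samples[glab == g]
    out[[paste0("freq_", g)]] <-
      rowMeans(!is.na(consensus$amplitude[, cols, drop = FALSE]))
  }
  out
}
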