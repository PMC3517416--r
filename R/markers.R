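#' Frequency filter for consensus peptides
#'
#' Only peptides detected in at least `threshold` (default 70%) of the samples
#' of at least one diagnostic group are carried into statistical testing.
#'
#' @param freqs data.frame from [detection_frequencies()] restricted to the
#'   two diagnostic groups, or any data.frame whose `freq_*` columns hold the
#'   per-group detection fractions.
#' @param threshold minimum detection fraction, default 0.70.
#' @return logical vector, TRUE for retained peptides.
#' @export
frequency_filter <- function(freqs, threshold = 0.70) {
  fc <- freqs[, grep("^freq_", names(freqs)), drop = FALSE]
  if (!ncol(fc)) stop("no freq_* columns found", call. = FALSE)
  apply(as.matrix(fc), 1L, max) >= threshold
}

# Exact null distribution of the case rank sum: enumerate all C(n+m, n)
# assignments of the (mid-)ranks to the case group. Feasible for
# min(n, m) <= 8 (C(16, 8) = 12870 subsets).
ranksum_exact_p <- function(w, ranks, n) {
  combos <- utils::combn(length(ranks), n)
  sums <- colSums(matrix(ranks[combos], nrow = n))
  eps <- 1e-9
  p_lo <- mean(sums <= w + eps)
  p_hi <- mean(sums >= w - eps)
  min(1, 2 * min(p_lo, p_hi))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact permutation distribution of the rank sum (mid-ranks for
#' ties) when the smaller group has at most `exact_max` observations, and the
#' normal approximation with tie correction and continuity correction
#' otherwise. Cohort sizes of 7-10 per group make the exact branch the
#' default working regime.
#'
#' @param case,control numeric amplitude vectors (each length >= 1).
#' @param exact_max largest min(n, m) for which the exact branch is used.
#' @return two-sided p-value in (0, 1].
#' @export
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))  # 0.1
ranksum_test <- function(case, control, exact_max = 8L) {
  n <- length(case); m <- length(control)
  if (n < 1 || m < 1) stop("both groups need >= 1 observation", call. = FALSE)
  ranks <- rank(c(case, control))
  w <- sum(ranks[seq_len(n)])
  if (min(n, m) <= exact_max) {
    return(ranksum_exact_p(w, ranks, n))
  }
  N <- n + m
  ties <- table(ranks)
  mu <- n * (N + 1) / 2
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)  # all observations tied
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_i = min over j >= i (in ascending p order) of p_j * m / j, capped at 1,
#' returned in the input order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Define differential peptide markers
#'
#' Applies the detection-frequency filter, the Wilcoxon rank-sum test per
#' consensus peptide, Benjamini-Hochberg adjustment across the retained
#' peptides, and regulation calling from group mean amplitudes. A peptide not
#' detected in a sample is by default scored as amplitude 0 there (both in the
#' test and in the means), preserving the presence/absence signal the
#' frequency filter implies; set `missing_as_zero = FALSE` to drop missing
#' observations instead.
#'
#' Peptides whose group means tie exactly carry no regulation sign; they are
#' flagged (`regulation = NA`) and must be excluded from orthology and
#' protease stages, which require a direction.
#'
#' @param consensus a `consensus_set` from [cluster_features()].
#' @param groups named character vector: sample_id -> group label.
#' @param case,control the two diagnostic group labels.
#' @param alpha significance level on the adjusted p-value (strict `<`).
#' @param freq_threshold detection-frequency threshold, default 0.70.
#' @param missing_as_zero score non-detections as amplitude 0 (default).
#' @return data.frame with one row per retained peptide: cluster_id, mass_da,
#'   migration_min, freq_case, freq_control, p_raw, p_adjusted, mean_amp_case,
#'   mean_amp_control, regulation ("up"/"down"/NA), significant. Peptides
#'   skipped (empty group under `missing_as_zero = FALSE`) are recorded in the
#'   `skipped` attribute.
#' @export
call_markers <- function(consensus, groups, case, control, alpha = 0.05,
                         freq_threshold = 0.70, missing_as_zero = TRUE) {
  stopifnot(inherits(consensus, "consensus_set"))
  samples <- colnames(consensus$amplitude)
  glab <- groups[samples]
  cs <- samples[glab == case]
  ts <- samples[glab == control]
  if (!length(cs) || !length(ts)) {
    stop("case/control labels not found among the samples", call. = FALSE)
  }
  amp <- consensus$amplitude
  freq_case <- rowMeans(!is.na(amp[, cs, drop = FALSE]))
  freq_control <- rowMeans(!is.na(amp[, ts, drop = FALSE]))
  keep <- pmax(freq_case, freq_control) >= freq_threshold
  idx <- which(keep)
  skipped <- character(0)
  p_raw <- rep(NA_real_, length(idx))
  mean_c <- rep(NA_real_, length(idx))
  mean_t <- rep(NA_real_, length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    a <- amp[i, cs]; b <- amp[i, ts]
    if (missing_as_zero) {
      a[is.na(a)] <- 0; b[is.na(b)] <- 0
    } else {
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (!length(a) || !length(b)) {
        skipped <- c(skipped, as.character(consensus$clusters$cluster_id[i]))
        next
      }
    }
    p_raw[j] <- ranksum_test(a, b)
    mean_c[j] <- mean(a); mean_t[j] <- mean(b)
  }
  ok <- !is.na(p_raw)
  out <- data.frame(
    cluster_id = consensus$clusters$cluster_id[idx][ok],
    mass_da = consensus$clusters$mass_da[idx][ok],
    migration_min = consensus$clusters$migration_min[idx][ok],
    freq_case = freq_case[idx][ok], freq_control = freq_control[idx][ok],
    p_raw = p_raw[ok])
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$mean_amp_case <- mean_c[ok]
  out$mean_amp_control <- mean_t[ok]
  out$regulation <- ifelse(out$mean_amp_case > out$mean_amp_control, "up",
                           ifelse(out$mean_amp_case < out$mean_amp_control,
                                  "down", NA_character_))
  if (anyNA(out$regulation)) {
    message("call_markers: ", sum(is.na(out$regulation)),
            " peptide(s) with exactly tied group means flagged unregulated")
  }
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$p_raw, out$cluster_id), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
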