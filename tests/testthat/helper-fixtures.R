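# Shared micro-fixtures built in code.

# Minimal peak-feature table builder.
make_features <- function(sample_id, mass_da, migration_min, amplitude) {
  data.frame(sample_id = sample_id, mass_da = mass_da,
             migration_min = migration_min, amplitude = amplitude,
             stringsAsFactors = FALSE)
}

# A precursor hosting a PGK><QGA junction at positions 4..9 (cut after 6).
FIXTURE_PROTEIN <- "MKTPGKQGAKGEPG"

# One-row marker entry of the shape tier_match() expects.
make_marker <- function(sequence, protein_id, start, stop, n_ctx, c_ctx,
                        regulation = "up", p_adjusted = 0.01,
                        n_complete = TRUE, c_complete = TRUE) {
  data.frame(sequence = sequence, protein_id = protein_id,
             protein_name = protein_id, map_start = start, map_stop = stop,
             n_context6 = n_ctx, c_context6 = c_ctx,
             n_complete = n_complete, c_complete = c_complete,
             regulation = regulation, p_adjusted = p_adjusted,
             mapped = TRUE, stringsAsFactors = FALSE)
}

identity_ortholog_map <- function(ids) {
  data.frame(rat_id = ids, human_id = ids, offset = 0L,
             stringsAsFactors = FALSE)
}

# Independent monoisotopic mass oracle from elemental composition:
# residue formulas x element masses, coded separately from the package's
# residue-mass table.
oracle_mass <- local({
  el <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
          O = 15.9949146221, S = 31.97207069)
  formulas <- list(
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  res_mass <- vapply(formulas, function(f) sum(f * el), numeric(1))
  function(seq) {
    ch <- strsplit(seq, "")[[1]]
    lower <- ch %in% c("p", "k", "m")
    parents <- toupper(ch)
    sum(res_mass[parents]) + sum(lower) * el[["O"]] +
      2 * el[["H"]] + el[["O"]]
  }
})

# Brute-force two-sided rank-sum p by full enumeration of rank splits,
# written independently of the package's implementation.
oracle_ranksum <- function(x, y) {
  N <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  splits <- utils::combn(N, length(x))
  ws <- apply(splits, 2, function(idx) sum(r[idx]))
  lo <- sum(ws <= w_obs + 1e-9) / ncol(splits)
  hi <- sum(ws >= w_obs - 1e-9) / ncol(splits)
  min(1, 2 * min(lo, hi))
}
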