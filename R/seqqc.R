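# Monoisotopic residue masses (Da). Lowercase codes are the panel-table
# modification alphabet: p = hydroxyproline, k = hydroxylysine, m = oxidized
# methionine, each the parent residue + one oxygen.
MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
HYDROXYL_MASS <- 15.9949
WATER_MASS <- 18.01056
MOD_PARENT <- c(p = "P", k = "K", m = "M")

#' Theoretical monoisotopic neutral peptide mass
#'
#' Sum of monoisotopic residue masses plus one water. Lowercase modification
#' codes (p, k, m) add +15.9949 Da to the mass of the parent residue.
#'
#' @param sequence character vector of modification-coded peptide sequences.
#' @return numeric vector of neutral monoisotopic masses in Da.
#' @export
#' @examples
#' theoretical_mass("G")              # 75.0320
#' theoretical_mass("p") - theoretical_mass("P")  # 15.9949
theoretical_mass <- function(sequence) {
  vapply(sequence, function(s) {
    if (!nzchar(s)) stop("empty sequence", call. = FALSE)
    chars <- strsplit(s, "")[[1]]
    mods <- chars %in% names(MOD_PARENT)
    parents <- chars
    parents[mods] <- MOD_PARENT[chars[mods]]
    bad <- !(parents %in% names(MONO_RESIDUE_MASS))
    if (any(bad)) {
      stop("unknown residue symbol '", chars[bad][1], "' in sequence '", s,
           "'", call. = FALSE)
    }
    sum(MONO_RESIDUE_MASS[parents]) + sum(mods) * HYDROXYL_MASS + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mass-deviation quality check
#'
#' Sequenced peptide identifications are accepted only when the measured and
#' theoretical masses agree within a ppm limit (default +/-80 ppm).
#'
#' @param measured,theoretical masses in Da, both positive.
#' @param limit_ppm acceptance half-window, default 80.
#' @return data.frame with columns `ppm` (signed deviation) and `pass`.
#' @export
mass_deviation_check <- function(measured, theoretical, limit_ppm = 80) {
  if (any(measured <= 0) || any(theoretical <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  ppm <- 1e6 * (measured - theoretical) / theoretical
  data.frame(ppm = ppm, pass = abs(ppm) < limit_ppm)
}

#' Construct a CE migration-time model
#'
#' At the working pH of 2 a peptide's CE migration time is governed by its
#' positive charge, i.e. its number of basic residues (K, R, H); more charge
#' means earlier migration. The model is a calibration table mapping basic
#' residue count to expected migration time, interpolated linearly between
#' counts and clamped at the boundaries. The true calibration of the original
#' instrument is not published, so the table is injectable; the default is a
#' plausible monotone curve spanning the observed 18-60 min window.
#'
#' @param counts integer vector of basic-residue counts (ascending).
#' @param minutes expected migration times, strictly decreasing.
#' @param window acceptance half-window in minutes, default 2.
#' @return object of class `migration_model`.
#' @export
migration_model <- function(counts = 0:6,
                            minutes = c(42, 37, 33, 30, 28, 26.5, 25.5),
                            window = 2) {
  if (!length(counts)) stop("empty calibration table", call. = FALSE)
  stopifnot(length(counts) == length(minutes))
  o <- order(counts)
  counts <- counts[o]; minutes <- minutes[o]
  if (length(minutes) > 1 && any(diff(minutes) >= 0)) {
    stop("expected migration time must strictly decrease with basic-residue ",
         "count", call. = FALSE)
  }
  structure(list(counts = counts, minutes = minutes, window = window),
            class = "migration_model")
}

#' Count basic residues (K, R, H) in an uppercased sequence
#' @param sequence modification-coded peptide sequence(s).
#' @return integer vector of counts.
#' @export
count_basic_residues <- function(sequence) {
  up <- toupper(sequence)
  vapply(strsplit(up, ""), function(ch) sum(ch %in% c("K", "R", "H")),
         integer(1))
}

#' Predicted CE migration time of a peptide sequence
#'
#' @param sequence modification-coded peptide sequence(s).
#' @param model a [migration_model()].
#' @return predicted migration time(s) in minutes.
#' @export
predict_migration_time <- function(sequence, model = migration_model()) {
  stopifnot(inherits(model, "migration_model"))
  b <- count_basic_residues(sequence)
  if (length(model$counts) == 1) return(rep(model$minutes, length(b)))
  stats::approx(model$counts, model$minutes, xout = b, rule = 2)$y
}

#' Migration-time quality check
#'
#' @param observed observed migration times (min).
#' @param sequence modification-coded sequences (same length).
#' @param model a [migration_model()].
#' @return data.frame with `predicted`, `delta_min` and `pass`
#'   (|delta| < window).
#' @export
migration_check <- function(observed, sequence, model = migration_model()) {
  pred <- predict_migration_time(sequence, model)
  delta <- observed - pred
  data.frame(predicted = pred, delta_min = delta,
             pass = abs(delta) < model$window)
}

#' Map a peptide onto its precursor protein
#'
#' Case-insensitive exact substring search of the uppercased peptide in the
#' precursor sequence. All occurrences are returned with 1-based inclusive
#' coordinates and up to three flanking protein residues on each side
#' (shorter at the termini). Collagens are repetitive, so multiple
#' occurrences are real and all retained.
#'
#' @param sequence modification-coded peptide sequence.
#' @param protein precursor amino-acid sequence (single string).
#' @return data.frame with columns start, stop, n_flank, c_flank; zero
#'   occurrences raise a mapping error.
#' @export
#' @examples
#' map_peptide("QGAKG", "MKTPGKQGAKGEPG")  # (7, 11, "PGK", "EPG")
map_peptide <- function(sequence, protein) {
  pep <- toupper(sequence)
  prot <- toupper(protein)
  hits <- gregexpr(pep, prot, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    stop("peptide '", sequence, "' not found in precursor", call. = FALSE)
  }
  start <- as.integer(hits)
  stop_ <- start + nchar(pep) - 1L
  n_flank <- substr(prot, pmax(1L, start - 3L), start - 1L)
  c_flank <- substr(prot, stop_ + 1L, pmin(nchar(prot), stop_ + 3L))
  data.frame(start = start, stop = stop_, n_flank = n_flank,
             c_flank = c_flank, stringsAsFactors = FALSE)
}

#' Run the sequencing quality filters and precursor mapping on a marker panel
#'
#' Applies, per marker: (i) the +/-80 ppm check of measured against
#' theoretical mass when a `mass_da` column is present; (ii) the +/-2 min CE
#' migration-time check when a `migration_min` column is present; and (iii)
#' exact mapping of the uppercased sequence onto the stated precursor, with
#' extraction of terminal cleavage contexts. Markers that fail to map are
#' flagged and must be excluded downstream.
#'
#' @param panel marker-panel data.frame with at least `sequence` and
#'   `protein_id` columns (see [read_panel()]).
#' @param proteins named character vector of precursor sequences (names =
#'   protein_id), e.g. from [read_fasta()].
#' @param model a [migration_model()].
#' @param limit_ppm mass acceptance half-window, default 80.
#' @return the panel with added columns: theoretical_mass, ppm, mass_pass,
#'   predicted_min, delta_min, time_pass, mapped, map_start, map_stop,
#'   n_flank, c_flank (first occurrence; all occurrences retrievable via
#'   [map_peptide()]).
#' @export
qc_markers <- function(panel, proteins, model = migration_model(),
                       limit_ppm = 80) {
  stopifnot(all(c("sequence", "protein_id") %in% names(panel)))
  n <- nrow(panel)
  panel$theoretical_mass <- theoretical_mass(panel$sequence)
  if ("mass_da" %in% names(panel)) {
    mc <- mass_deviation_check(panel$mass_da, panel$theoretical_mass,
                               limit_ppm)
    panel$ppm <- mc$ppm; panel$mass_pass <- mc$pass
  }
  if ("migration_min" %in% names(panel)) {
    tc <- migration_check(panel$migration_min, panel$sequence, model)
    panel$predicted_min <- tc$predicted
    panel$delta_min <- tc$delta_min
    panel$time_pass <- tc$pass
  }
  panel$mapped <- FALSE
  panel$map_start <- NA_integer_; panel$map_stop <- NA_integer_
  panel$n_flank <- NA_character_; panel$c_flank <- NA_character_
  for (i in seq_len(n)) {
    prot <- proteins[[panel$protein_id[i]]]
    if (is.null(prot) || is.na(prot)) next
    hit <- tryCatch(map_peptide(panel$sequence[i], prot),
                    error = function(e) NULL)
    if (is.null(hit)) next
    panel$mapped[i] <- TRUE
    panel$map_start[i] <- hit$start[1]
    panel$map_stop[i] <- hit$stop[1]
    panel$n_flank[i] <- hit$n_flank[1]
    panel$c_flank[i] <- hit$c_flank[1]
  }
  if (any(!panel$mapped)) {
    message("qc_markers: ", sum(!panel$mapped),
            " marker(s) failed precursor mapping; flagged")
  }
  panel
}
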