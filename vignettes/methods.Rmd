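---
title: "Methods: cross-species urinary peptidomics with pepclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species urinary peptidomics with pepclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepclip)
```

# Scope and model

`pepclip` analyses CE-MS urinary peptidomics studies downstream of charge
deconvolution: its inputs are per-sample peak lists (neutral mass,
normalized migration time, amplitude), sequenced marker-panel tables, precursor
FASTA, and a protease cleavage-motif table. Raw spectra handling, MS/MS
identification and search-engine FDR control are deliberately out of scope —
the package applies only post-hoc QC to already-sequenced peptides.

## Consensus clustering

Two features from different samples are treated as the same polypeptide when
they fall inside mass- and time-dependent tolerance windows. Both windows are
piecewise linear; "gradually increasing" between the published anchors is
read as linear interpolation, the simplest monotone continuous
interpretation:

* mass: ±50 ppm below 4000 Da, ramping to ±150 ppm at 6000 Da, constant
  beyond;
* time: ±1.0 min up to 19 min, ramping to ±2.5 min at 50 min, constant
  beyond.

The clustering algorithm itself is not specified by the source methodology,
so a deterministic greedy scheme was chosen: features are visited in
descending amplitude; each joins the nearest in-window cluster
(distance = |Δm|/tol_m + |Δt|/tol_t, both components ≤ 1) or founds a new
one. Cluster representatives are running means — drift is bounded and the
membership invariant (every member within the window of its representative)
is asserted post hoc in the test suite rather than assumed. A cluster keeps
at most one feature per sample; on a collision the nearer feature keeps the
slot and the other founds a singleton. On well-separated data (pairwise
distances much larger than the windows) the result is provably
order-independent, which the suite checks by permutation.

Amplitudes are normalized per sample so the median amplitude of matched
internal standards equals a common reference. The identity of the original
internal polypeptide standards is not published; the standard mass set is a
configuration input. A sample matching no standard is *excluded*, not left
unscaled — an unscaled sample would silently distort the rank tests.

## Marker statistics

Only peptides detected in ≥ 70% of at least one diagnostic group are tested
(`freq_threshold`, dimensionless fraction). The test is the two-sided
Wilcoxon rank-sum: for min(n, m) ≤ 8 the exact permutation distribution of
the mid-rank sum is enumerated (all C(n+m, n) splits), because cohorts of
7–10 make the normal approximation marginal; above that, the tie-corrected
normal approximation with continuity correction is used. The two branches
agree within 0.02 at n = m = 8 (tested). Multiplicity is handled by
Benjamini–Hochberg step-up, implemented directly (and cross-checked against
`stats::p.adjust` in the tests); significance is strict `q < α` with
α = 0.05.

A peptide that is detected in some samples but missing in others is scored
as amplitude 0 by default, in both the test and the group means: the
frequency filter implies presence/absence is signal, and zeroes preserve it.
`missing_as_zero = FALSE` switches to dropping missing observations (the
source analysis is silent on this point; both behaviours are available, and
a group left empty under the drop rule skips the peptide with a log entry).
Regulation is the sign of the *mean* amplitude difference. An exact tie
yields no sign; such peptides are flagged `NA` and must be excluded from the
orthology and protease stages, whose logic requires a direction.

## Sequencing QC

Theoretical masses are monoisotopic residue sums plus water; the lowercase
codes p/k/m add one oxygen (+15.9949 Da) to Pro/Lys/Met. The acceptance
window for measured vs theoretical mass is ±80 ppm. CE migration time is
predicted from the basic-residue count (#K + #R + #H of the uppercased
sequence; the N-terminal amine is not counted — the calibration table is
injectable, so any charge convention can be emulated) via linear
interpolation in an expected-time table that must be strictly decreasing
(more positive charge at pH 2 means earlier migration); the acceptance
window is ±2 min. The default table (0→42 min … 6→25.5 min) is a plausible
monotone curve spanning the observed 18–60 min separation window; the true
instrument calibration is not published, which is why the model is a
constructor argument everywhere it is used.

Peptides are mapped to precursors by case-insensitive exact substring
search; *all* occurrences are returned (collagens are repetitive), with up
to three flanking residues per side, shorter at termini. Coordinates are
1-based inclusive on the supplied precursor — whether that FASTA contains
the signal peptide is the caller's choice.

## Orthology tiers

Cleavage contexts are 6-residue strings: 3 precursor residues before the cut
plus 3 after, uppercased — matching is modification-insensitive because
motif tables list unmodified residues while urinary collagen fragments carry
hydroxyprolines at the same positions. A context extracted at a protein
terminus is shorter than 6 and flagged incomplete; incomplete contexts never
count as identical and are skipped by the motif matcher.

Tier 1 requires identical uppercased sequence *and* both contexts identical;
tier 2 at least one identical context; tier 3 a coordinate overlap of ≥ 2
residues after the ortholog map's per-pair offset (default 0; fibrillar
collagens are near-collinear, and an alignment-derived offset can be
supplied instead of a full pairwise alignment). Tier 2 is implemented as "at
least one" rather than "exactly one" identical site so that the tier
predicate is monotone — every tier-1 pair also satisfies tier 2 — and the
reported tier is the highest satisfied. All tiers additionally require the
same regulation direction; flipping one marker's sign removes the match.
In panel comparison each rat marker contributes at most one match (best
tier, ties to the human marker with lowest adjusted p), so tier totals are
disjoint counts — the counting scheme was not published, and one-best-match
prevents double counting.

## Protease-activity inference

The motif database is a local table (bundled: 14 curated collagen alpha-1(I)
cleavage sites with their protease annotations; the live MEROPS/CutDB
services are never queried, for reproducibility). Strict matching is exact
equality; the relaxed search tolerates Hamming distance ≤ 2. For the tally,
strict hits pre-empt relaxed ones, and among relaxed hits only the nearest
distance counts. Each matched site increments every protease *group* its
motif maps to — a site annotated to two groups counts in both, which is
accepted and documented. The default grouping collapses all MMP isoforms
into "MMP" and merges CTSK with F2; ADAMTS5 and anything else stay
separate. Sites are deduplicated per marker at the context-string level.
Direction is the sign of up- vs down-side counts, "unclear" on ties.
Footnote-level source labels (CutDB-only vs MEROPS-only annotations) are
carried in the table but do not affect counting, as their attachment is
ambiguous in the source table.

# The synthetic-study generator

The generator emulates the statistical structure the analysis assumes — it
is a stated world, not a tuning knob.

* **References**: collagen-like Gly-X-Y precursors (default 3 proteins of
  600 residues) with 6-residue cleavage motifs overwritten at evenly spaced
  cut positions (8 per protein, cycling through the bundled motif set with a
  per-protein stride so a few proteins cover all 14 motifs). Rat and human
  orthologs are identical sequences under species-suffixed identifiers —
  deliberately, so tier-1 orthology has planted positives.
* **Fragments**: substrings between pairs of cut sites (adjacent and
  one-skip), so each fragment's re-extracted terminal contexts equal planted
  motifs exactly (a tested invariant). A fragment's true case/control fold
  is the product of its two terminal motifs' planted protease weights
  (release requires both cuts) times a fold-4 factor for 8 randomly chosen
  planted markers. Default weights — ADAMTS5 ×3, MMP ×2, CTSK/F2 ×1/3 in
  cases — plant the qualitative picture the analysis should recover:
  increased ADAMTS5/MMP, decreased CTSK/F2 activity.
* **Sampling**: per sample, a fragment's cleavage-event count is Poisson
  with mean `lambda_base` (20) times its fold (cases) or 1 (controls);
  amplitude = typical abundance × relative count × log-normal noise
  (σ = 0.5, the working log-scale SD) × a per-sample instrument factor
  (σ = 0.2) that internal-standard normalization removes exactly. Detection
  requires ≥ 1 cleavage event and a logistic coin in log-amplitude
  (midpoint log 100, slope 1.5), giving the missingness-at-low-abundance
  structure real CE-MS data show. Measured mass is theoretical ×
  (1 + ε), ε ~ N(0, 10 ppm); measured time is the migration model's
  prediction + N(0, 0.25 min). Group sizes default to 10 cases vs 7
  controls (rat, the late-stage cohort) and 10 vs 10 (human).
* **Truth sidecar**: planted folds, motifs, coordinates and regulation are
  serialized separately and never consumed by analysis stages, preventing
  leakage in tests.

What the generator does *not* emulate: isotope envelopes, charge states,
chemical noise, correlated peptide families from shared precursor turnover,
batch drift in migration time, or realistic panel sizes (thousands of
peptides). A green test therefore establishes algorithmic correctness and
statistical calibration at desk scale, not instrument-level realism.

# Numerical and operational choices

* Window functions are clamped interpolations; continuity at the breakpoints
  and monotonicity are tested.
* Exact rank-sum enumeration uses mid-ranks with a 1e-9 slack when
  comparing tied rank sums; the two-sided p is 2·min(P≤, P≥) capped at 1,
  which reproduces `wilcox.test(exact = TRUE)` on untied data.
* Degenerate inputs: empty feature tables cluster to empty output (not an
  error); zero noise sigmas reproduce theoretical masses and model times
  exactly; a panel emptied by filtering produces an empty tally with a
  warning.
* Determinism: every stochastic operation derives its RNG state from the
  configuration seed and restores the caller's RNG; a fixed configuration
  reproduces all serialized outputs byte-for-byte (tested).
* Monte-Carlo budgets: the null-calibration check uses 200 replicates of
  desk-scale studies (2 proteins, 5 cuts) and the recovery checks 20 and
  100 replicates with 10-vs-10 groups; sizes were scaled down for test-time
  budget, not re-scaled after observing outcomes. Planted-marker recovery is
  estimated over 20 replicates (160 planted markers) because a single study
  plants only 8 markers, making the estimate's granularity (12.5%) coarser
  than the 90% criterion it is compared against.

# Known limitations

* Ortholog declarations are inputs; no de novo ortholog detection.
* Tier-3 overlap uses raw coordinates plus a scalar offset, not alignment.
* The migration-time predictor is a stand-in calibration, injectable but not
  fitted to instrument data.
* Protease inference counts motif co-occurrence; it is not kinetic evidence,
  and group-level double counting slightly favours promiscuous motifs.
* With default settings the two species share identical reference sequences,
  so cross-species results exercise the machinery rather than simulate real
  rat/human sequence divergence; supply species-specific FASTA and a
  non-trivial ortholog map for the latter.
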