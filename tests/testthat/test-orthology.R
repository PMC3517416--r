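test_that("cleavage contexts are 3+3 residues around each cut, uppercased", {
  panel <- data.frame(sequence = "QGAkG", protein_id = "P1",
                      protein_name = "P1", start = 7L, stop = 11L,
                      p_adjusted = 0.01, mean_amp_case = 2,
                      mean_amp_control = 1, regulation = "up",
                      stringsAsFactors = FALSE)
  panel <- qc_markers(panel, c(P1 = FIXTURE_PROTEIN))
  panel <- cleavage_contexts(panel)
  expect_equal(panel$n_context6, "PGKQGA")  # matches a published motif string
  expect_equal(panel$c_context6, "AKGEPG")
  expect_true(panel$n_complete && panel$c_complete)
})

test_that("contexts at protein termini are flagged incomplete", {
  panel <- data.frame(sequence = c("MKT", "EPG", "KTP"),
                      protein_id = "P1", protein_name = "P1",
                      start = c(1L, 12L, 2L), stop = c(3L, 14L, 4L),
                      p_adjusted = 0.01, mean_amp_case = 2,
                      mean_amp_control = 1, regulation = "up",
                      stringsAsFactors = FALSE)
  panel <- cleavage_contexts(qc_markers(panel, c(P1 = FIXTURE_PROTEIN)))
  expect_false(panel$n_complete[1])   # starts at position 1
  expect_false(panel$c_complete[2])   # ends at the C-terminus
  # a 3-residue peptide serves both context halves
  expect_equal(panel$n_context6[3], "MKTP")  # only 1 flank residue: incomplete
  expect_false(panel$n_complete[3])
  expect_equal(panel$c_context6[3], "KTPGKQ")
  expect_true(panel$c_complete[3])
})

test_that("tier assignment follows the three-tier rules with regulation gate", {
  omap <- data.frame(rat_id = "R", human_id = "H", offset = 0L)
  base <- function(...) make_marker(..., protein_id = "R")
  hum <- function(...) make_marker(..., protein_id = "H")
  r1 <- base("QGAKG", start = 7, stop = 11, n_ctx = "PGKQGA", c_ctx = "AKGEPG")
  # identical sequence + both contexts -> tier 1
  h1 <- hum("QGAKG", start = 7, stop = 11, n_ctx = "PGKQGA", c_ctx = "AKGEPG")
  expect_equal(tier_match(r1, h1, omap), 1L)
  # one shared context, different sequence -> tier 2
  h2 <- hum("QGAKGAA", start = 7, stop = 13, n_ctx = "PGKQGA",
            c_ctx = "GAAXYZ")
  expect_equal(tier_match(r1, h2, omap), 2L)
  # coordinate overlap of exactly 2 residues -> tier 3; 1 residue -> none
  r3 <- base("X", start = 100, stop = 120, n_ctx = "AAAAAA", c_ctx = "BBBBBB",
             regulation = "down")
  h3 <- hum("Y", start = 119, stop = 140, n_ctx = "CCCCCC", c_ctx = "DDDDDD",
            regulation = "down")
  expect_equal(tier_match(r3, h3, omap), 3L)
  h3$map_start <- 120
  expect_true(is.na(tier_match(r3, h3, omap)))
  # regulation disagreement removes any match
  h1_down <- h1; h1_down$regulation <- "down"
  expect_true(is.na(tier_match(r1, h1_down, omap)))
  # proteins not declared orthologous -> none
  expect_true(is.na(tier_match(r1, h1,
                               data.frame(rat_id = "Z", human_id = "H",
                                          offset = 0L))))
})

test_that("tier predicate is symmetric under map inversion", {
  omap <- data.frame(rat_id = "R", human_id = "H", offset = 0L)
  inv <- data.frame(rat_id = "H", human_id = "R", offset = 0L)
  r <- make_marker("QGAKG", "R", 7, 11, "PGKQGA", "AKGEPG")
  hs <- list(
    make_marker("QGAKG", "H", 7, 11, "PGKQGA", "AKGEPG"),
    make_marker("QGAKGAA", "H", 7, 13, "PGKQGA", "GAAXYZ"),
    make_marker("ZZZZ", "H", 9, 14, "UUUUUU", "VVVVVV"))
  for (h in hs) {
    expect_identical(tier_match(r, h, omap), tier_match(h, r, inv))
  }
})

test_that("per-pair coordinate offset shifts the tier-3 overlap computation", {
  omap <- data.frame(rat_id = "R", human_id = "H", offset = 19L)
  r <- make_marker("X", "R", 100, 120, "AAAAAA", "BBBBBB")
  h <- make_marker("Y", "H", 138, 160, "CCCCCC", "DDDDDD")
  expect_equal(tier_match(r, h, omap), 3L)  # 100+19..139 vs 138.. -> 2 overlap
})

test_that("compare_panels counts disjoint best-tier matches", {
  omap <- identity_ortholog_map("P")
  t1r <- make_marker("QGAKG", "P", 7, 11, "PGKQGA", "AKGEPG")
  t1h <- t1r
  t2r <- make_marker("AAGGA", "P", 40, 44, "PGPSGK", "GGAXXX")
  t2h <- make_marker("AAGGAQQ", "P", 40, 46, "PGPSGK", "QQYYAA")
  t3r <- make_marker("LLLL", "P", 200, 220, "EEEEEE", "FFFFFF")
  t3h <- make_marker("MMMM", "P", 219, 230, "GGGGGG", "HHHHHH")
  rat <- rbind(t1r, t2r, t3r)
  hum <- rbind(t1h, t2h, t3h)
  cmp <- compare_panels(rat, hum, omap)
  expect_equal(unname(cmp$tier_counts), c(1L, 1L, 1L))
  # feeding a panel against itself under an identity map: all tier 1
  self <- compare_panels(rbind(t1r), rbind(t1r), omap)
  expect_equal(unname(self$tier_counts), c(1L, 0L, 0L))
  # disjoint proteins -> zero matches
  hum2 <- hum; hum2$protein_id <- "Q"
  expect_equal(sum(compare_panels(rat, hum2, omap)$tier_counts), 0L)
  # regulation summary tallies per precursor and species
  expect_true(all(c("rat", "human") %in% cmp$regulation_summary$species))
  expect_equal(sum(cmp$regulation_summary$n_up[
    cmp$regulation_summary$species == "rat"]), 3L)
})

test_that("select_top_markers is deterministic under ties", {
  panel <- data.frame(sequence = c("B", "A", "C"),
                      p_adjusted = c(0.01, 0.01, 0.5),
                      mean_amp_case = c(4, 2, 1), mean_amp_control = c(1, 1, 1),
                      stringsAsFactors = FALSE)
  top2 <- select_top_markers(panel, 2)
  expect_equal(top2$sequence, c("B", "A"))  # tie broken by larger |log FC|
  expect_identical(select_top_markers(panel, 2), top2)
  expect_warning(all3 <- select_top_markers(panel, 50), "only 3")
  expect_equal(nrow(all3), 3L)
})
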