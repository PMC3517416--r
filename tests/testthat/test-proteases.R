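test_that("bundled motif database loads the curated collagen cleavage sites", {
  db <- load_motif_db()
  expect_s3_class(db, "motif_db")
  expect_equal(nrow(db), 14L)
  expect_setequal(db$proteases[[match("PGKQGA", db$context6)]],
                  c("MMP2", "MMP3", "MMP8", "MMP12", "MMP13"))
  expect_equal(db$proteases[[match("PGPSGK", db$context6)]], "ADAMTS5")
  expect_setequal(db$proteases[[match("GPRGPP", db$context6)]],
                  c("CTSK", "F2"))
})

test_that("malformed motif rows are rejected; duplicates are merged", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("context6\tproteases", "PGKQG\tMMP2"), bad)
  expect_error(load_motif_db(bad), "row 1")
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("context6\tproteases", "PGKQGA\tMMP2", "PGKQGA\tMMP9"), dup)
  db <- load_motif_db(dup)
  expect_equal(nrow(db), 1L)
  expect_setequal(db$proteases[[1]], c("MMP2", "MMP9"))
  empty <- tempfile(fileext = ".tsv")
  writeLines(c("context6\tproteases", "PGKQGA\t"), empty)
  expect_error(load_motif_db(empty), "empty protease")
})

test_that("strict and relaxed matching follow Hamming distance", {
  db <- load_motif_db()
  strict <- match_site("PGKQGA", db)
  expect_setequal(strict$protease, c("MMP2", "MMP3", "MMP8", "MMP12",
                                     "MMP13"))
  expect_true(all(strict$mode == "strict"))
  relaxed <- match_site("PGKQGG", db, max_mismatches = 2L)
  expect_true("PGKQGA" %in% relaxed$motif)
  expect_equal(min(relaxed$mismatches[relaxed$motif == "PGKQGA"]), 1L)
  # AAAAAA is >= 3 substitutions from every bundled motif (brute-force scan)
  dists <- vapply(db$context6, function(m) {
    sum(strsplit(m, "")[[1]] != strsplit("AAAAAA", "")[[1]])
  }, integer(1))
  expect_true(all(dists >= 3L))
  expect_equal(nrow(match_site("AAAAAA", db, max_mismatches = 2L)), 0L)
  expect_error(match_site("PGKQG", db), "6 residues")
})

test_that("strict matches are a subset of relaxed matches", {
  db <- load_motif_db()
  set.seed(17)
  aas <- strsplit("GASPVTLINDQKEMHFRYW", "")[[1]]
  for (r in 1:30) {
    ctx <- paste(sample(aas, 6, replace = TRUE), collapse = "")
    s0 <- match_site(ctx, db, 0L)
    for (mm in 1:2) {
      sm <- match_site(ctx, db, mm)
      expect_true(all(paste(s0$motif, s0$protease) %in%
                        paste(sm$motif, sm$protease)))
      # relaxed matcher equals an all-pairs Hamming scan
      expect_setequal(unique(sm$motif), db$context6[vapply(db$context6,
        function(m) sum(strsplit(m, "")[[1]] !=
                          strsplit(ctx, "")[[1]]) <= mm, logical(1))])
    }
  }
})

make_tally_panel <- function(c_contexts, regulation) {
  n <- length(c_contexts)
  data.frame(sequence = sprintf("PEP%02d", seq_len(n)),
             protein_id = "COL1A1", protein_name = "COL1A1",
             regulation = regulation,
             n_context6 = sprintf("ZZZZZ%d", seq_len(n) %% 10),  # unmatched
             c_context6 = c_contexts,
             n_complete = FALSE, c_complete = TRUE,
             mapped = TRUE, stringsAsFactors = FALSE)
}

test_that("activity tally counts sites by regulation side and infers direction", {
  db <- load_motif_db()
  panel <- make_tally_panel(c("PGPSGK", "PGPSGK", "PGPSGK", "PGPAGP"),
                            c("up", "up", "up", "down"))
  res <- tally_activity(panel, db, max_mismatches = 0L)
  row <- res$tally[res$tally$protease_group == "ADAMTS5", ]
  expect_equal(row$n_sites_up, 3L)
  expect_equal(row$n_sites_down, 1L)
  expect_equal(row$direction, "increased")
  # tally conservation: up + down = matched (site, group) pairs
  expect_equal(sum(res$tally$n_sites_up + res$tally$n_sites_down),
               nrow(res$provenance))  # one group per provenance row here
  # flipping every regulation swaps the sides and the direction
  flipped <- panel
  flipped$regulation <- ifelse(panel$regulation == "up", "down", "up")
  res2 <- tally_activity(flipped, db, max_mismatches = 0L)
  row2 <- res2$tally[res2$tally$protease_group == "ADAMTS5", ]
  expect_equal(row2$n_sites_up, row$n_sites_down)
  expect_equal(row2$n_sites_down, row$n_sites_up)
  expect_equal(row2$direction, "decreased")
})

test_that("tally deduplicates repeated contexts per marker and honors filters", {
  db <- load_motif_db()
  panel <- make_tally_panel("PGPSGK", "up")
  panel$n_context6 <- "PGPSGK"  # same context at both termini
  panel$n_complete <- TRUE
  res <- tally_activity(panel, db, max_mismatches = 0L)
  expect_equal(res$tally$n_sites_up[res$tally$protease_group == "ADAMTS5"],
               1L)  # counted once
  other <- make_tally_panel("PGPSGK", "up")
  other$protein_id <- "ALBU"; other$protein_name <- "ALBU"
  both <- rbind(panel, other)
  res3 <- tally_activity(both, db, protein_filter = "COL1A1",
                         max_mismatches = 0L)
  expect_equal(sum(res3$tally$n_sites_up), 1L)
  expect_warning(tally_activity(both[0, ], db), "empty panel")
})

test_that("default grouping collapses MMP isoforms and merges CTSK with F2", {
  expect_equal(default_protease_grouping(c("MMP2", "MMP13", "ADAMTS5",
                                           "CTSK", "F2")),
               c("MMP", "MMP", "ADAMTS5", "CTSK/F2", "CTSK/F2"))
})
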