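test_that("tolerance windows reproduce the anchors and interpolate linearly", {
  expect_equal(mass_tolerance(3000), 50)
  expect_equal(mass_tolerance(7000), 150)
  expect_equal(mass_tolerance(5000), 100)  # midpoint of the ramp
  expect_equal(time_tolerance(19), 1.0)
  expect_equal(time_tolerance(50), 2.5)
  expect_equal(time_tolerance(34.5), 1.75)
  expect_error(mass_tolerance(0), "positive")
  expect_error(time_tolerance(-1), "positive")
})

test_that("tolerance functions are continuous at breakpoints and monotone", {
  for (bp in c(4000, 6000)) {
    expect_equal(mass_tolerance(bp - 1e-6), mass_tolerance(bp + 1e-6),
                 tolerance = 1e-3)
  }
  for (bp in c(19, 50)) {
    expect_equal(time_tolerance(bp - 1e-6), time_tolerance(bp + 1e-6),
                 tolerance = 1e-3)
  }
  m <- seq(801, 24000, length.out = 500)
  expect_true(all(diff(mass_tolerance(m)) >= 0))
  t <- seq(1, 70, length.out = 500)
  expect_true(all(diff(time_tolerance(t)) >= 0))
})

test_that("internal-standard normalization rescales without distorting ratios", {
  std <- 1000
  f <- make_features(rep(c("a", "b"), each = 3),
                     rep(c(std, 1500, 2000), 2),
                     rep(c(25, 30, 35), 2),
                     c(100, 40, 60,    # sample a: standard at 100
                       200, 80, 120))  # sample b: everything doubled
  out <- normalize_amplitudes(f, std, reference = 100)
  a <- out$features[out$features$sample_id == "a", ]
  b <- out$features[out$features$sample_id == "b", ]
  expect_equal(b$amplitude, a$amplitude)  # sample b halved onto a's scale
  # within-sample ratios unchanged
  expect_equal(b$amplitude[2] / b$amplitude[3], 80 / 120)
  # already at reference -> identity
  out2 <- normalize_amplitudes(f[f$sample_id == "a", ], std, reference = 100)
  expect_equal(out2$features$amplitude, c(100, 40, 60))
})

test_that("samples without a matched standard are excluded, not left unscaled", {
  f <- make_features(c("a", "a", "b"), c(1000, 1500, 5000), c(25, 30, 40),
                     c(100, 40, 7))
  expect_message(out <- normalize_amplitudes(f, 1000, reference = 100),
                 "no internal standard")
  expect_equal(out$excluded_samples, "b")
  expect_false("b" %in% out$features$sample_id)
  expect_error(
    suppressMessages(normalize_amplitudes(f[3, ], 1000)),
    "no sample")
})

test_that("clustering merges within windows and splits outside them", {
  # 30 ppm mass gap and 0.5 min time gap: both inside -> one cluster
  f <- make_features(c("s1", "s2"), c(1000.000, 1000.030), c(25.0, 25.5),
                     c(10, 9))
  cs <- cluster_features(f)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$n_members, 2L)
  # 100 ppm gap at 1 kDa exceeds the 50 ppm window -> two clusters
  f2 <- make_features(c("s1", "s2"), c(1000.000, 1000.100), c(25.0, 25.0),
                      c(10, 9))
  expect_equal(nrow(cluster_features(f2)$clusters), 2L)
  # single feature -> one cluster, detected in its group with frequency 1
  f3 <- make_features("s1", 1200, 30, 5)
  cs3 <- cluster_features(f3)
  expect_equal(nrow(cs3$clusters), 1L)
  fr <- detection_frequencies(cs3, c(s1 = "case"))
  expect_equal(fr$freq_case, 1)
  # empty input is not an error
  expect_equal(nrow(cluster_features(f3[0, ])$clusters), 0L)
})

test_that("a cluster keeps at most one feature per sample", {
  # two features of the same sample near one location: nearer (and stronger)
  # keeps the slot, the other founds its own cluster
  f <- make_features(c("s1", "s1", "s2"),
                     c(1000.000, 1000.020, 1000.002),
                     c(25.0, 25.0, 25.0), c(10, 8, 9))
  cs <- cluster_features(f)
  expect_equal(nrow(cs$clusters), 2L)
  tab <- table(cs$members$cluster_id, cs$members$sample_id)
  expect_true(all(tab <= 1))
})

test_that("every member lies within the tolerance window of its representative", {
  study <- simulate_study(simulation_config(seed = 3))
  feat <- study$samples$rat$features
  cs <- cluster_features(feat)
  reps <- cs$clusters[cs$members$cluster_id, ]
  dmass_ppm <- abs(cs$members$mass_da - reps$mass_da) / reps$mass_da * 1e6
  dtime <- abs(cs$members$migration_min - reps$migration_min)
  expect_true(all(dmass_ppm <= mass_tolerance(reps$mass_da) + 1e-9))
  expect_true(all(dtime <= time_tolerance(reps$migration_min) + 1e-9))
})

test_that("cluster count is order-independent for well-separated features", {
  set.seed(99)
  masses <- seq(1000, 3000, by = 100)  # gaps >> 50 ppm windows
  f <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(s) {
    make_features(s, masses * (1 + rnorm(length(masses), 0, 5e-6)),
                  25 + rnorm(length(masses), 0, 0.1),
                  runif(length(masses), 1, 100))
  }))
  n_ref <- nrow(cluster_features(f)$clusters)
  for (r in 1:5) {
    perm <- f[sample(nrow(f)), ]
    expect_equal(nrow(cluster_features(perm)$clusters), n_ref)
  }
  expect_equal(n_ref, length(masses))
})
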