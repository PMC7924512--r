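test_that("RR intervals are consecutive R-peak differences in seconds", {
  expect_equal(compute_rr_intervals(c(0, 360, 720), 360), c(1, 1))
  expect_equal(compute_rr_intervals(c(0, 288), 360), 0.8)
  expect_error(compute_rr_intervals(c(10, 10, 20), 360), "increasing")
  expect_error(compute_rr_intervals(5, 360), "two")
})

test_that("interval sums telescope to the total span", {
  set.seed(21)
  for (k in 1:20) {
    r <- sort(sample.int(100000, sample(5:60, 1)))
    iv <- compute_rr_intervals(r, 360)
    expect_equal(sum(iv), (max(r) - min(r)) / 360, tolerance = 1e-12)
  }
})

test_that("a metronomic rhythm yields constant features and unit ratio", {
  r <- seq(0, by = 288, length.out = 30)  # 0.8 s at 360 Hz
  f <- extract_rr_features(r, 360)
  expect_true(all(abs(f$prev_rr_s - 0.8) < 1e-12))
  expect_true(all(abs(f$post_rr_s - 0.8) < 1e-12))
  expect_true(all(abs(f$ratio_rr - 1) < 1e-12))
  expect_true(all(abs(f$local_rr_s - 0.8) < 1e-12))
  norm <- normalize_rr_features(f, 0.8)
  expect_true(all(abs(as.matrix(norm) -
                        matrix(rep(c(0, 0, 1, 0), each = 30), 30)) < 1e-12))
})

test_that("hand-computed features match at irregular spacing", {
  f <- extract_rr_features(c(0, 300, 650, 950), 360, beat_position = 3)
  expect_equal(f$prev_rr_s, 350 / 360, tolerance = 1e-12)
  expect_equal(f$post_rr_s, 300 / 360, tolerance = 1e-12)
  expect_equal(f$ratio_rr, 350 / 300, tolerance = 1e-12)
  expect_equal(f$local_rr_s, mean(c(300, 350) / 360), tolerance = 1e-12)
})

test_that("normalization subtracts the record mean except from the ratio", {
  f <- tibble::tibble(prev_rr_s = 0.9722, post_rr_s = 0.8333,
                      ratio_rr = 1.1667, local_rr_s = 0.85)
  norm <- normalize_rr_features(f, 0.85)
  expect_equal(norm$prev_rr_s, 0.1222, tolerance = 1e-9)
  expect_equal(norm$post_rr_s, -0.0167, tolerance = 1e-9)
  expect_equal(norm$ratio_rr, 1.1667, tolerance = 1e-12)  # untouched
  expect_equal(norm$local_rr_s, 0, tolerance = 1e-12)
  expect_error(normalize_rr_features(f, 0), "positive")
})

test_that("ratio is invariant under normalization for random rhythms", {
  set.seed(22)
  r <- cumsum(sample(200:500, 40))
  f <- extract_rr_features(r, 360)
  norm <- normalize_rr_features(f, 0.77)
  expect_equal(norm$ratio_rr, f$ratio_rr)
})

test_that("local RR averages at most the 10 preceding intervals", {
  iv <- c(rep(0.5, 12), rep(1, 3)) * 360      # samples
  r <- cumsum(c(0, iv))
  f <- extract_rr_features(r, 360)
  # beat 16: preceding intervals are 2 x 0.5 s short of all-1 s
  expect_equal(f$local_rr_s[16], mean(c(rep(0.5, 7), rep(1, 3))),
               tolerance = 1e-12)
  # beat 3 has exactly two preceding intervals
  expect_equal(f$local_rr_s[3], 0.5, tolerance = 1e-12)
  # beat 1 has none: record mean imputed
  expect_equal(f$local_rr_s[1], mean(iv) / 360, tolerance = 1e-12)
})

test_that("features are per-record: cohort processing order is irrelevant", {
  cfg <- synthetic_config(duration_s = 60, seed = 19)
  recs <- simulate_cohort(3, cfg, seed = 23)
  fwd <- prepare_cohort(recs)
  rev_ <- prepare_cohort(rev(recs))
  fwd <- dplyr::arrange(fwd, record_id, r_index)
  rev_ <- dplyr::arrange(rev_, record_id, r_index)
  expect_equal(fwd$prev_rr_s, rev_$prev_rr_s)
  expect_equal(fwd$local_rr_s, rev_$local_rr_s)
  expect_equal(fwd$segment, rev_$segment)
})
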