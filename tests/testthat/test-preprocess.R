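test_that("median windows are the odd sample counts nearest the ms widths", {
  expect_equal(median_window_samples(200, 360), 73)
  expect_equal(median_window_samples(600, 360), 217)
  expect_equal(median_window_samples(200, 250), 51)  # round(50) -> 50 -> 51
})

test_that("constant and zero signals are their own baseline", {
  expect_equal(estimate_baseline(rep(2.5, 400), 360), rep(2.5, 400))
  expect_equal(estimate_baseline(numeric(400), 360), numeric(400))
})

test_that("an isolated impulse train leaves a zero baseline", {
  x <- numeric(2000)
  x[seq(100, 2000, by = 500)] <- 1  # width 1, spacing >> 600-ms window
  expect_equal(estimate_baseline(x, 360), numeric(2000))
})

test_that("cascaded medians match the brute-force sliding-median oracle", {
  set.seed(31)
  for (k in 1:6) {
    n <- sample(250:1200, 1)
    x <- cumsum(rnorm(n)) + rnorm(n)
    expect_equal(estimate_baseline(x, 360), oracle_baseline(x, 360),
                 tolerance = 1e-12)
  }
  # a non-MIT sampling rate exercises different window sizes
  x <- rnorm(700)
  expect_equal(estimate_baseline(x, 128), oracle_baseline(x, 128),
               tolerance = 1e-12)
})

test_that("baseline removal is shift-invariant and flattens slow drift", {
  set.seed(32)
  s <- rnorm(1500)
  expect_equal(remove_baseline(s + 3.7, 360), remove_baseline(s, 360),
               tolerance = 1e-10)
  # pure 5-s sinusoid: almost everything is baseline. Away from the
  # reflect-padded record ends (one 600-ms window) the residual is tiny.
  t <- (0:3599) / 360
  drift <- sin(2 * pi * t / 5)
  resid <- abs(remove_baseline(drift, 360))
  expect_lt(max(resid[218:(3600 - 217)]), 0.1)
})

test_that("short signals are rejected", {
  expect_error(estimate_baseline(rnorm(100), 360), "600-ms")
})

test_that("corrected beats from a wandering record are centered near zero", {
  cfg <- synthetic_config(duration_s = 60, wander_amplitude = 0.4,
                          noise_sd = 0, seed = 6)
  rec <- simulate_record(cfg)
  corrected <- remove_baseline(rec$signal, rec$sampling_rate_hz)
  segs <- segment_heartbeats(corrected, rec$annotations, record_id = "w")
  med <- vapply(segs$segment, stats::median, numeric(1))
  expect_lt(max(abs(med)), 0.1)  # beat windows sit near zero, unlike the raw
  raw_segs <- segment_heartbeats(rec$signal, rec$annotations, record_id = "w")
  raw_med <- vapply(raw_segs$segment, stats::median, numeric(1))
  expect_gt(max(abs(raw_med)), max(abs(med)))
})

test_that("segmentation uses the half-open 0-based [r-90, r+110) window", {
  sig <- seq_len(200) * 1.0
  ann <- tibble::tibble(sample = 90L, symbol = "N")
  segs <- segment_heartbeats(sig, ann)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$segment[[1]], sig)     # the entire signal
  expect_equal(attr(segs, "n_dropped"), 0)

  # one sample earlier and the window would underflow: dropped, counted
  segs2 <- segment_heartbeats(sig, tibble::tibble(sample = 89L, symbol = "N"))
  expect_equal(nrow(segs2), 0)
  expect_equal(attr(segs2, "n_dropped"), 1)
})

test_that("kept plus dropped always equals the input beat count", {
  rec <- small_record()
  segs <- segment_heartbeats(rec$signal, rec$annotations,
                             record_id = rec$record_id)
  expect_equal(nrow(segs) + attr(segs, "n_dropped"), nrow(rec$annotations))
  expect_true(all(lengths(segs$segment) == 200))
})

test_that("windows not totalling 200 samples are a configuration error", {
  expect_error(segment_heartbeats(rnorm(300),
                                  tibble::tibble(sample = 150L, symbol = "N"),
                                  pre = 100, post = 110),
               "200")
})
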