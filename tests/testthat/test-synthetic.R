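test_that("noise-free all-normal generation places the expected beat count", {
  cfg <- synthetic_config(duration_s = 60, class_proportions = c(1, 0, 0, 0),
                          rr_jitter_sd_s = 0, wander_amplitude = 0,
                          noise_sd = 0, seed = 3)
  rec <- simulate_record(cfg)
  expected <- floor(60 / 0.8)
  expect_gte(nrow(rec$annotations), expected - 1)
  expect_lte(nrow(rec$annotations), expected + 1)
  expect_true(all(rec$annotations$symbol == "N"))
  expect_true(all(map_annotation_symbol(rec$annotations$symbol) == "N"))
})

test_that("generation is reproducible given the seed", {
  cfg <- synthetic_config(duration_s = 40, seed = 11)
  a <- simulate_record(cfg); b <- simulate_record(cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$annotations, b$annotations)
  c <- simulate_record(synthetic_config(duration_s = 40, seed = 12))
  expect_false(identical(a$signal, c$signal))
})

test_that("class frequencies track the requested proportions", {
  p <- c(0.89, 0.03, 0.07, 0.01)
  cfg <- synthetic_config(duration_s = 1605, class_proportions = p, seed = 5)
  rec <- simulate_record(cfg)
  n <- nrow(rec$annotations)
  expect_gte(n, 1900)
  freq <- table(factor(rec$annotations$symbol, levels = c("N", "A", "V", "F")))
  for (k in 1:4) {
    se <- sqrt(p[k] * (1 - p[k]) / n)
    expect_lt(abs(freq[k] / n - p[k]), 3 * se + 1 / n)  # 3 binomial SEs
  }
})

test_that("a clean record has a near-zero estimated baseline", {
  cfg <- synthetic_config(duration_s = 30, wander_amplitude = 0, noise_sd = 0,
                          seed = 8)
  rec <- simulate_record(cfg)
  base <- estimate_baseline(rec$signal, rec$sampling_rate_hz)
  expect_lt(max(abs(base)), 0.05 * max(rec$signal))  # < 5% of QRS amplitude
})

test_that("SVEB beats are premature: previous RR below the record mean", {
  cfg <- synthetic_config(duration_s = 240,
                          class_proportions = c(0.8, 0.2, 0, 0), seed = 13)
  rec <- simulate_record(cfg)
  iv <- compute_rr_intervals(rec$annotations$sample, rec$sampling_rate_hz)
  mean_rr <- mean(iv)
  sveb_pos <- which(rec$annotations$symbol == "A")
  sveb_pos <- sveb_pos[sveb_pos > 1]
  expect_gt(length(sveb_pos), 5)
  expect_true(all(iv[sveb_pos - 1] < mean_rr))
})

test_that("VEB beats have a wider QRS than normal beats", {
  cfg <- synthetic_config(duration_s = 240,
                          class_proportions = c(0.7, 0, 0.3, 0),
                          wander_amplitude = 0, noise_sd = 0, seed = 17)
  rec <- simulate_record(cfg)
  width_at_half <- function(r) {
    w <- rec$signal[(r - 35):(r + 37)]  # 0-based r -> 1-based window
    sum(w > max(w) / 2) / rec$sampling_rate_hz
  }
  ann <- rec$annotations[rec$annotations$sample > 40, ]
  wN <- mean(vapply(ann$sample[ann$symbol == "N"] + 1, width_at_half, numeric(1)))
  wV <- mean(vapply(ann$sample[ann$symbol == "V"] + 1, width_at_half, numeric(1)))
  expect_gt(wV, 1.5 * wN)
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(class_proportions = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  expect_error(synthetic_config(wander_period_s = 0.5), "0.6")
  expect_error(simulate_record(synthetic_config(duration_s = 6)),
               "at least 12")
})
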