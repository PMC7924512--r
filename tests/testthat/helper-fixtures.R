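# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# quiet 2-minute record with all noise sources on (default config)
small_record <- function() {
  fixture("small_record", function() {
    simulate_record(synthetic_config(duration_s = 120, seed = 42), "small")
  })
}

# tiny cohort for training smoke tests: ~1,100 well-separated beats
smoke_beats <- function() {
  fixture("smoke_beats", function() {
    cfg <- synthetic_config(
      duration_s = 150, seed = 7,
      class_proportions = c(0.55, 0.15, 0.2, 0.1),  # balanced enough to learn fast
      noise_sd = 0.01, wander_amplitude = 0.05
    )
    recs <- simulate_cohort(6, cfg, seed = 21, record_prefix = "smk")
    prepare_cohort(recs)
  })
}

smoke_test_beats <- function() {
  fixture("smoke_test_beats", function() {
    cfg <- synthetic_config(
      duration_s = 150, seed = 7,
      class_proportions = c(0.55, 0.15, 0.2, 0.1),
      noise_sd = 0.01, wander_amplitude = 0.05
    )
    recs <- simulate_cohort(2, cfg, seed = 77, record_prefix = "smkheld")
    prepare_cohort(recs)
  })
}

# brute-force two-pass sliding-median oracle (explicit windows + reflect
# padding), independent of the runmed-based implementation
oracle_median_pass <- function(x, w) {
  n <- length(x); h <- w %/% 2
  xp <- c(rev(x[seq_len(h)]), x, rev(x[seq.int(n - h + 1, n)]))
  vapply(seq_len(n), function(i) stats::median(xp[i:(i + w - 1)]), numeric(1))
}

oracle_baseline <- function(x, fs) {
  odd <- function(w) if (w %% 2 == 0) w + 1 else w
  w200 <- odd(round(0.2 * fs)); w600 <- odd(round(0.6 * fs))
  oracle_median_pass(oracle_median_pass(x, w200), w600)
}
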