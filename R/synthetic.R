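#' Configuration for the synthetic ECG generator
#'
#' The generator emulates the features of an ambulatory single-lead recording
#' that matter downstream: periodic beats with P/QRS/T morphology, labeled
#' R-peak sample indices carrying MIT-BIH annotation symbols, low-frequency
#' baseline wander, additive broadband noise, class-dependent RR timing
#' (premature supraventricular and ventricular beats), and a four-class
#' imbalance comparable to the MIT-BIH AAMI breakdown (about 89% N, 2.8%
#' SVEB, 7% VEB, 0.8% F).
#'
#' @param sampling_rate_hz Sampling frequency in Hz (default 360, the MIT-BIH
#'   rate).
#' @param duration_s Record duration in seconds. Must allow at least 12 beats
#'   at `mean_rr_s` (the local-RR feature looks back over 10 intervals).
#' @param class_proportions Four non-negative numbers summing to 1, the
#'   sampling probabilities over (N, SVEB, VEB, F).
#' @param mean_rr_s Mean RR interval in seconds (default 0.8, i.e. 75 bpm).
#' @param rr_jitter_sd_s Gaussian jitter of each nominal RR interval.
#' @param wander_amplitude Peak amplitude (mV) of the baseline wander.
#' @param wander_period_s Shortest wander period in seconds; must exceed
#'   0.6 s so the wander survives the 600-ms median filter while beat
#'   complexes do not.
#' @param noise_sd Standard deviation (mV) of additive white noise.
#' @param sveb_prematurity Factor (< 1) by which an SVEB beat shortens its
#'   previous RR interval; the following beat stays on schedule, giving a
#'   compensatory pause.
#' @param veb_prematurity Same for VEB beats.
#' @param seed Integer seed; generation is fully reproducible given the seed.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(sampling_rate_hz = 360,
                             duration_s = 120,
                             class_proportions = c(N = 0.895, SVEB = 0.0275,
                                                   VEB = 0.0695, F = 0.008),
                             mean_rr_s = 0.8,
                             rr_jitter_sd_s = 0.04,
                             wander_amplitude = 0.15,
                             wander_period_s = 3.3,
                             noise_sd = 0.03,
                             sveb_prematurity = 0.60,
                             veb_prematurity = 0.75,
                             seed = 1L) {
  if (length(class_proportions) != 4L || any(class_proportions < 0)) {
    abort("`class_proportions` must be 4 non-negative numbers over (N, SVEB, VEB, F).")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1 (within 1e-9).")
  }
  if (wander_period_s <= 0.6) {
    abort("`wander_period_s` must exceed 0.6 s (the wider median-filter width).")
  }
  stopifnot(sampling_rate_hz > 0, duration_s > 0, mean_rr_s > 0,
            rr_jitter_sd_s >= 0, wander_amplitude >= 0, noise_sd >= 0,
            sveb_prematurity > 0, sveb_prematurity < 1,
            veb_prematurity > 0, veb_prematurity < 1)
  structure(
    list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
         class_proportions = unname(class_proportions), mean_rr_s = mean_rr_s,
         rr_jitter_sd_s = rr_jitter_sd_s, wander_amplitude = wander_amplitude,
         wander_period_s = wander_period_s, noise_sd = noise_sd,
         sveb_prematurity = sveb_prematurity, veb_prematurity = veb_prematurity,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Evaluate code under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gaussian-bump morphology per AAMI class: columns amp (mV), mu (s, relative
# to the R apex), sd (s). Implementation constants; VEB has a wide, P-less
# QRS with discordant T, F blends normal and ventricular shapes.
beat_morphology <- function(class_idx, amplitude_scale = 1) {
  shape <- switch(class_idx,
    # N: full P-QRS-T
    rbind(c( 0.15, -0.200, 0.025),   # P
          c(-0.12, -0.033, 0.010),   # Q
          c( 1.00,  0.000, 0.012),   # R
          c(-0.25,  0.030, 0.012),   # S
          c( 0.35,  0.220, 0.045)),  # T
    # SVEB: premature atrial beat - small early P, normal QRS-T
    rbind(c( 0.08, -0.150, 0.018),
          c(-0.12, -0.033, 0.010),
          c( 1.00,  0.000, 0.012),
          c(-0.25,  0.030, 0.012),
          c( 0.35,  0.220, 0.045)),
    # VEB: no P, wide QRS, deep slurred S, inverted T
    rbind(c( 1.10,  0.000, 0.032),
          c(-0.55,  0.060, 0.030),
          c(-0.35,  0.280, 0.055)),
    # F: fusion of ventricular and normal morphology
    rbind(c( 0.07, -0.200, 0.025),
          c(-0.06, -0.033, 0.010),
          c( 1.05,  0.000, 0.022),
          c(-0.40,  0.045, 0.021),
          c( 0.05,  0.250, 0.050))
  )
  shape[, 1] <- shape[, 1] * amplitude_scale
  shape
}

#' Generate a synthetic single-lead ECG record
#'
#' Lays out beats at jittered RR intervals, draws each beat's AAMI class from
#' `class_proportions`, advances premature classes (SVEB, VEB) toward their
#' predecessor so their previous RR interval is shortened while the next beat
#' stays on schedule, renders each beat as a class-specific mixture of
#' Gaussian bumps, and adds sinusoidal baseline wander (periods at and above
#' `wander_period_s`) plus white noise. The annotated sample of every beat is
#' exactly the QRS apex. Annotation symbols are the canonical MIT-BIH codes
#' `N`, `A`, `V`, `F` for the four classes.
#'
#' @param config A [synthetic_config()].
#' @param record_id Name for the generated record.
#' @param amplitude_scale Per-record multiplicative scaling of all bump
#'   amplitudes (emulates inter-patient electrode gain differences).
#' @return An [ecg_record()].
#' @export
#' @examples
#' rec <- simulate_record(synthetic_config(duration_s = 30, seed = 7))
#' rec
simulate_record <- function(config, record_id = "syn", amplitude_scale = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$sampling_rate_hz
  margin <- 0.5  # s kept clear at each end (P/T support + segment window)
  n_nominal <- floor((config$duration_s - 2 * margin) / config$mean_rr_s) + 1L
  if (n_nominal < 12L) {
    abort(sprintf(paste0("duration %.1f s yields only %d beats at mean RR ",
                         "%.2f s; at least 12 are required (local RR needs ",
                         "10 prior intervals)"),
                  config$duration_s, n_nominal, config$mean_rr_s))
  }
  with_seed(config$seed, {
    n_samp <- round(config$duration_s * fs)
    t_grid <- (seq_len(n_samp) - 1L) / fs

    # nominal schedule, then class-dependent prematurity
    jit <- rnorm(n_nominal, 0, config$rr_jitter_sd_s)
    jit <- pmax(pmin(jit, 3 * config$rr_jitter_sd_s), -3 * config$rr_jitter_sd_s)
    iv <- pmax(config$mean_rr_s + jit, 0.4 * config$mean_rr_s)
    t0 <- margin + cumsum(c(0, iv[-n_nominal]))
    t0 <- t0[t0 <= config$duration_s - margin]
    n_beats <- length(t0)
    cls <- sample.int(4L, n_beats, replace = TRUE, prob = config$class_proportions)
    cls[1L] <- 1L  # a premature first beat has no previous interval to shorten
    tt <- t0
    fac <- c(1, config$sveb_prematurity, config$veb_prematurity, 1)
    for (i in seq_len(n_beats)[-1L]) {
      tt[i] <- tt[i - 1L] + fac[cls[i]] * (t0[i] - tt[i - 1L])
    }
    # anchor each apex on an exact sample
    r_sample <- round(tt * fs)
    keep <- c(TRUE, diff(r_sample) > 0)
    r_sample <- r_sample[keep]; cls <- cls[keep]; n_beats <- length(r_sample)

    sig <- numeric(n_samp)
    half <- round(0.45 * fs)
    for (b in seq_len(n_beats)) {
      shape <- beat_morphology(cls[b], amplitude_scale)
      i0 <- max(0L, r_sample[b] - half); i1 <- min(n_samp - 1L, r_sample[b] + half)
      idx <- (i0:i1) + 1L
      rel <- (i0:i1) / fs - r_sample[b] / fs
      bump <- numeric(length(rel))
      for (g in seq_len(nrow(shape))) {
        bump <- bump + shape[g, 1] * exp(-(rel - shape[g, 2])^2 / (2 * shape[g, 3]^2))
      }
      sig[idx] <- sig[idx] + bump
    }
    if (config$wander_amplitude > 0) {
      ph <- runif(2, 0, 2 * pi)
      sig <- sig +
        config$wander_amplitude * sin(2 * pi * t_grid / config$wander_period_s + ph[1]) +
        0.4 * config$wander_amplitude *
          sin(2 * pi * t_grid / (2.3 * config$wander_period_s) + ph[2])
    }
    if (config$noise_sd > 0) sig <- sig + rnorm(n_samp, 0, config$noise_sd)

    ecg_record(record_id, sig, fs,
               tibble(sample = as.integer(r_sample),
                      symbol = c("N", "A", "V", "F")[cls]))
  })
}

#' Generate a cohort of synthetic "patients"
#'
#' Draws per-record physiology (resting RR interval, electrode gain) from
#' cohort-level distributions, then calls [simulate_record()] once per
#' record with a seed derived from `seed`. Records are therefore mutually
#' independent and individually reproducible, and inter-patient variation is
#' present, so a train/test split over record ids is a genuine inter-patient
#' split.
#'
#' @param n_records Number of records to generate.
#' @param config Base [synthetic_config()]; per-record `mean_rr_s` is drawn
#'   around `config$mean_rr_s` (sd 0.07 s, clamped to \[0.55, 1.1\] s) and the
#'   amplitude scale from U(0.85, 1.15).
#' @param seed Cohort seed (overrides `config$seed`).
#' @param record_prefix Prefix for record ids (`<prefix>01`, ...).
#' @return A named list of [ecg_record()] objects.
#' @export
simulate_cohort <- function(n_records, config = synthetic_config(),
                            seed = config$seed, record_prefix = "syn") {
  stopifnot(n_records >= 1)
  params <- with_seed(seed, {
    tibble(
      mean_rr = pmin(pmax(rnorm(n_records, config$mean_rr_s, 0.07), 0.55), 1.1),
      amp = runif(n_records, 0.85, 1.15),
      rec_seed = sample.int(.Machine$integer.max, n_records)
    )
  })
  recs <- purrr::map(seq_len(n_records), function(i) {
    cfg_i <- config
    cfg_i$mean_rr_s <- params$mean_rr[i]
    cfg_i$seed <- params$rec_seed[i]
    simulate_record(cfg_i,
                    record_id = sprintf("%s%02d", record_prefix, i),
                    amplitude_scale = params$amp[i])
  })
  names(recs) <- purrr::map_chr(recs, "record_id")
  recs
}
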