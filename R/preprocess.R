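#' Median-filter window width in samples
#'
#' Converts a width in milliseconds to an odd sample count:
#' `round(width_ms * fs / 1000)`, incremented by 1 if even. Odd windows keep
#' the running median on the sample grid. At 360 Hz the 200-ms and 600-ms
#' windows are 73 and 217 samples.
#'
#' @param width_ms Window width in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return Odd integer window length.
#' @export
median_window_samples <- function(width_ms, fs) {
  w <- as.integer(round(width_ms * fs / 1000))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

# One exact sliding-median pass with reflect padding: the signal is extended
# by floor(w/2) mirrored samples at each end (left pad rev(head(x, h)), right
# pad rev(tail(x, h))), so output length equals input length and the ends are
# true medians of the padded window.
median_pass <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  h <- w %/% 2L
  xp <- c(rev(x[seq_len(h)]), x, rev(x[seq.int(n - h + 1L, n)]))
  stats::runmed(xp, w, endrule = "keep")[(h + 1L):(h + n)]
}

#' Estimate baseline wander with cascaded median filters
#'
#' A 200-ms running median removes QRS complexes and P waves, and a 600-ms
#' running median applied to its output removes T waves; what remains is the
#' baseline wander. Each pass uses an odd window ([median_window_samples()])
#' and reflect padding so the output has the input's length.
#'
#' @param signal Numeric amplitude vector.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of the same length: the estimated baseline.
#' @export
#' @examples
#' estimate_baseline(rep(1, 500), 360)   # constant in, constant out
estimate_baseline <- function(signal, fs) {
  stopifnot(fs > 0)
  if (length(signal) == 0L) abort("`signal` must be non-empty.")
  w200 <- median_window_samples(200, fs)
  w600 <- median_window_samples(600, fs)
  if (length(signal) < w600) {
    abort(sprintf("signal has %d samples but the 600-ms median window needs %d.",
                  length(signal), w600))
  }
  median_pass(median_pass(signal, w200), w600)
}

#' Remove baseline wander
#'
#' Subtracts the cascaded-median baseline estimate from the signal; beats end
#' up centered near zero while their morphology is untouched. No other
#' conditioning (no rescaling, no high-frequency filtering) is applied.
#'
#' @inheritParams estimate_baseline
#' @return Baseline-corrected signal of the same length.
#' @export
remove_baseline <- function(signal, fs) {
  signal - estimate_baseline(signal, fs)
}

#' Cut fixed-length heartbeat segments around labeled R-peaks
#'
#' For each annotated beat takes the half-open window
#' `[r - pre, r + post)` of the (baseline-corrected) signal in 0-based sample
#' coordinates: `pre` samples before the R-peak, the R-peak sample itself,
#' and `post - 1` samples after it, 200 samples in total by default. Beats
#' whose window would cross either record edge are dropped, never padded.
#'
#' @param signal Baseline-corrected amplitude vector.
#' @param annotations Tibble with 0-based `sample` indices and a `label`
#'   column (AAMI class) or `symbol` column; rows are one beat each.
#' @param pre,post Samples before/after the R-peak; `pre + post` must equal
#'   200, the network's fixed input length.
#' @param record_id Record name stamped on each segment row.
#' @return A tibble with one row per kept beat: `record_id`, `r_index`
#'   (0-based), any label columns from `annotations`, and `segment` (a
#'   list-column of length-200 numeric vectors). The number of edge-dropped
#'   beats is in `attr(, "n_dropped")`; kept + dropped equals the input beat
#'   count.
#' @export
segment_heartbeats <- function(signal, annotations, pre = 90L, post = 110L,
                               record_id = "rec") {
  if (pre + post != 200L) {
    abort(sprintf("pre + post must equal 200 (the model input length), got %d.",
                  pre + post))
  }
  ann <- as_tibble(annotations)
  n_sig <- length(signal)
  r <- as.integer(ann$sample)
  ok <- (r - pre >= 0L) & (r + post <= n_sig)
  kept <- ann[ok, , drop = FALSE]
  segs <- purrr::map(kept$sample, function(ri) {
    signal[(ri - pre + 1L):(ri + post)]  # 0-based [ri-pre, ri+post) window
  })
  out <- tibble(record_id = record_id, r_index = as.integer(kept$sample))
  for (col in setdiff(names(kept), "sample")) out[[col]] <- kept[[col]]
  out$segment <- segs
  attr(out, "n_dropped") <- sum(!ok)
  out
}
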