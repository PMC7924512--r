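#' RR intervals from R-peak sample indices
#'
#' @param r_indices Strictly increasing 0-based R-peak sample indices
#'   (at least two).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `length(r_indices) - 1` intervals in seconds:
#'   `(r[i+1] - r[i]) / fs`.
#' @export
#' @examples
#' compute_rr_intervals(c(0, 360, 720), 360)  # 1 s, 1 s
compute_rr_intervals <- function(r_indices, fs) {
  stopifnot(fs > 0)
  if (length(r_indices) < 2L) abort("need at least two R-peak indices.")
  if (any(diff(r_indices) <= 0)) abort("`r_indices` must be strictly increasing.")
  diff(r_indices) / fs
}

#' Per-beat RR dynamic features
#'
#' Four rhythm features per beat: the previous RR interval, the post
#' (following) RR interval, their ratio, and the local RR interval (mean of
#' the up-to-10 intervals immediately preceding the beat). Edge rules: the
#' first beat's previous interval and the last beat's post interval are
#' imputed with the record mean RR; a beat with no preceding interval gets
#' the record mean as its local RR. The ratio is previous/post after
#' imputation. All values are in seconds (the ratio is dimensionless).
#'
#' @inheritParams compute_rr_intervals
#' @param beat_position Optional 1-based beat position; if given, the single
#'   corresponding row is returned.
#' @return A tibble with columns `prev_rr_s`, `post_rr_s`, `ratio_rr`,
#'   `local_rr_s`, one row per beat (or the one requested row).
#' @export
extract_rr_features <- function(r_indices, fs, beat_position = NULL) {
  iv <- compute_rr_intervals(r_indices, fs)
  n <- length(r_indices)
  mean_rr <- mean(iv)
  prev <- c(mean_rr, iv)            # prev[i] = interval ending at beat i
  post <- c(iv, mean_rr)            # post[i] = interval starting at beat i
  csum <- c(0, cumsum(iv))
  local <- vapply(seq_len(n), function(i) {
    hi <- i - 1L                    # last preceding interval index
    if (hi < 1L) return(mean_rr)
    lo1 <- max(hi - 10L, 0L)        # one before the first used interval
    (csum[hi + 1L] - csum[lo1 + 1L]) / (hi - lo1)
  }, numeric(1))
  out <- tibble(prev_rr_s = prev, post_rr_s = post,
                ratio_rr = prev / post, local_rr_s = local)
  if (!is.null(beat_position)) {
    stopifnot(beat_position >= 1L, beat_position <= n)
    out <- out[beat_position, , drop = FALSE]
  }
  out
}

#' Subtract the record mean RR interval from the RR features
#'
#' Rhythm differs across patients, so the interval features are centered per
#' record: the mean RR interval over the whole record (all intervals, both
#' training and test records use their own mean, so no information crosses
#' patients) is subtracted from the previous, post and local RR features.
#' The ratio is left unchanged.
#'
#' @param features Tibble from [extract_rr_features()].
#' @param record_mean_rr_s Positive mean RR interval of the record, seconds.
#' @return Tibble of the same shape with centered interval features.
#' @export
#' @examples
#' f <- tibble::tibble(prev_rr_s = 0.8, post_rr_s = 0.8,
#'                     ratio_rr = 1, local_rr_s = 0.8)
#' normalize_rr_features(f, 0.8)  # (0, 0, 1, 0)
normalize_rr_features <- function(features, record_mean_rr_s) {
  if (!is.numeric(record_mean_rr_s) || record_mean_rr_s <= 0) {
    abort("`record_mean_rr_s` must be positive.")
  }
  dplyr::mutate(as_tibble(features),
                prev_rr_s = .data$prev_rr_s - record_mean_rr_s,
                post_rr_s = .data$post_rr_s - record_mean_rr_s,
                local_rr_s = .data$local_rr_s - record_mean_rr_s)
}
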