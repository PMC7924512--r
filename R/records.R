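#' Construct a single-lead ECG record
#'
#' An `ecg_record` bundles one lead of an ECG signal with its sampling rate
#' and beat annotations. Annotation sample indices are 0-based (the WFDB
#' convention) and all windowing in this package is half-open `[a, b)` on
#' 0-based indices; this is stated once here and holds everywhere.
#'
#' @param record_id Character scalar naming the record (e.g. `"100"`).
#' @param signal Numeric vector of amplitudes in millivolts for one lead.
#' @param sampling_rate_hz Positive sampling frequency in Hz.
#' @param annotations Data frame with columns `sample` (0-based integer
#'   indices, strictly increasing, each `< length(signal)`) and `symbol`
#'   (single-character MIT-BIH annotation codes).
#'
#' @return An object of class `ecg_record`: a list with elements `record_id`,
#'   `sampling_rate_hz`, `signal` and `annotations` (a tibble).
#' @export
#' @examples
#' rec <- ecg_record("toy", sin(seq(0, 20, by = 0.01)), 100,
#'                   data.frame(sample = c(157, 785), symbol = c("N", "N")))
#' rec
ecg_record <- function(record_id, signal, sampling_rate_hz, annotations) {
  if (!is.character(record_id) || length(record_id) != 1L) {
    abort("`record_id` must be a single string.")
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a positive number.")
  }
  signal <- as.numeric(signal)
  if (length(signal) == 0L) abort("`signal` must be non-empty.")
  ann <- as_tibble(annotations)
  if (!all(c("sample", "symbol") %in% names(ann))) {
    abort("`annotations` needs columns `sample` and `symbol`.")
  }
  ann$sample <- as.integer(ann$sample)
  ann$symbol <- as.character(ann$symbol)
  if (nrow(ann) > 0) {
    if (any(ann$sample < 0L) || any(ann$sample >= length(signal))) {
      abort("annotation samples must lie in [0, length(signal)) (0-based).")
    }
    if (nrow(ann) > 1 && any(diff(ann$sample) <= 0L)) {
      abort("annotation samples must be strictly increasing.")
    }
    if (any(nchar(ann$symbol) != 1L)) {
      abort("annotation symbols must be single characters.")
    }
  }
  structure(
    list(record_id = record_id,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         signal = signal,
         annotations = ann),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$signal) / x$sampling_rate_hz
  cat(sprintf("<ecg_record '%s'>  %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$record_id, length(x$signal), x$sampling_rate_hz, dur,
              nrow(x$annotations)))
  if (nrow(x$annotations) > 0) {
    tab <- table(x$annotations$symbol)
    cat("  symbols:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Write an ECG record as a plain-text signal/annotation pair
#'
#' Writes `<id>.csv` (a single `value` column of amplitudes) and
#' `<id>.ann.json` (an array of `{sample, symbol}` objects, samples 0-based)
#' plus the sampling rate inside the JSON header. This plain-text dialect
#' mirrors the content of a WFDB record without its binary encodings.
#'
#' @param record An [ecg_record()].
#' @param dir Directory to write into (created if missing).
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(record$record_id, ".csv"))
  js  <- file.path(dir, paste0(record$record_id, ".ann.json"))
  utils::write.csv(data.frame(value = record$signal), csv, row.names = FALSE)
  jsonlite::write_json(
    list(record_id = record$record_id,
         sampling_rate_hz = record$sampling_rate_hz,
         annotations = record$annotations),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv, js))
}

read_record_csv <- function(path) {
  base <- sub("\\.csv$", "", path)
  js <- paste0(base, ".ann.json")
  if (!file.exists(path)) abort(paste0("signal file not found: ", path))
  if (!file.exists(js)) abort(paste0("annotation file not found: ", js))
  sig <- utils::read.csv(path)$value
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  ann <- as_tibble(meta$annotations)
  if (nrow(ann) == 0) ann <- tibble(sample = integer(), symbol = character())
  ecg_record(meta$record_id, sig, meta$sampling_rate_hz, ann)
}

#' Load an ECG record from disk
#'
#' Reads either a binary WFDB record (`.hea`/`.dat`/`.atr`, signal format
#' 212) or the package's plain-text dialect (`.csv` + `.ann.json`, see
#' [write_record()]). Non-beat annotations (rhythm changes, signal-quality
#' marks, comments) are dropped; only beat annotations are kept.
#'
#' @param path Path to the record: either `<dir>/<id>.csv`, or a WFDB header
#'   `<dir>/<id>.hea`, or a bare `<dir>/<id>` prefix resolved against both.
#' @param lead_name For WFDB records, the signal description to select
#'   (default `"MLII"`, the modified limb lead II). An absent lead is an
#'   error naming the available leads; no silent substitution.
#' @return An [ecg_record()].
#' @export
load_record <- function(path, lead_name = "MLII") {
  if (grepl("\\.csv$", path)) return(read_record_csv(path))
  if (grepl("\\.hea$", path)) return(read_wfdb_record(sub("\\.hea$", "", path), lead_name))
  if (file.exists(paste0(path, ".csv"))) return(read_record_csv(paste0(path, ".csv")))
  if (file.exists(paste0(path, ".hea"))) return(read_wfdb_record(path, lead_name))
  abort(paste0("no readable record at: ", path,
               " (looked for .csv/.ann.json and .hea/.dat/.atr)"))
}

#' Plot an ECG record
#'
#' Draws a window of the signal with R-peak annotations marked at their
#' labeled sample positions.
#'
#' @param object An [ecg_record()].
#' @param from,to Time window in seconds (defaults to the first 10 s).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, from = 0, to = min(10, length(object$signal) / object$sampling_rate_hz), ...) {
  fs <- object$sampling_rate_hz
  i0 <- max(0L, floor(from * fs)); i1 <- min(length(object$signal), ceiling(to * fs))
  df <- tibble(time_s = (i0:(i1 - 1L)) / fs,
               mv = object$signal[(i0 + 1L):i1])
  ann <- dplyr::filter(object$annotations,
                       .data$sample >= i0, .data$sample < i1)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)",
                  title = paste0("record ", object$record_id)) +
    ggplot2::theme_minimal()
  if (nrow(ann) > 0) {
    ann$mv <- object$signal[ann$sample + 1L]
    ann$time_s <- ann$sample / fs
    p <- p + ggplot2::geom_point(data = ann, colour = "red", size = 1) +
      ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$symbol),
                         vjust = -0.8, size = 3, colour = "red")
  }
  p
}
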