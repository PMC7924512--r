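# Minimal WFDB reader: .hea headers, format-212 .dat signals, MIT-format
# .atr annotations. Covers what the MIT-BIH arrhythmia database uses; it is
# not a general WFDB implementation.

# annotation code -> mnemonic (wfdb annotation code table)
.wfdb_ann_symbols <- local({
  s <- rep(NA_character_, 41)
  s[c(1:14, 16, 18:41)] <- c(
    "N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q", "~",
    "|",
    "s", "T", "*", "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?", "!",
    "[", "]", "e", "n", "@", "x", "f", "(", ")", "r")
  s
})

# beat (QRS) annotation symbols; everything else is a non-beat mark
.wfdb_beat_symbols <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E",
                        "j", "/", "Q", "e", "n", "f", "r", "B", "?")

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- sub("/.*$", "", rec[1])
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[3])) else 250
  n_samples <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- purrr::map(seq_len(n_sig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else NA_real_
    gain <- as.numeric(sub("[(/].*$", "", gain_field))
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    list(file = f[1], fmt = sub("x.*|:.*|\\+.*", "", f[2]),
         gain = gain,
         baseline = if (is.na(baseline)) adc_zero else baseline,
         description = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                       else paste0("sig", i - 1))
  })
  list(record_name = record_name, n_sig = n_sig, fs = fs,
       n_samples = n_samples, signals = sig)
}

read_wfdb_dat212 <- function(dat_path, n_sig, n_samples) {
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  total <- n_samples * n_sig
  n_triplets <- ceiling(total / 2)
  b <- as.integer(raw[seq_len(3 * n_triplets)])
  b1 <- b[seq(1, length(b), by = 3)]
  b2 <- b[seq(2, length(b), by = 3)]
  b3 <- b[seq(3, length(b), by = 3)]
  s1 <- bitwAnd(b2, 0x0F) * 256L + b1
  s2 <- bitwAnd(b2, 0xF0) * 16L + b3
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  adc <- numeric(2 * n_triplets)
  adc[seq(1, length(adc), by = 2)] <- s1
  adc[seq(2, length(adc), by = 2)] <- s2
  matrix(adc[seq_len(total)], ncol = n_sig, byrow = TRUE)
}

read_wfdb_annotations <- function(atr_path) {
  raw <- readBin(atr_path, "raw", n = file.size(atr_path))
  n <- length(raw)
  samples <- integer(0); symbols <- character(0)
  t_cur <- 0L; i <- 1L
  while (i + 1L <= n) {
    w <- as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
    i <- i + 2L
    code <- w %/% 1024L
    interval <- w %% 1024L
    if (code == 0L && interval == 0L) break       # EOF
    if (code == 59L) {                            # SKIP: 4-byte interval
      if (interval == 0L) {
        hi <- as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
        lo <- as.integer(raw[i + 2L]) + 256L * as.integer(raw[i + 3L])
        i <- i + 4L
        t_cur <- t_cur + hi * 65536L + lo
      }
    } else if (code == 63L) {                     # AUX: skip payload (+ pad)
      i <- i + interval + interval %% 2L
    } else if (code %in% c(60L, 61L, 62L)) {      # NUM/SUB/CHN: no time
      next
    } else {
      t_cur <- t_cur + interval
      sym <- if (code >= 1L && code <= length(.wfdb_ann_symbols)) {
        .wfdb_ann_symbols[code]
      } else NA_character_
      if (!is.na(sym)) {
        samples <- c(samples, t_cur)
        symbols <- c(symbols, sym)
      }
    }
  }
  tibble(sample = samples, symbol = symbols)
}

#' Read one lead of a WFDB record
#'
#' Parses `<prefix>.hea`, decodes the format-212 `<prefix>.dat`, selects the
#' lead whose header description matches `lead_name`, converts ADC units to
#' millivolts via the header gain and baseline, reads `<prefix>.atr`, and
#' keeps beat annotations only (non-beat marks such as rhythm changes and
#' quality flags are dropped).
#'
#' @param prefix Path prefix of the record (no extension).
#' @param lead_name Signal description to select, e.g. `"MLII"`.
#' @return An [ecg_record()] with amplitudes in mV and 0-based annotation
#'   samples.
#' @export
read_wfdb_record <- function(prefix, lead_name = "MLII") {
  hea <- paste0(prefix, ".hea")
  if (!file.exists(hea)) abort(paste0("WFDB header not found: ", hea))
  hdr <- parse_wfdb_header(hea)
  leads <- purrr::map_chr(hdr$signals, "description")
  k <- match(lead_name, leads)
  if (is.na(k)) {
    abort(sprintf("lead '%s' not in record %s; available leads: %s",
                  lead_name, hdr$record_name, paste(leads, collapse = ", ")))
  }
  fmts <- unique(purrr::map_chr(hdr$signals, "fmt"))
  if (!identical(fmts, "212")) {
    abort(paste0("only signal format 212 is supported, header declares: ",
                 paste(fmts, collapse = ", ")))
  }
  dat <- file.path(dirname(hea), hdr$signals[[k]]$file)
  if (!file.exists(dat)) abort(paste0("WFDB signal file not found: ", dat))
  adc <- read_wfdb_dat212(dat, hdr$n_sig, hdr$n_samples)
  mv <- (adc[, k] - hdr$signals[[k]]$baseline) / hdr$signals[[k]]$gain
  atr <- paste0(prefix, ".atr")
  ann <- if (file.exists(atr)) read_wfdb_annotations(atr) else {
    tibble(sample = integer(), symbol = character())
  }
  ann <- ann[ann$symbol %in% .wfdb_beat_symbols &
               ann$sample < length(mv), , drop = FALSE]
  ecg_record(basename(prefix), mv, hdr$fs, ann)
}
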