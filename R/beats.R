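#' Prepare model-ready beats from one record
#'
#' Runs the whole per-record pipeline: maps annotation symbols to AAMI
#' classes and removes excluded beats, subtracts the cascaded-median baseline
#' from the signal, cuts 200-sample segments around the labeled R-peaks
#' (dropping edge beats), computes the four RR features from *all* annotated
#' beats of the record, and centers the interval features with the record's
#' own mean RR. RR features are per-record quantities, so no information
#' crosses records.
#'
#' @param record An [ecg_record()].
#' @param pre,post Segment window (samples before/after the R-peak).
#' @return A beat tibble: `record_id`, `r_index`, `label` (factor over
#'   [aami_classes]), `prev_rr_s`, `post_rr_s`, `ratio_rr`, `local_rr_s`,
#'   `segment` (list of length-200 numeric vectors). Attribute `n_dropped`
#'   counts edge-dropped beats.
#' @export
#' @examples
#' rec <- simulate_record(synthetic_config(duration_s = 30, seed = 2))
#' beats <- prepare_beats(rec)
#' dplyr::count(beats, label)
prepare_beats <- function(record, pre = 90L, post = 110L) {
  stopifnot(inherits(record, "ecg_record"))
  ann <- record$annotations
  if (nrow(ann) < 2L) abort("record must contain at least two beats.")
  ann$label <- map_annotation_symbol(ann$symbol)

  # RR features come from the full annotated beat sequence (before any
  # class exclusion would distort rhythm context)
  rr <- extract_rr_features(ann$sample, record$sampling_rate_hz)
  mean_rr <- mean(compute_rr_intervals(ann$sample, record$sampling_rate_hz))
  rr <- normalize_rr_features(rr, mean_rr)
  ann <- dplyr::bind_cols(ann, rr)

  keep <- ann$label != "excluded"
  ann <- ann[keep, , drop = FALSE]
  corrected <- remove_baseline(record$signal, record$sampling_rate_hz)
  beats <- segment_heartbeats(corrected, ann[, setdiff(names(ann), "symbol")],
                              pre = pre, post = post,
                              record_id = record$record_id)
  beats$label <- factor(beats$label, levels = aami_classes)
  beats
}

#' Prepare beats for a set of records
#'
#' @param records List of [ecg_record()] objects.
#' @inheritParams prepare_beats
#' @return One beat tibble with all records stacked; per-record processing
#'   order has no effect on any beat's features.
#' @export
prepare_cohort <- function(records, pre = 90L, post = 110L) {
  purrr::map_dfr(records, prepare_beats, pre = pre, post = post)
}

#' Load and prepare the MIT-BIH arrhythmia database
#'
#' Reads every non-paced record's MLII lead from a local WFDB directory,
#' prepares beats ([prepare_beats()]), and tags each beat with its DS1/DS2
#' split membership. The paced records 102, 104, 107 and 217 are never read.
#'
#' @param db_dir Directory containing `<id>.hea/.dat/.atr` files.
#' @param lead_name Lead to read (default `"MLII"`).
#' @return A beat tibble with an extra `split` column (`"DS1"`/`"DS2"`).
#' @export
load_mitdb_beats <- function(db_dir, lead_name = "MLII") {
  if (!dir.exists(db_dir)) {
    abort(paste0("MIT-BIH directory not found: ", db_dir))
  }
  ids <- sort(unique(sub("\\.hea$", "", basename(
    list.files(db_dir, pattern = "\\.hea$")))))
  if (length(ids) == 0) abort(paste0("no .hea files in ", db_dir))
  sp <- split_inter_patient(ids)
  use <- c(sp$ds1, sp$ds2)
  beats <- purrr::map_dfr(use, function(id) {
    prepare_beats(read_wfdb_record(file.path(db_dir, id), lead_name))
  })
  beats$split <- ifelse(beats$record_id %in% sp$ds1, "DS1", "DS2")
  beats
}
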