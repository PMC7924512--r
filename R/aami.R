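#' AAMI heartbeat classes
#'
#' The fixed four-class order used everywhere in this package (loss targets,
#' confusion-matrix axes, reports): N = 0, SVEB = 1, VEB = 2, F = 3. The
#' fifth AAMI group (Q, unknown/paced) exists only as an exclusion marker,
#' never as a model class.
#'
#' @format Character vector of length 4.
#' @export
aami_classes <- c("N", "SVEB", "VEB", "F")

# MIT-BIH beat symbol -> AAMI class lookup
.aami_map <- c(
  "N" = "N", "j" = "N", "e" = "N", "R" = "N", "L" = "N",
  "a" = "SVEB", "S" = "SVEB", "J" = "SVEB", "A" = "SVEB",
  "E" = "VEB", "V" = "VEB",
  "F" = "F",
  "Q" = "excluded", "f" = "excluded", "/" = "excluded"
)

#' Map MIT-BIH annotation symbols to AAMI classes
#'
#' Normal-group beats (`N`, `j`, `e`, `R`, `L`) map to N; supraventricular
#' ectopic beats (`a`, `S`, `J`, `A`) to SVEB; ventricular ectopic beats
#' (`E`, `V`) to VEB; fusion (`F`) to F. The unknown/paced group (`Q`, `f`,
#' `/`) maps to `"excluded"`, as does - with a warning - any symbol outside
#' the table. Total function: never errors.
#'
#' @param symbol Character vector of single-character MIT-BIH beat codes.
#' @return Character vector over `"N"`, `"SVEB"`, `"VEB"`, `"F"`,
#'   `"excluded"`.
#' @export
#' @examples
#' map_annotation_symbol(c("L", "A", "/"))  # N, SVEB, excluded
map_annotation_symbol <- function(symbol) {
  out <- unname(.aami_map[symbol])
  unknown <- is.na(out)
  if (any(unknown)) {
    warn(paste0("unrecognized annotation symbol(s) excluded: ",
                paste(unique(symbol[unknown]), collapse = " ")))
    out[unknown] <- "excluded"
  }
  out
}

# Canonical inter-patient partition of the 44 non-paced MIT-BIH records
# (de Chazal protocol): DS1 trains, DS2 tests.
.ds1_records <- c("101", "106", "108", "109", "112", "114", "115", "116",
                  "118", "119", "122", "124", "201", "203", "205", "207",
                  "208", "209", "215", "220", "223", "230")
.ds2_records <- c("100", "103", "105", "111", "113", "117", "121", "123",
                  "200", "202", "210", "212", "213", "214", "219", "221",
                  "222", "228", "231", "232", "233", "234")
.paced_records <- c("102", "104", "107", "217")

#' Inter-patient DS1/DS2 split of MIT-BIH records
#'
#' Partitions record ids into the canonical de Chazal training set (DS1) and
#' test set (DS2), excluding the four paced records 102, 104, 107 and 217
#' from both. Ids outside the 48-record database land in neither set and are
#' reported in a warning.
#'
#' @param record_ids Character vector of MIT-BIH record names.
#' @return A list with character vectors `ds1` and `ds2` (disjoint), plus
#'   `excluded` (paced) and `unknown`.
#' @export
#' @examples
#' split_inter_patient(c("100", "101", "102"))
split_inter_patient <- function(record_ids) {
  record_ids <- as.character(record_ids)
  known <- c(.ds1_records, .ds2_records, .paced_records)
  unknown <- setdiff(record_ids, known)
  if (length(unknown) > 0) {
    warn(paste0("unknown record id(s) placed in neither split: ",
                paste(unknown, collapse = " ")))
  }
  list(ds1 = intersect(record_ids, .ds1_records),
       ds2 = intersect(record_ids, .ds2_records),
       excluded = intersect(record_ids, .paced_records),
       unknown = unknown)
}

#' Per-split per-class beat counts
#'
#' Tabulates already-mapped beat labels into the DS1 / DS2 / Total table:
#' one row per split plus a `Total` row, columns for the four AAMI classes
#' plus a row-sum `Total` column.
#'
#' @param labeled_beats Tibble/data frame with columns `record_id` and
#'   `label` (values among `aami_classes`; excluded beats already removed).
#' @return A tibble with rows `DS1`, `DS2`, `Total`.
#' @export
summarize_counts <- function(labeled_beats) {
  df <- as_tibble(labeled_beats)
  sp <- split_inter_patient(unique(as.character(df$record_id)))
  one_row <- function(ids, name) {
    sub <- df[df$record_id %in% ids, , drop = FALSE]
    cnt <- vapply(aami_classes, function(cl) sum(sub$label == cl), integer(1))
    tibble(dataset = name, !!!as.list(cnt), Total = sum(cnt))
  }
  r1 <- one_row(sp$ds1, "DS1")
  r2 <- one_row(sp$ds2, "DS2")
  tot <- r1
  tot$dataset <- "Total"
  for (col in c(aami_classes, "Total")) tot[[col]] <- r1[[col]] + r2[[col]]
  bind_rows(r1, r2, tot)
}
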