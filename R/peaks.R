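#' Read a fragment-analysis peak table
#'
#' The canonical input is a tab-delimited file with header columns
#' `sample_id`, `fragment_size` (bp) and `peak_area` (fluorescence units),
#' one sized peak per row — the typical export of fragment-analysis software
#' after size calling. Lines starting with `#` are ignored. Rows with
#' non-numeric, non-positive sizes or negative areas are rejected with their
#' row numbers; an empty file yields an empty table with a warning.
#'
#' @param path File path.
#' @return Tibble with columns `sample_id`, `fragment_size`, `peak_area`.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("peak table not found: ", path), class = "maq_io_error")
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("sample_id", "fragment_size", "peak_area")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("peak table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "maq_format_error")
  }
  if (nrow(raw) == 0) {
    warn("peak table is empty")
    return(tibble(sample_id = character(), fragment_size = double(),
                  peak_area = double()))
  }
  size <- suppressWarnings(as.numeric(raw$fragment_size))
  area <- suppressWarnings(as.numeric(raw$peak_area))
  bad <- which(is.na(size) | is.na(area) | size <= 0 | area < 0)
  if (length(bad) > 0) {
    abort(paste0("malformed peak rows (need fragment_size > 0, peak_area >= 0): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "maq_parse_error")
  }
  tibble(sample_id = as.character(raw$sample_id),
         fragment_size = size, peak_area = area)
}

#' Read a sample sheet
#'
#' Tab-delimited file with columns `sample_id` and `kind` (`tumor` or
#' `control`). Sample kind is declared here, never inferred from names.
#'
#' @param path File path.
#' @return Tibble with columns `sample_id`, `kind`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("sample sheet not found: ", path), class = "maq_io_error")
  }
  sheet <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("sample_id", "kind"), names(sheet))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "maq_format_error")
  }
  if (!all(sheet$kind %in% c("tumor", "control"))) {
    abort("sample sheet kind must be 'tumor' or 'control'",
          class = "maq_validation_error")
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort("duplicate sample_id in sample sheet", class = "maq_validation_error")
  }
  select(sheet, all_of(c("sample_id", "kind")))
}

#' Assign peaks to panel amplicons by fragment length
#'
#' Each peak is assigned to the amplicon whose designed length is nearest to
#' the observed fragment size, provided the distance is within the panel's
#' `length_tolerance`; designed lengths are unique within a kit, so the
#' assignment is unambiguous and injective on peaks. Peaks with no amplicon
#' within tolerance are dropped with a message. When two peaks of one sample
#' resolve to the same amplicon, the larger area wins (the dominant peak is
#' the amplicon product; minor peaks are stutter) and a warning is raised.
#' Amplicons with no matched peak are simply absent from the result — missing
#' data is represented by absence, never by a zero area, because zeros would
#' corrupt downstream dosage ratios.
#'
#' @param peaks Tibble as returned by [read_peak_table()].
#' @param panel A [maq_panel()].
#' @return Tibble of per-sample measurements: `sample_id`, `amplicon_id`,
#'   `peak_area`.
#' @export
match_peaks <- function(peaks, panel) {
  if (nrow(peaks) == 0) {
    return(tibble(sample_id = character(), amplicon_id = character(),
                  peak_area = double()))
  }
  tol <- length_tolerance(panel)
  idx <- vapply(peaks$fragment_size, function(s) {
    d <- abs(panel$expected_length - s)
    j <- which.min(d)
    if (d[j] <= tol) j else NA_integer_
  }, integer(1))
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    inform(paste0(dropped, " peak(s) outside length tolerance dropped"))
  }
  matched <- peaks[!is.na(idx), ]
  matched$amplicon_id <- panel$id[idx[!is.na(idx)]]
  dups <- matched %>%
    dplyr::count(.data$sample_id, .data$amplicon_id) %>%
    filter(.data$n > 1)
  if (nrow(dups) > 0) {
    warn(paste0("multiple peaks mapped to one amplicon (largest area kept): ",
                paste(paste0(dups$sample_id, "/", dups$amplicon_id),
                      collapse = ", ")))
  }
  matched %>%
    group_by(.data$sample_id, .data$amplicon_id) %>%
    summarise(peak_area = max(.data$peak_area), .groups = "drop") %>%
    arrange(.data$sample_id, .data$amplicon_id)
}

#' Serialize per-sample measurements back to a peak table
#'
#' Inverse of [match_peaks()] for round-tripping: each measurement becomes a
#' peak at the amplicon's designed fragment length.
#'
#' @param runs Tibble from [match_peaks()].
#' @inheritParams match_peaks
#' @return Tibble with columns `sample_id`, `fragment_size`, `peak_area`.
#' @export
runs_to_peaks <- function(runs, panel) {
  runs %>%
    left_join(select(as_tibble(panel), amplicon_id = "id", "expected_length"),
              by = "amplicon_id") %>%
    mutate(fragment_size = .data$expected_length) %>%
    select(all_of(c("sample_id", "fragment_size", "peak_area")))
}

#' Write a dosage-quotient table
#'
#' TSV with columns `sample_id`, `amplicon_id`, `region`, `dq_mean`, `dq_sd`,
#' `n_combinations`, rows ordered by sample and then genomic position.
#'
#' @param dq Tibble from [dq_profile()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dq_table <- function(dq, path) {
  out <- dq %>%
    arrange(.data$sample_id, .data$chromosome, .data$arm, .data$position) %>%
    select(all_of(c("sample_id", "amplicon_id", "region",
                    "dq_mean", "dq_sd", "n_combinations")))
  readr::write_tsv(out, path)
  invisible(path)
}
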