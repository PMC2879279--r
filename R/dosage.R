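#' Pairwise dosage quotient
#'
#' The elementary double ratio behind all downstream calling: the target
#' amplicon's peak area relative to one reference amplicon, in the test
#' sample relative to one control sample,
#' `(tar_s / ref_s) / (tar_ctr / ref_ctr)`. A value near 1 indicates two
#' copies, 0.5 a single-copy loss, 1.5 a single-copy gain on a diploid
#' background, and values far above 1 amplification. Combinations with any
#' missing or non-positive area are undefined and return `NA` (they are
#' skipped, never imputed, by the aggregation step).
#'
#' @param tar_s,ref_s Target and reference peak areas in the test sample.
#' @param tar_ctr,ref_ctr The same two areas in the control sample.
#' @return Numeric dosage quotient(s); `NA` where undefined. Vectorized.
#' @export
#' @examples
#' pairwise_dq(50, 100, 100, 100) # 0.5
pairwise_dq <- function(tar_s, ref_s, tar_ctr, ref_ctr) {
  ok <- !is.na(tar_s) & !is.na(ref_s) & !is.na(tar_ctr) & !is.na(ref_ctr) &
    tar_s > 0 & ref_s > 0 & tar_ctr > 0 & ref_ctr > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- (tar_s[ok] / ref_s[ok]) / (tar_ctr[ok] / ref_ctr[ok])
  out
}

#' Aggregate dosage quotient for one target amplicon
#'
#' Computes the pairwise dosage quotient for every (reference amplicon,
#' control sample) combination for which all four areas are present and
#' positive, and summarizes them: the final DQ is the arithmetic mean over
#' the full Cartesian product of valid combinations, the spread is the sample
#' standard deviation (n - 1 denominator; 0 when a single combination
#' remains), and `n_combinations` counts the combinations used. With zero
#' valid combinations the target has no data (`dq_mean` = `NA`).
#'
#' @param sample_areas Named numeric vector of peak areas for the test
#'   sample (names are amplicon ids; missing amplicons simply absent).
#' @param control_areas List of named numeric vectors, one per control
#'   sample.
#' @param target_id Target amplicon id.
#' @param reference_ids Character vector of reference amplicon ids.
#' @return One-row tibble: `dq_mean`, `dq_sd`, `n_combinations`.
#' @export
aggregate_dq <- function(sample_areas, control_areas, target_id, reference_ids) {
  if (length(control_areas) < 1) {
    abort("at least one control sample is required", class = "maq_config_error")
  }
  tar_s <- sample_areas[target_id][[1]] %||% NA_real_
  dqs <- unlist(lapply(control_areas, function(ctrl) {
    pairwise_dq(
      tar_s = rep(unname(tar_s), length(reference_ids)),
      ref_s = unname(sample_areas[reference_ids]),
      tar_ctr = rep(unname(ctrl[target_id][[1]] %||% NA_real_),
                    length(reference_ids)),
      ref_ctr = unname(ctrl[reference_ids])
    )
  }), use.names = FALSE)
  dqs <- dqs[!is.na(dqs)]
  n <- length(dqs)
  tibble(
    dq_mean = if (n > 0) mean(dqs) else NA_real_,
    dq_sd = if (n > 1) sd(dqs) else if (n == 1) 0 else NA_real_,
    n_combinations = n
  )
}

#' Dosage-quotient profile of tumor samples
#'
#' Runs [aggregate_dq()] for every target amplicon of every tumor sample,
#' normalizing against all reference amplicons of the panel and all control
#' samples. Kits are analyzed independently: call this once per panel and
#' bind the results; dosage quotients are never pooled across kits before
#' scoring.
#'
#' @param runs Measurement tibble from [match_peaks()] (tumor and control
#'   samples together).
#' @param panel A [maq_panel()].
#' @param sample_sheet Tibble with `sample_id` and `kind` as from
#'   [read_sample_sheet()]; controls are the rows with `kind == "control"`.
#' @return Tibble with one row per (tumor sample, target amplicon):
#'   `sample_id`, `amplicon_id`, `region`, `chromosome`, `arm`, `position`,
#'   `kit_id`, `dq_mean`, `dq_sd`, `n_combinations`, ordered by sample and
#'   genomic position. Targets with no valid combination keep `NA` means.
#' @export
dq_profile <- function(runs, panel, sample_sheet) {
  controls_ids <- sample_sheet$sample_id[sample_sheet$kind == "control"]
  tumor_ids <- sample_sheet$sample_id[sample_sheet$kind == "tumor"]
  if (length(controls_ids) == 0) {
    abort("no control samples in sample sheet", class = "maq_config_error")
  }
  unknown <- setdiff(unique(runs$amplicon_id), panel$id)
  if (length(unknown) > 0) {
    abort(paste0("measurements reference amplicons absent from panel: ",
                 paste(unknown, collapse = ", ")),
          class = "maq_validation_error")
  }
  area_vec <- function(sid) {
    sub <- runs[runs$sample_id == sid, ]
    setNames(sub$peak_area, sub$amplicon_id)
  }
  control_areas <- lapply(controls_ids, area_vec)
  targets <- panel %>% filter(.data$role == "target")
  reference_ids <- panel$id[panel$role == "reference"]
  tumor_ids <- intersect(unique(runs$sample_id), tumor_ids)
  res <- purrr::map_dfr(tumor_ids, function(sid) {
    areas <- area_vec(sid)
    dq <- purrr::map_dfr(targets$id, function(tid) {
      aggregate_dq(areas, control_areas, tid, reference_ids)
    })
    dplyr::bind_cols(
      tibble(sample_id = sid, amplicon_id = targets$id,
             region = targets$region, chromosome = targets$chromosome,
             arm = targets$arm, position = targets$position,
             kit_id = kit_id(panel)),
      dq
    )
  })
  n_missing <- sum(is.na(res$dq_mean))
  if (n_missing > 0) {
    inform(paste0(n_missing, " target(s) had no valid (reference, control) ",
                  "combination and carry no data"))
  }
  arrange(res, .data$sample_id, .data$chromosome, .data$arm, .data$position)
}
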