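#' Read a gold-standard call table
#'
#' Tab-delimited file with columns `sample_id`, `region`, `status`
#' (`positive`, `negative` or `no_data`), typically transcribed from a
#' genome-wide reference assay such as array CGH (in the original validation,
#' circular-binary-segmentation values beyond +-0.3 defined gains/losses).
#'
#' @param path File path.
#' @return Tibble with columns `sample_id`, `region`, `status`.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("gold standard not found: ", path), class = "maq_io_error")
  }
  gold <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("sample_id", "region", "status"), names(gold))
  if (length(missing_cols) > 0) {
    abort(paste0("gold standard missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "maq_format_error")
  }
  if (!all(gold$status %in% c("positive", "negative", "no_data"))) {
    abort("gold status must be positive/negative/no_data",
          class = "maq_validation_error")
  }
  if (anyDuplicated(gold[c("sample_id", "region")])) {
    abort("duplicate (sample_id, region) in gold standard",
          class = "maq_validation_error")
  }
  select(gold, all_of(c("sample_id", "region", "status")))
}

# expected aberration direction per prognostic region; whole-chromosome
# regions accept either direction
default_region_directions <- c(
  "1p" = "loss", "3p" = "loss", "11q" = "loss", "17q" = "gain",
  "MYCN" = "amplified"
)

region_direction <- function(region) {
  d <- unname(default_region_directions[region])
  ifelse(is.na(d), "any", d)
}

call_is_positive <- function(status, direction) {
  pos <- if (direction == "any") {
    status %in% c("loss", "gain")
  } else {
    status == direction
  }
  pos[status == "no_data"] <- NA
  pos
}

#' Confusion counts for one region against the gold standard
#'
#' Call statuses are binarized direction-matched to the region's expected
#' aberration (loss for 1p/3p/11q, gain for 17q, amplified for MYCN; either
#' direction for whole-chromosome regions): a call of the expected kind is
#' positive, `normal` (or a call in the unexpected direction) negative.
#' Pairs with `no_data` on either side are excluded from the counts.
#' Gold rows with no matching call are counted as negative calls (the
#' pipeline evaluated the sample and reported nothing for that region).
#'
#' @param calls Call tibble from [region_calls()] (columns `sample_id`,
#'   `region`, `status`).
#' @param gold Gold-standard tibble from [read_gold_standard()].
#' @param region Region name present in the gold standard.
#' @param direction `"loss"`, `"gain"`, `"amplified"` or `"any"`; default
#'   looked up from the region name.
#' @return One-row tibble: `region`, `tp`, `fp`, `tn`, `fn`, `n_excluded`.
#' @export
confusion_counts <- function(calls, gold, region,
                             direction = region_direction(region)) {
  g <- gold[gold$region == region, ]
  if (nrow(g) == 0) {
    abort(paste0("region '", region, "' absent from gold standard"),
          class = "maq_config_error")
  }
  c_sub <- calls[calls$region == region, c("sample_id", "status")]
  m <- g %>%
    left_join(rename(c_sub, call_status = "status"), by = "sample_id") %>%
    mutate(call_status = dplyr::coalesce(.data$call_status, "normal"),
           call_pos = call_is_positive(.data$call_status, direction),
           gold_pos = ifelse(.data$status == "no_data", NA,
                             .data$status == "positive"))
  excl <- is.na(m$call_pos) | is.na(m$gold_pos)
  m <- m[!excl, ]
  tibble(
    region = region,
    tp = sum(m$call_pos & m$gold_pos),
    fp = sum(m$call_pos & !m$gold_pos),
    tn = sum(!m$call_pos & !m$gold_pos),
    fn = sum(!m$call_pos & m$gold_pos),
    n_excluded = sum(excl)
  )
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, as percentages at full precision (round only for
#' display). Ratios with a zero denominator are undefined and reported as
#' `NA`, never as 0 or 100.
#'
#' @param counts One-row tibble (or data frame of rows) with columns `tp`,
#'   `fp`, `tn`, `fn`.
#' @return The input with columns `sensitivity`, `specificity`, `ppv`,
#'   `npv` appended (percent).
#' @export
performance_metrics <- function(counts) {
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  counts %>%
    mutate(
      sensitivity = pct(.data$tp, .data$tp + .data$fn),
      specificity = pct(.data$tn, .data$tn + .data$fp),
      ppv = pct(.data$tp, .data$tp + .data$fp),
      npv = pct(.data$tn, .data$tn + .data$fn)
    )
}

#' Two-point ROC AUC from a single operating point
#'
#' The ROC curve of a binary caller has a single operating point; the area
#' under the two-segment curve through (1 - specificity, sensitivity) is
#' `(sensitivity + specificity) / 2`. Undefined whenever sensitivity or
#' specificity is.
#'
#' @inheritParams performance_metrics
#' @return Numeric AUC(s) as percentages.
#' @export
binary_auc <- function(counts) {
  m <- performance_metrics(counts)
  (m$sensitivity + m$specificity) / 2
}

#' Threshold-swept ROC AUC from continuous region scores
#'
#' Trapezoidal area under the full ROC curve over all score thresholds,
#' equal to the Mann-Whitney probability that a random positive outscores a
#' random negative, with ties counted half (midpoint convention). Scores
#' should be oriented so that larger means more aberrant — see
#' [region_scores()].
#'
#' @param scores Numeric vector of per-sample scores.
#' @param positive Logical vector, `TRUE` for gold-positive samples.
#' @return AUC as a percentage, or `NA` if either class is empty.
#' @export
continuous_auc <- function(scores, positive) {
  ok <- !is.na(scores) & !is.na(positive)
  scores <- scores[ok]
  positive <- as.logical(positive[ok])
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  u <- sum(r[positive]) - n1 * (n1 + 1) / 2
  100 * u / (n1 * n0)
}

#' Continuous aberration score per sample for one region
#'
#' The maximal dosage-quotient deviation from 1 over the region's loci,
#' signed toward the region's expected aberration: `max(1 - DQ)` for loss
#' regions, `max(DQ - 1)` for gain and amplification regions, `max(|DQ - 1|)`
#' when either direction counts.
#'
#' @param dq DQ tibble from [dq_profile()].
#' @param region Region label; for whole-chromosome scoring pass the
#'   chromosome name and set `chromosome = TRUE`.
#' @param direction See [confusion_counts()].
#' @param chromosome If `TRUE`, pool all target loci of that chromosome
#'   rather than one arm region.
#' @return Tibble `sample_id`, `score`.
#' @export
region_scores <- function(dq, region, direction = region_direction(region),
                          chromosome = FALSE) {
  sub <- if (chromosome) dq[dq$chromosome == region, ] else dq[dq$region == region, ]
  sub %>%
    group_by(sample_id = .data$sample_id) %>%
    summarise(score = {
      v <- .data$dq_mean[!is.na(.data$dq_mean)]
      if (length(v) == 0) NA_real_
      else switch(direction,
                  loss = max(1 - v),
                  gain = ,
                  amplified = max(v - 1),
                  max(abs(v - 1)))
    }, .groups = "drop")
}

#' Macro-average AUC
#'
#' Unweighted arithmetic mean over per-region AUCs (the summary used to
#' condense a per-region performance table into one figure). `NA` entries
#' are dropped; an empty input gives `NA`.
#'
#' @param aucs Numeric vector of per-region AUC percentages.
#' @return Single percentage.
#' @export
#' @examples
#' macro_average_auc(c(97.1, 100, 100, 97.1, 100))
macro_average_auc <- function(aucs) {
  aucs <- aucs[!is.na(aucs)]
  if (length(aucs) == 0) return(NA_real_)
  mean(aucs)
}

#' Pooled false-positive and false-negative rates
#'
#' Pools confusion counts across regions (all evaluable sample-region
#' pairs) and reports `fpr = fp / (fp + tn)` and `fnr = fn / (fn + tp)` as
#' percentages; zero denominators give `NA`.
#'
#' @param counts Data frame of per-region counts with columns `tp`, `fp`,
#'   `tn`, `fn` (one or more rows).
#' @return One-row tibble: `fp`, `fn`, `fpr`, `fnr`.
#' @export
error_rates <- function(counts) {
  fp <- sum(counts$fp); tn <- sum(counts$tn)
  fn <- sum(counts$fn); tp <- sum(counts$tp)
  tibble(
    fp = fp, fn = fn,
    fpr = if (fp + tn > 0) 100 * fp / (fp + tn) else NA_real_,
    fnr = if (fn + tp > 0) 100 * fn / (fn + tp) else NA_real_
  )
}

#' Bland-Altman repeatability of paired replicate measurements
#'
#' For paired dosage quotients from two replicate runs, reports the mean
#' difference (bias), 1.96 times the standard deviation of the differences
#' (the half-width of the limits of agreement, the quantity compared against
#' scoring thresholds), and a conservative coefficient of repeatability
#' `|bias| + 1.96 * sd` that folds the bias in. Pairs with a missing value
#' on either side are excluded; fewer than two complete pairs give `NA`s.
#'
#' @param replicate_a,replicate_b Numeric vectors of paired DQs (same
#'   length, paired by amplicon).
#' @return One-row tibble: `n_pairs`, `bias`, `loa_halfwidth`, `cr`.
#' @export
#' @examples
#' bland_altman_cr(c(1, 1.1, 0.9), c(1, 1.1, 0.9)) # zero differences
bland_altman_cr <- function(replicate_a, replicate_b) {
  if (length(replicate_a) != length(replicate_b)) {
    abort("replicates must be paired (equal length)",
          class = "maq_validation_error")
  }
  d <- replicate_a - replicate_b
  d <- d[!is.na(d)]
  if (length(d) < 2) {
    return(tibble(n_pairs = length(d), bias = NA_real_,
                  loa_halfwidth = NA_real_, cr = NA_real_))
  }
  bias <- mean(d)
  half <- 1.96 * sd(d)
  tibble(n_pairs = length(d), bias = bias, loa_halfwidth = half,
         cr = abs(bias) + half)
}

#' Evaluate calls against a gold standard
#'
#' Builds the per-region performance table (confusion counts, sensitivity,
#' specificity, predictive values, two-point AUC), the pooled error rates
#' and the macro-average AUC for every region present in the gold standard.
#'
#' @param calls Call tibble from [region_calls()].
#' @param gold Gold-standard tibble.
#' @param regions Regions to evaluate (default: all in the gold standard,
#'   in order of first appearance).
#' @return A `maq_performance` object; see [tidy.maq_performance()] and
#'   [glance.maq_performance()].
#' @export
evaluate_performance <- function(calls, gold, regions = unique(gold$region)) {
  if (nrow(calls) == 0) {
    abort("no calls to evaluate", class = "maq_validation_error")
  }
  per_region <- purrr::map_dfr(regions, function(r) {
    confusion_counts(calls, gold, r)
  }) %>%
    performance_metrics()
  per_region$auc <- binary_auc(per_region)
  structure(
    list(
      per_region = per_region,
      pooled = error_rates(per_region),
      macro_auc = macro_average_auc(per_region$auc)
    ),
    class = "maq_performance"
  )
}

#' @export
print.maq_performance <- function(x, ...) {
  cat("# Diagnostic performance vs gold standard\n")
  show <- x$per_region %>%
    mutate(across(c("sensitivity", "specificity", "ppv", "npv", "auc"),
                  ~ round(.x, 1)))
  print(as.data.frame(show), row.names = FALSE)
  cat(sprintf("macro AUC %.1f%%; pooled FPR %.1f%%, FNR %.1f%%\n",
              x$macro_auc, x$pooled$fpr, x$pooled$fnr))
  invisible(x)
}

#' Tidy and summarize a performance object
#'
#' `tidy()` returns the per-region metric table (one row per region, full
#' precision); `glance()` a one-row summary with the macro-average AUC and
#' the pooled error rates.
#'
#' @param x A `maq_performance` from [evaluate_performance()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.maq_performance <- function(x, ...) x$per_region

#' @rdname tidy.maq_performance
#' @export
glance.maq_performance <- function(x, ...) {
  tibble(macro_auc = x$macro_auc, fpr = x$pooled$fpr, fnr = x$pooled$fnr,
         fp = x$pooled$fp, fn = x$pooled$fn,
         n_regions = nrow(x$per_region))
}

#' Segmental calls contradicting a simulated truth table
#'
#' Audit helper for simulated cohorts: returns every segmental loss/gain
#' call that does not correspond to a true copy-number aberration of
#' matching direction at that call's location — neither a true segmental
#' event at the region nor a true whole-chromosome change of the same sign
#' on the call's chromosome (the latter being a real aberration detected
#' with the wrong scope, not a false positive in the copy-number sense).
#'
#' @param calls Call tibble from [region_calls()].
#' @param truth Truth tibble from [simulate_cohort()] (`$truth`).
#' @return The subset of `calls` that are genuine false positives against
#'   the simulated copy-number truth.
#' @export
false_segmental_calls <- function(calls, truth) {
  seg <- calls %>%
    filter(.data$scope == "segmental", .data$status %in% c("loss", "gain"),
           .data$region != "MYCN")
  if (nrow(seg) == 0) return(seg)
  sign_of <- function(status) ifelse(status == "gain", 1L, -1L)
  keep <- vapply(seq_len(nrow(seg)), function(i) {
    sid <- seg$sample_id[i]
    reg <- seg$region[i]
    chrom <- sub("[pq]$", "", reg)
    want <- sign_of(seg$status[i])
    tr <- truth[truth$sample_id == sid & truth$positive, ]
    seg_hit <- any(tr$scope == "segmental" & tr$region == reg &
                     sign(tr$change) == want)
    wc_hit <- any(tr$scope == "whole_chromosome" & tr$region == chrom &
                    sign(tr$change) == want)
    !(seg_hit || wc_hit)
  }, logical(1))
  seg[keep, ]
}
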