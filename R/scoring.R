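#' Score one arm region for a segmental aberration
#'
#' Applies the consecutive-loci rule (and, for rule sets with the fraction
#' clause enabled, the fraction rule) to the position-ordered dosage
#' quotients of one arm region. A locus with missing DQ breaks adjacency:
#' runs of deviating loci never bridge a failed amplicon. Both deviating
#' loci of a run must deviate in the same direction. With fewer than two
#' numeric DQs the region has no data.
#'
#' @param dq Named numeric vector of dosage quotients in ascending genomic
#'   position (names are amplicon ids; `NA` for failed loci).
#' @param rules A [maq_rules()] rule set.
#' @return One-row tibble: `status` (`loss`/`gain`/`normal`/`no_data`),
#'   `rule_fired`, `supporting_loci` (list column of amplicon ids).
#' @export
#' @examples
#' score_segmental(c(a = 0.79, b = 0.78, c = 1.01, d = 0.99), maq_rules())
score_segmental <- function(dq, rules) {
  ids <- names(dq) %||% as.character(seq_along(dq))
  if (sum(!is.na(dq)) < 2) {
    return(call_row("no_data", "insufficient_loci", character()))
  }
  lo <- 1 - rules$segmental_delta
  hi <- 1 + rules$segmental_delta
  state <- ifelse(is.na(dq), 0L, ifelse(dq <= lo, -1L, ifelse(dq >= hi, 1L, 0L)))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  qualifying <- which(runs$values != 0L &
                        runs$lengths >= rules$segmental_min_consecutive)
  if (length(qualifying) > 0) {
    # if loss and gain runs coexist (pathological), the first qualifying
    # run along the arm determines the call
    best <- qualifying[order(starts[qualifying])][1]
    dir <- if (runs$values[best] < 0) "loss" else "gain"
    return(call_row(dir, paste0("consecutive_", dir),
                    ids[starts[best]:ends[best]]))
  }
  if (rules$fraction_rule_enabled) {
    num <- !is.na(dq)
    down <- num & dq <= 1 - rules$fraction_rule_delta
    up <- num & dq >= 1 + rules$fraction_rule_delta
    if (sum(down) / sum(num) > rules$fraction_rule_fraction) {
      return(call_row("loss", "fraction_loss", ids[down]))
    }
    if (sum(up) / sum(num) > rules$fraction_rule_fraction) {
      return(call_row("gain", "fraction_gain", ids[up]))
    }
  }
  call_row("normal", "none", character())
}

call_row <- function(status, rule_fired, loci) {
  tibble(status = status, rule_fired = rule_fired,
         supporting_loci = list(as.character(loci)))
}

#' Score one chromosome for a whole-chromosome (numerical) aberration
#'
#' Evaluated per chromosome, and in the full pipeline only for samples
#' without any segmental call. A loss requires at least the arm fraction
#' (default 75%) of the numeric DQs of *both* the p and the q arm to lie
#' below 1, and more than half of all the chromosome's numeric DQs to show a
#' decrease of at least the majority delta (0.1); gains are symmetric. The
#' majority clause is applied to the union of both arms. Either arm without
#' a numeric DQ makes the chromosome unevaluable (`no_data`).
#'
#' @param dq_p,dq_q Named numeric DQ vectors for the p and q arm.
#' @inheritParams score_segmental
#' @return One-row tibble as in [score_segmental()].
#' @export
score_whole_chromosome <- function(dq_p, dq_q, rules) {
  p <- dq_p[!is.na(dq_p)]
  q <- dq_q[!is.na(dq_q)]
  if (length(p) == 0 || length(q) == 0) {
    return(call_row("no_data", "missing_arm", character()))
  }
  all_dq <- c(p, q)
  ids <- names(all_dq) %||% as.character(seq_along(all_dq))
  for (dir in c("loss", "gain")) {
    off_one <- if (dir == "loss") function(x) x < 1 else function(x) x > 1
    dev <- if (dir == "loss") {
      all_dq <= 1 - rules$numerical_majority_delta
    } else {
      all_dq >= 1 + rules$numerical_majority_delta
    }
    if (mean(off_one(p)) >= rules$numerical_arm_fraction &&
        mean(off_one(q)) >= rules$numerical_arm_fraction &&
        mean(dev) > rules$numerical_majority_fraction) {
      return(call_row(dir, paste0("whole_chromosome_", dir), ids[dev]))
    }
  }
  call_row("normal", "none", character())
}

#' Score MYCN amplification
#'
#' Amplified when every measurable MYCN-locus DQ shows an increase of at
#' least `mycn_delta` (3) over the normal baseline of 1 (DQ >= 4), with at
#' least `mycn_required_loci` loci measurable (MAQ 3, MLPA 2); fewer numeric
#' loci than required gives `no_data`.
#'
#' @param dq Named numeric vector of DQs at the designated MYCN loci.
#' @inheritParams score_segmental
#' @return One-row tibble with `status` in
#'   `amplified`/`normal`/`no_data`.
#' @export
score_mycn <- function(dq, rules) {
  num <- dq[!is.na(dq)]
  if (length(num) < rules$mycn_required_loci) {
    return(call_row("no_data", "insufficient_loci", character()))
  }
  cut <- if (rules$mycn_absolute) rules$mycn_delta else 1 + rules$mycn_delta
  if (all(num >= cut)) {
    call_row("amplified", "mycn_amplification",
             names(num) %||% as.character(seq_along(num)))
  } else {
    call_row("normal", "none", character())
  }
}

#' Classify samples from their dosage-quotient profiles
#'
#' The full decision cascade, per sample. Every arm region of interest is
#' first scored for segmental aberrations; MYCN amplification is scored
#' independently of everything else. If at least one segmental loss or gain
#' is found the sample is classified `segmental` and whole-chromosome
#' scoring is skipped entirely (segmental precedence is global per sample).
#' Otherwise every chromosome covered on both arms is scored for
#' whole-chromosome changes; any such loss or gain classifies the sample
#' `numerical`, else `none`. When MYCN is amplified, the MYCN loci are
#' excluded from chromosome-2 whole-chromosome evaluation (amplification
#' DQs would trivially satisfy the gain clauses and mask ploidy assessment);
#' when not amplified they stand in as chromosome 2's p arm.
#'
#' @param dq DQ tibble from [dq_profile()], possibly several kits bound
#'   together by rows.
#' @param rules A rule set, or anything [as_ruleset()] accepts.
#' @return Tibble with one row per sample: `sample_id`, `category`
#'   (`segmental`/`numerical`/`none`), `mycn_amplified` (`TRUE`/`FALSE`,
#'   `NA` when unevaluable), and a `region_calls` list column of per-region
#'   call tibbles (`region`, `scope`, `status`, `rule_fired`,
#'   `supporting_loci`). Use [region_calls()] to unnest all calls.
#' @export
classify_samples <- function(dq, rules = maq_rules()) {
  rules <- as_ruleset(rules)
  dq <- arrange(dq, .data$sample_id, .data$chromosome, .data$arm, .data$position)
  purrr::map_dfr(split(dq, dq$sample_id), function(d) {
    classify_one(d, rules)
  })
}

classify_one <- function(d, rules) {
  sid <- d$sample_id[1]
  named_dq <- function(sub) setNames(sub$dq_mean, sub$amplicon_id)

  mycn_d <- d[d$region == "MYCN", ]
  mycn_call <- NULL
  mycn_amp <- NA
  if (nrow(mycn_d) > 0) {
    mycn_call <- score_mycn(named_dq(mycn_d), rules) %>%
      mutate(region = "MYCN", scope = "segmental", .before = 1)
    mycn_amp <- switch(mycn_call$status,
                       amplified = TRUE, normal = FALSE, NA)
  }

  seg_regions <- setdiff(unique(d$region), "MYCN")
  seg_calls <- purrr::map_dfr(seg_regions, function(r) {
    score_segmental(named_dq(d[d$region == r, ]), rules) %>%
      mutate(region = r, scope = "segmental", .before = 1)
  })
  has_segmental <- nrow(seg_calls) > 0 &&
    any(seg_calls$status %in% c("loss", "gain"))

  calls <- bind_rows(seg_calls, mycn_call)

  if (!has_segmental) {
    chrom_d <- d
    if (isTRUE(mycn_amp)) chrom_d <- chrom_d[chrom_d$region != "MYCN", ]
    chroms <- unique(chrom_d$chromosome)
    wc_calls <- purrr::map_dfr(chroms, function(ch) {
      sub <- chrom_d[chrom_d$chromosome == ch, ]
      score_whole_chromosome(named_dq(sub[sub$arm == "p", ]),
                             named_dq(sub[sub$arm == "q", ]), rules) %>%
        mutate(region = ch, scope = "whole_chromosome", .before = 1)
    })
    calls <- bind_rows(calls, wc_calls)
    category <- if (any(wc_calls$status %in% c("loss", "gain"))) {
      "numerical"
    } else {
      "none"
    }
  } else {
    category <- "segmental"
  }

  if (nrow(calls) == 0 || all(calls$status == "no_data")) {
    warn(paste0("sample ", sid, ": no region evaluable"))
    category <- "none"
  }
  tibble(sample_id = sid, category = category, mycn_amplified = mycn_amp,
         region_calls = list(select(calls, all_of(
           c("region", "scope", "status", "rule_fired", "supporting_loci")))))
}

#' Flatten region calls out of a classification
#'
#' @param classification Tibble from [classify_samples()].
#' @return Tibble with one row per (sample, evaluated region): `sample_id`,
#'   `region`, `scope`, `status`, `rule_fired`, `supporting_loci`
#'   (semicolon-separated amplicon ids).
#' @export
region_calls <- function(classification) {
  classification %>%
    select(all_of(c("sample_id", "region_calls"))) %>%
    tidyr::unnest("region_calls") %>%
    mutate(supporting_loci = vapply(.data$supporting_loci,
                                    paste, character(1), collapse = ";"))
}

#' Write region calls as TSV
#'
#' @param calls Tibble from [region_calls()].
#' @param path Output path.
#' @param header_comment Optional character vector of provenance lines to
#'   prepend as `#` comments (rule set, seed, version).
#' @return The path, invisibly.
#' @export
write_calls <- function(calls, path, header_comment = NULL) {
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), path)
    readr::write_tsv(calls, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(calls, path)
  }
  invisible(path)
}

#' Read region calls written by [write_calls()]
#'
#' @param path File path.
#' @return Tibble of calls.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("calls file not found: ", path), class = "maq_io_error")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    .default = readr::col_character()))
}
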