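#' Simulate per-amplicon copy numbers
#'
#' Lays a background ploidy over every locus of the panel set, applies
#' events additively (an event names either an arm region such as `"1p"` or
#' a bare chromosome such as `"17"`, in which case all loci on that
#' chromosome — reference amplicons included — are shifted), then sets the
#' MYCN loci to `mycn_copies` if given, and finally applies explicit copy
#' overrides on reference regions. Any locus ending below zero copies is a
#' configuration error.
#'
#' @param panels A [maq_panel()] or a list of them.
#' @param background_ploidy Copies per locus before events (2 diploid,
#'   3 near-triploid).
#' @param events Data frame with columns `region` and `change` (signed
#'   integer copies), or `NULL`.
#' @param mycn_copies Total MYCN copy number, or `NULL` to leave the MYCN
#'   loci at their chromosome's value.
#' @param reference_overrides Data frame with columns `region` (e.g. `"5q"`
#'   or a chromosome) and `copies` (absolute), or `NULL`.
#' @return Tibble with one row per amplicon: `amplicon_id`, `kit_id`,
#'   `chromosome`, `arm`, `position`, `expected_length`, `role`, `region`,
#'   `copies`.
#' @export
#' @examples
#' cn <- simulate_copy_numbers(nb_panels(), events = data.frame(
#'   region = "1p", change = -1L
#' ))
#' table(cn$copies)
simulate_copy_numbers <- function(panels, background_ploidy = 2L,
                                  events = NULL, mycn_copies = NULL,
                                  reference_overrides = NULL) {
  amp <- panel_amplicons(panels)
  amp$copies <- as.numeric(background_ploidy)
  if (!is.null(events) && nrow(as.data.frame(events)) > 0) {
    events <- as.data.frame(events)
    for (i in seq_len(nrow(events))) {
      hit <- locus_selector(amp, events$region[i])
      if (!any(hit)) {
        abort(paste0("event region '", events$region[i],
                     "' matches no panel locus"),
              class = "maq_config_error")
      }
      amp$copies[hit] <- amp$copies[hit] + events$change[i]
    }
  }
  if (!is.null(mycn_copies)) {
    amp$copies[amp$region == "MYCN"] <- as.numeric(mycn_copies)
  }
  if (!is.null(reference_overrides) &&
      nrow(as.data.frame(reference_overrides)) > 0) {
    ro <- as.data.frame(reference_overrides)
    for (i in seq_len(nrow(ro))) {
      hit <- locus_selector(amp, ro$region[i]) & amp$role == "reference"
      amp$copies[hit] <- as.numeric(ro$copies[i])
    }
  }
  if (any(amp$copies < 0)) {
    abort("events yield negative copy numbers", class = "maq_config_error")
  }
  amp
}

panel_amplicons <- function(panels) {
  if (inherits(panels, "maq_panel")) panels <- list(panels)
  purrr::map_dfr(panels, function(p) {
    as_tibble(p) %>%
      mutate(kit_id = kit_id(p)) %>%
      rename(amplicon_id = "id")
  })
}

# a selector names an arm region ("1p", "MYCN", "5q") or a chromosome ("17")
locus_selector <- function(amp, sel) {
  if (sel %in% amp$region) amp$region == sel else amp$chromosome == sel
}

#' Simulate a fragment-analysis run from copy numbers
#'
#' Peak areas follow `baseline_area * efficiency * (copies / 2) *
#' exp(N(0, sigma))`: fluorescence is proportional to locus copy number,
#' scaled by a fixed per-amplicon amplification efficiency and corrupted by
#' multiplicative lognormal noise (peak areas are positive and their error
#' scales with signal). With `sigma = 0` the output is deterministic.
#' Fragment sizes are emitted at the designed lengths; size-calling jitter
#' is far below the matching tolerance on modern capillary systems and is
#' not modelled.
#'
#' @param copies Tibble from [simulate_copy_numbers()] (column `copies` may
#'   be fractional, e.g. for subclonal events).
#' @param sample_id Sample name for the emitted rows.
#' @param sigma Standard deviation of the lognormal noise on the log scale.
#' @param baseline_area Mean area of a two-copy locus at efficiency 1.
#' @param efficiencies Named numeric vector of per-amplicon efficiency
#'   factors (default all 1). Held fixed across samples of a run, these
#'   cancel in the dosage quotient — the reason the double ratio works.
#' @return Peak-table tibble: `kit_id`, `sample_id`, `fragment_size`,
#'   `peak_area`.
#' @export
simulate_peaks <- function(copies, sample_id, sigma = 0.03,
                           baseline_area = 10000, efficiencies = NULL) {
  stopifnot(baseline_area > 0, sigma >= 0)
  eff <- rep(1, nrow(copies))
  if (!is.null(efficiencies)) {
    eff <- unname(efficiencies[copies$amplicon_id])
    if (anyNA(eff) || any(eff <= 0)) {
      abort("efficiencies must be positive and cover every amplicon",
            class = "maq_config_error")
    }
  }
  noise <- if (sigma > 0) rlnorm(nrow(copies), 0, sigma) else 1
  tibble(
    kit_id = copies$kit_id,
    sample_id = sample_id,
    fragment_size = copies$expected_length,
    peak_area = baseline_area * eff * (copies$copies / 2) * noise
  )
}

#' Simulate a validation cohort
#'
#' Generates a reproducible cohort of tumor samples, control samples and a
#' matched gold-standard table with the structure of a typical
#' neuroblastoma validation series: `n_segmental` samples carrying clonal
#' segmental events drawn from the prognostic regions (1p/3p/11q loss,
#' 17q gain), a subset of them MYCN-amplified and a subset on a
#' near-triploid background, plus `n_numerical` near-triploid samples with
#' whole-chromosome changes only, whose reference chromosomes are
#' themselves frequently co-aberrant — the normalization confound that
#' makes numerical calling hard. Whole-chromosome events are attenuated by
#' `numerical_clonality` (observed copies `3 + clonality * (true - 3)`):
#' in aneuploid tumors such imbalances present as compressed dosage shifts
#' that barely reach the +-0.1 majority threshold, rather than the full
#' one-copy ratio. The gold standard is derived from the simulated truth
#' and never from any caller output.
#'
#' @param panels Panel set (default the built-in three kits).
#' @param n_segmental,n_numerical Tumor counts per category (defaults 35
#'   and 17, the published validation design).
#' @param n_mycn_amplified Number of segmental samples with MYCN
#'   amplification (default 22: 19 tumors plus 3 cell lines).
#' @param n_seg_triploid Segmental samples on a near-triploid background
#'   (default 15).
#' @param n_controls Diploid control samples (default 2).
#' @param sigma Lognormal noise sd; the default 0.03 is calibrated so that
#'   replicate DQ differences reproduce the assay's reported Bland-Altman
#'   repeatability of about 0.10-0.12 (1.96 * SD of replicate differences
#'   is about 3.4 * sigma under this design).
#' @param baseline_area See [simulate_peaks()].
#' @param numerical_clonality Attenuation of whole-chromosome events
#'   (default 1/3, giving observed DQ about 0.89/1.11 for one-copy
#'   changes on a near-triploid background).
#' @param seg_region_prob Named per-region event probabilities for
#'   segmental samples.
#' @param num_chrom_prob Named per-chromosome aberration probabilities for
#'   numerical samples.
#' @param num_gain_prob Named probability that an aberrant chromosome is
#'   gained rather than lost.
#' @param seed Integer seed; the whole cohort is a pure function of it.
#' @return A `maq_cohort` list: `peaks` (named list of peak tables, one per
#'   kit), `sample_sheet`, `gold`, `truth` (long event table), `panels`,
#'   `params`.
#' @export
simulate_cohort <- function(panels = nb_panels(),
                            n_segmental = 35, n_numerical = 17,
                            n_mycn_amplified = 22, n_seg_triploid = 15,
                            n_controls = 2,
                            sigma = 0.03, baseline_area = 10000,
                            numerical_clonality = 1 / 3,
                            seg_region_prob = c("1p" = 18 / 35, "3p" = 10 / 35,
                                                "11q" = 13 / 35, "17q" = 27 / 35),
                            num_chrom_prob = c("1" = 9 / 17, "2" = 10 / 17,
                                               "3" = 13 / 17, "11" = 14 / 17,
                                               "17" = 16 / 17),
                            num_gain_prob = c("1" = 0.6, "2" = 0.6, "3" = 0.3,
                                              "11" = 0.3, "17" = 0.95),
                            seed = 1L) {
  stopifnot(n_segmental >= 0, n_numerical >= 0, n_controls >= 1,
            n_mycn_amplified <= n_segmental, n_seg_triploid <= n_segmental)
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    amp <- panel_amplicons(panels)
    efficiencies <- setNames(rlnorm(nrow(amp), 0, 0.2), amp$amplicon_id)

    seg_ids <- sprintf("SEG%02d", seq_len(n_segmental))
    num_ids <- sprintf("NUM%02d", seq_len(n_numerical))
    ctl_ids <- sprintf("CTRL%d", seq_len(n_controls))
    mycn_pos <- seg_ids[sample_ids_subset(n_segmental, n_mycn_amplified)]
    triploid <- seg_ids[sample_ids_subset(n_segmental, n_seg_triploid)]

    truth <- list()
    peaks <- list()
    gold <- list()

    loss_dir <- c("1p" = -1L, "3p" = -1L, "11q" = -1L, "17q" = +1L)

    for (sid in seg_ids) {
      bg <- if (sid %in% triploid) 3L else 2L
      repeat {
        has <- stats::runif(length(seg_region_prob)) < seg_region_prob
        if (any(has)) break
      }
      regions <- names(seg_region_prob)[has]
      events <- tibble(region = regions, change = unname(loss_dir[regions]))
      mycn_cp <- if (sid %in% mycn_pos) sample(15:60, 1) else NULL
      cn <- simulate_copy_numbers(panels, background_ploidy = bg,
                                  events = events, mycn_copies = mycn_cp)
      peaks[[sid]] <- simulate_peaks(cn, sid, sigma = sigma,
                                     baseline_area = baseline_area,
                                     efficiencies = efficiencies)
      truth[[sid]] <- tibble(
        sample_id = sid, group = "segmental", background_ploidy = bg,
        region = c(names(seg_region_prob), "MYCN"),
        scope = "segmental",
        positive = c(has, !is.null(mycn_cp)),
        change = c(ifelse(has, unname(loss_dir[names(seg_region_prob)]), 0L),
                   if (is.null(mycn_cp)) 0L else as.integer(mycn_cp))
      )
      gold[[sid]] <- tibble(
        sample_id = sid, region = truth[[sid]]$region,
        status = ifelse(truth[[sid]]$positive, "positive", "negative")
      )
    }

    for (sid in num_ids) {
      bg <- 3L
      aberrant <- stats::runif(length(num_chrom_prob)) < num_chrom_prob
      chroms <- names(num_chrom_prob)[aberrant]
      dirs <- ifelse(stats::runif(length(chroms)) <
                       num_gain_prob[chroms], 1L, -1L)
      # references co-aberrant in nearly every near-triploid tumor, but as
      # low-level (weakly clonal) changes: typically one of the four ref
      # chromosomes, at half the attenuated deviation of the primary events
      n_ref_ab <- sample(0:2, 1, prob = c(0.06, 0.70, 0.24))
      ref_chroms <- sample(c("5", "13", "21", "22"), n_ref_ab)
      ref_dirs <- ifelse(stats::runif(length(ref_chroms)) < 0.5, 1L, -1L)
      cn <- simulate_copy_numbers(panels, background_ploidy = bg)
      for (i in seq_along(chroms)) {
        hit <- cn$chromosome == chroms[i]
        cn$copies[hit] <- bg + numerical_clonality * dirs[i]
      }
      for (i in seq_along(ref_chroms)) {
        hit <- cn$chromosome == ref_chroms[i]
        cn$copies[hit] <- bg + numerical_clonality / 2 * ref_dirs[i]
      }
      peaks[[sid]] <- simulate_peaks(cn, sid, sigma = sigma,
                                     baseline_area = baseline_area,
                                     efficiencies = efficiencies)
      all_dirs <- integer(length(num_chrom_prob))
      all_dirs[aberrant] <- dirs
      truth[[sid]] <- tibble(
        sample_id = sid, group = "numerical", background_ploidy = bg,
        region = names(num_chrom_prob), scope = "whole_chromosome",
        positive = aberrant, change = all_dirs
      )
      gold[[sid]] <- tibble(
        sample_id = sid, region = names(num_chrom_prob),
        status = ifelse(aberrant, "positive", "negative")
      )
    }

    for (sid in ctl_ids) {
      cn <- simulate_copy_numbers(panels, background_ploidy = 2L)
      peaks[[sid]] <- simulate_peaks(cn, sid, sigma = sigma,
                                     baseline_area = baseline_area,
                                     efficiencies = efficiencies)
    }

    all_peaks <- bind_rows(peaks)
    peak_tables <- lapply(split(all_peaks, all_peaks$kit_id), function(x) {
      select(as_tibble(x), all_of(c("sample_id", "fragment_size", "peak_area")))
    })

    sample_sheet <- tibble(
      sample_id = c(seg_ids, num_ids, ctl_ids),
      kind = c(rep("tumor", n_segmental + n_numerical),
               rep("control", n_controls))
    )

    structure(
      list(
        peaks = peak_tables,
        sample_sheet = sample_sheet,
        gold = if (length(gold) > 0) bind_rows(gold) else
          tibble(sample_id = character(), region = character(),
                 status = character()),
        truth = if (length(truth) > 0) bind_rows(truth) else
          tibble(sample_id = character(), group = character(),
                 background_ploidy = integer(), region = character(),
                 scope = character(), positive = logical(),
                 change = integer()),
        panels = panels,
        params = list(seed = seed, sigma = sigma,
                      n_segmental = n_segmental, n_numerical = n_numerical,
                      n_mycn_amplified = n_mycn_amplified,
                      n_seg_triploid = n_seg_triploid,
                      n_controls = n_controls,
                      numerical_clonality = numerical_clonality,
                      baseline_area = baseline_area)
      ),
      class = "maq_cohort"
    )
  })
}

# deterministic subset of 1..n of size k
sample_ids_subset <- function(n, k) {
  if (k == 0) return(integer())
  sample(seq_len(n), k)
}

#' @export
print.maq_cohort <- function(x, ...) {
  cat("# Simulated cohort: ", x$params$n_segmental, " segmental + ",
      x$params$n_numerical, " numerical tumors, ", x$params$n_controls,
      " controls; sigma ", x$params$sigma, ", seed ", x$params$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits one peak table per kit (`peaks_<kit>.tsv`), the sample sheet, the
#' gold standard, the truth table and a YAML manifest recording the seed
#' and generator parameters. Every TSV carries the seed in a header
#' comment.
#'
#' @param cohort A `maq_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("seed: ", cohort$params$seed)
  wr <- function(x, name) {
    path <- file.path(dir, name)
    writeLines(paste0("# ", stamp), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  }
  for (kit in names(cohort$peaks)) {
    wr(cohort$peaks[[kit]], paste0("peaks_", kit, ".tsv"))
  }
  wr(cohort$sample_sheet, "sample_sheet.tsv")
  wr(cohort$gold, "gold_standard.tsv")
  wr(cohort$truth, "truth.tsv")
  yaml::write_yaml(cohort$params, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Run the full calling pipeline on a cohort
#'
#' Matches peaks, computes dosage quotients per kit (kits are never pooled
#' before scoring) and classifies every tumor sample under the given rule
#' set.
#'
#' @param cohort A `maq_cohort`, or a list with elements `peaks` (named
#'   list of peak tables), `sample_sheet` and `panels`.
#' @param rules Rule set or name, see [as_ruleset()].
#' @return List: `dq` (bound DQ tibble), `classification` (from
#'   [classify_samples()]), `calls` (from [region_calls()]).
#' @export
call_cohort <- function(cohort, rules = maq_rules()) {
  rules <- as_ruleset(rules)
  dq <- purrr::map_dfr(names(cohort$panels), function(kit) {
    panel <- cohort$panels[[kit]]
    runs <- match_peaks(cohort$peaks[[kit]], panel)
    dq_profile(runs, panel, cohort$sample_sheet)
  })
  classification <- classify_samples(dq, rules)
  list(dq = dq, classification = classification,
       calls = region_calls(classification))
}
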