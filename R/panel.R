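#' Construct a multiplex amplicon panel
#'
#' A panel describes one multiplex PCR kit: a set of amplicons, each a point
#' locus with a designed fragment length that is unique within the kit so that
#' capillary-electrophoresis peaks can be demultiplexed by size alone.
#' Amplicons are either `target` (inside a region of interest) or `reference`
#' (in rarely altered regions, here 5q/13q/21q/22q, used as normalization
#' denominators).
#'
#' @param amplicons Data frame with columns `id`, `chromosome`, `arm` ("p" or
#'   "q"), `position` (1-based bp), `expected_length` (bp), `role` ("target"
#'   or "reference") and `region` (e.g. "1p", "17q", "MYCN").
#' @param kit_id Single string naming the kit.
#' @param length_tolerance Maximum distance (bp) between an observed fragment
#'   size and an amplicon's designed length for peak assignment. Default 0.5
#'   bp: designed lengths are unique, so the nearest length within half a base
#'   is unambiguous.
#'
#' @return A `maq_panel`: a tibble of amplicons ordered by chromosome, arm and
#'   position, with attributes `kit_id` and `length_tolerance`.
#' @export
#' @examples
#' p <- maq_panel(
#'   tibble::tibble(
#'     id = c("t1", "t2", "r1"), chromosome = c("2", "2", "5"),
#'     arm = c("p", "p", "q"), position = c(100L, 200L, 500L),
#'     expected_length = c(100, 110, 120),
#'     role = c("target", "target", "reference"),
#'     region = c("MYCN", "MYCN", "5q")
#'   ),
#'   kit_id = "demo"
#' )
#' p
maq_panel <- function(amplicons, kit_id = "panel", length_tolerance = 0.5) {
  required <- c("id", "chromosome", "arm", "position", "expected_length",
                "role", "region")
  missing_cols <- setdiff(required, names(amplicons))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "maq_format_error")
  }
  amp <- as_tibble(amplicons) %>%
    mutate(
      id = as.character(.data$id),
      chromosome = as.character(.data$chromosome),
      arm = as.character(.data$arm),
      position = as.integer(.data$position),
      expected_length = as.numeric(.data$expected_length),
      role = as.character(.data$role),
      region = as.character(.data$region)
    ) %>%
    select(all_of(required))
  validate_panel(amp, kit_id)
  if (length_tolerance < 0) {
    abort("length_tolerance must be non-negative", class = "maq_validation_error")
  }
  amp <- arrange(amp, .data$chromosome, .data$arm, .data$position)
  structure(amp,
            kit_id = as.character(kit_id),
            length_tolerance = as.numeric(length_tolerance),
            class = c("maq_panel", class(amp)))
}

validate_panel <- function(amp, kit_id) {
  err <- function(msg) abort(paste0("panel '", kit_id, "': ", msg),
                             class = "maq_validation_error")
  if (nrow(amp) == 0) err("contains no amplicons")
  if (anyDuplicated(amp$id)) err("duplicate amplicon ids")
  if (!all(amp$arm %in% c("p", "q"))) err("arm must be 'p' or 'q'")
  if (!all(amp$role %in% c("target", "reference"))) {
    err("role must be 'target' or 'reference'")
  }
  if (any(!is.finite(amp$position) | amp$position <= 0)) err("positions must be > 0")
  if (any(!is.finite(amp$expected_length) | amp$expected_length <= 0)) {
    err("expected lengths must be > 0")
  }
  dup <- amp$expected_length[duplicated(amp$expected_length)]
  if (length(dup) > 0) {
    clash <- amp$id[amp$expected_length %in% dup]
    err(paste0("expected fragment lengths must be unique within a kit; ",
               "colliding amplicons: ", paste(clash, collapse = ", ")))
  }
  if (!any(amp$role == "reference")) err("needs at least one reference amplicon")
  if (!any(amp$role == "target")) err("needs at least one target amplicon")
  if (any(amp$role == "target" & (is.na(amp$region) | amp$region == ""))) {
    err("target amplicons must carry a non-empty region label")
  }
  ref <- amp[amp$role == "reference", ]
  bad_ref <- ref$region != paste0(ref$chromosome, ref$arm)
  if (any(bad_ref)) {
    err(paste0("reference amplicons must use their arm as region label: ",
               paste(ref$id[bad_ref], collapse = ", ")))
  }
  invisible(amp)
}

#' @export
print.maq_panel <- function(x, ...) {
  cat("# Amplicon panel '", kit_id(x), "': ",
      sum(x$role == "target"), " targets, ",
      sum(x$role == "reference"), " references, length tolerance ",
      length_tolerance(x), " bp\n", sep = "")
  NextMethod()
}

#' Panel attribute accessors
#'
#' @param panel A [maq_panel()].
#' @return `kit_id()` the kit name; `length_tolerance()` the peak-matching
#'   tolerance in bp.
#' @export
kit_id <- function(panel) attr(panel, "kit_id")

#' @rdname kit_id
#' @export
length_tolerance <- function(panel) attr(panel, "length_tolerance")

#' Read or write a panel definition TSV
#'
#' The canonical panel format is a tab-delimited file with header columns
#' `id`, `chromosome`, `arm`, `position`, `expected_length`, `role`, `region`.
#' Lines starting with `#` are ignored. `write_panel()` and `read_panel()`
#' round-trip all fields exactly.
#'
#' @param path File path.
#' @param kit_id Kit name to attach (default: file name without extension).
#' @inheritParams maq_panel
#' @return `read_panel()` a [maq_panel()]; `write_panel()` the path, invisibly.
#' @export
read_panel <- function(path, kit_id = NULL, length_tolerance = 0.5) {
  if (!file.exists(path)) {
    abort(paste0("panel file not found: ", path), class = "maq_io_error")
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  kit_id <- kit_id %||% sub("\\.[^.]*$", "", basename(path))
  maq_panel(raw, kit_id = kit_id, length_tolerance = length_tolerance)
}

#' @rdname read_panel
#' @param panel A [maq_panel()].
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(as_tibble(panel), path)
  invisible(path)
}

#' Export a panel as BED for genome-browser display
#'
#' Point loci are written as 0-based half-open single-base intervals
#' (`chromosome`, `position - 1`, `position`, `id`).
#'
#' @inheritParams write_panel
#' @return The path, invisibly.
#' @export
panel_to_bed <- function(panel, path) {
  bed <- tibble(
    chrom = panel$chromosome,
    start = panel$position - 1L,
    end = panel$position,
    name = panel$id
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Regions of interest covered by a panel
#'
#' One row per target region, with its chromosome, arm and kind:
#' `segmental_locus_set` for arm regions scored by the segmental rules, or
#' `mycn_locus_set` for the MYCN amplification locus set.
#'
#' @inheritParams write_panel
#' @return Tibble with columns `region`, `chromosome`, `arm`, `kind`,
#'   `n_amplicons`.
#' @export
panel_regions <- function(panel) {
  panel %>%
    filter(.data$role == "target") %>%
    group_by(region = .data$region) %>%
    summarise(
      chromosome = .data$chromosome[1],
      arm = .data$arm[1],
      kind = if (.data$region[1] == "MYCN") "mycn_locus_set" else "segmental_locus_set",
      n_amplicons = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$chromosome, .data$arm)
}

#' Target amplicons of one region, in genomic order
#'
#' @inheritParams write_panel
#' @param region Region label present in the panel (e.g. `"1p"`, `"MYCN"`).
#' @return Tibble of the region's target amplicons sorted by ascending
#'   position (stable; positions are unique within a panel in practice).
#' @export
resolve_region <- function(panel, region) {
  hits <- panel %>%
    filter(.data$role == "target", .data$region == !!region) %>%
    arrange(.data$position)
  if (nrow(hits) == 0) {
    abort(paste0("region '", region, "' has no target amplicons in panel '",
                 kit_id(panel), "'"),
          class = "maq_lookup_error")
  }
  as_tibble(hits)
}

#' Built-in neuroblastoma panels
#'
#' Three synthetic fixture kits mirroring the published structure of the
#' NB assay: kit 1 with 21 targets on chromosomes 3 and 17, kit 2 with 19
#' targets on chromosomes 1 and 11, and a separate MYCN kit 3 with 9 targets
#' on chromosome 2 (3 MYCN amplicons on 2p plus the 2q opposite arm; MYCN is
#' isolated in its own kit because high-level amplification interferes with
#' quantification of co-amplified loci). Each kit carries 8 or 9 reference
#' amplicons spread evenly over 5q, 13q, 21q and 22q, and each target
#' chromosome is covered on both arms so whole-chromosome changes can be
#' assessed. Coordinates are invented (the panels are fixtures): they encode
#' only arm membership and ordering, not real primer positions.
#'
#' @param length_tolerance Peak-matching tolerance in bp, see [maq_panel()].
#' @return Named list of three [maq_panel()] objects (`kit1`, `kit2`, `kit3`).
#' @export
#' @examples
#' panels <- nb_panels()
#' sapply(panels, function(p) sum(p$role == "target"))
nb_panels <- function(length_tolerance = 0.5) {
  list(
    kit1 = nb_kit(
      "kit1",
      targets = list(`3` = c(p = 6, q = 4), `17` = c(p = 4, q = 7)),
      n_ref = 9, length_tolerance = length_tolerance
    ),
    kit2 = nb_kit(
      "kit2",
      targets = list(`1` = c(p = 6, q = 4), `11` = c(p = 4, q = 5)),
      n_ref = 9, length_tolerance = length_tolerance
    ),
    kit3 = nb_kit(
      "kit3",
      targets = list(`2` = c(p = 3, q = 6)),
      n_ref = 8, mycn = TRUE, length_tolerance = length_tolerance
    )
  )
}

# builds one fixture kit; fragment lengths 100, 106, 112, ... are unique by
# construction; p-arm positions sit below an arbitrary centromere at 5e7
nb_kit <- function(kit_id, targets, n_ref, mycn = FALSE, length_tolerance = 0.5) {
  rows <- list()
  for (chrom in names(targets)) {
    for (arm in c("p", "q")) {
      k <- targets[[chrom]][[arm]]
      if (is.null(k) || k == 0) next
      pos <- if (arm == "p") seq(5e6, 4e7, length.out = k) else
        seq(6e7, 1.2e8, length.out = k)
      region <- if (mycn && chrom == "2" && arm == "p") "MYCN" else paste0(chrom, arm)
      rows[[length(rows) + 1]] <- tibble(
        id = sprintf("%s_%s%s_%02d", kit_id, chrom, arm, seq_len(k)),
        chromosome = chrom, arm = arm, position = as.integer(round(pos)),
        role = "target", region = region
      )
    }
  }
  ref_chroms <- c("5", "13", "21", "22")
  per <- rep(n_ref %/% 4, 4) + c(rep(1, n_ref %% 4), rep(0, 4 - n_ref %% 4))
  for (i in seq_along(ref_chroms)) {
    k <- per[i]
    if (k == 0) next
    rows[[length(rows) + 1]] <- tibble(
      id = sprintf("%s_ref%s_%02d", kit_id, ref_chroms[i], seq_len(k)),
      chromosome = ref_chroms[i], arm = "q",
      position = as.integer(round(seq(6e7, 9e7, length.out = k))),
      role = "reference", region = paste0(ref_chroms[i], "q")
    )
  }
  amp <- bind_rows(rows)
  amp$expected_length <- 100 + 6 * (seq_len(nrow(amp)) - 1)
  maq_panel(amp, kit_id = kit_id, length_tolerance = length_tolerance)
}
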