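# small panels and measurement tables built in code

tiny_panel <- function(n_targets = 4, n_refs = 2, region = "2p",
                       chromosome = "2", arm = "p", kit_id = "tiny",
                       length_tolerance = 0.5) {
  amp <- tibble::tibble(
    id = c(sprintf("t%02d", seq_len(n_targets)),
           sprintf("r%02d", seq_len(n_refs))),
    chromosome = c(rep(chromosome, n_targets), rep("5", n_refs)),
    arm = c(rep(arm, n_targets), rep("q", n_refs)),
    position = c(seq(1e6, 2e6, length.out = n_targets),
                 seq(5e6, 6e6, length.out = n_refs)),
    expected_length = 100 + 10 * seq_len(n_targets + n_refs),
    role = c(rep("target", n_targets), rep("reference", n_refs)),
    region = c(rep(region, n_targets), rep("5q", n_refs))
  )
  maq_panel(amp, kit_id = kit_id, length_tolerance = length_tolerance)
}

# long measurement table from named area vectors
runs_from_areas <- function(...) {
  samples <- list(...)
  purrr::map_dfr(names(samples), function(sid) {
    tibble::tibble(sample_id = sid,
                   amplicon_id = names(samples[[sid]]),
                   peak_area = unname(samples[[sid]]))
  })
}

sheet_for <- function(tumors, controls) {
  tibble::tibble(sample_id = c(tumors, controls),
                 kind = c(rep("tumor", length(tumors)),
                          rep("control", length(controls))))
}

# DQ tibble for scoring tests: one sample, loci laid out per region spec
# regions: named list region -> list(chromosome, arm, dq vector)
dq_from_values <- function(regions, sample_id = "S1") {
  purrr::map_dfr(names(regions), function(r) {
    x <- regions[[r]]
    k <- length(x$dq)
    tibble::tibble(
      sample_id = sample_id,
      amplicon_id = paste0(r, "_", seq_len(k)),
      region = r, chromosome = x$chromosome, arm = x$arm,
      position = seq_len(k) * 1e6 + (x$arm == "q") * 5e7,
      kit_id = "tiny",
      dq_mean = x$dq, dq_sd = 0, n_combinations = 2L
    )
  })
}
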