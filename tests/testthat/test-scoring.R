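test_that("segmental scoring follows the consecutive-loci clause", {
  maq <- maq_rules()
  r <- score_segmental(c(a = 0.79, b = 0.78, c = 1.01, d = 0.99), maq)
  expect_identical(r$status, "loss")
  expect_identical(r$rule_fired, "consecutive_loss")
  expect_identical(r$supporting_loci[[1]], c("a", "b"))

  # alternating deviants never sit adjacent
  expect_identical(score_segmental(c(0.79, 1.00, 0.79, 1.00), maq)$status,
                   "normal")
  # thresholds are inclusive
  expect_identical(score_segmental(c(1.20, 1.20), maq)$status, "gain")
  expect_identical(score_segmental(c(0.80, 0.80), maq)$status, "loss")
  # a failed locus breaks adjacency
  expect_identical(score_segmental(c(0.75, NA, 0.75, 1), maq)$status, "normal")
  # mixed directions never call
  expect_identical(score_segmental(c(0.7, 1.3, 0.7), maq)$status, "normal")
  # fewer than two numeric loci is unevaluable
  expect_identical(score_segmental(c(0.5, NA), maq)$status, "no_data")
  expect_identical(score_segmental(numeric(), maq)$status, "no_data")
})

test_that("the MLPA fraction clause rescues sub-threshold consistent shifts", {
  mlpa <- mlpa_rules()
  dq <- c(0.85, 0.84, 0.85, 0.83, 0.85, 0.82, 0.85, 1.0)
  # 7 of 8 loci at a deviation of at least 0.15, never 2 consecutive at 0.75
  r <- score_segmental(dq, mlpa)
  expect_identical(r$status, "loss")
  expect_identical(r$rule_fired, "fraction_loss")
  # the same profile is normal under the MAQ set (no fraction clause,
  # consecutive threshold 0.8 not reached twice in a row)
  expect_identical(score_segmental(dq, maq_rules())$status, "normal")
  # exactly 75% does not trigger (the clause is strictly more than)
  dq8 <- c(0.84, 0.84, 0.92, 0.84, 0.84, 0.91, 0.84, 0.84)
  expect_identical(score_segmental(dq8, mlpa)$status, "normal")
})

test_that("whole-chromosome scoring needs both arms off 1 plus a deviating majority", {
  maq <- maq_rules()
  # both arms fully below 1, 4 of 5 loci deviating by at least 0.1
  r <- score_whole_chromosome(c(0.88, 0.85, 0.91), c(0.87, 0.89), maq)
  expect_identical(r$status, "loss")
  # both arms below 1 but no locus deviates by 0.1: majority clause fails
  expect_identical(
    score_whole_chromosome(c(0.95, 0.96), c(0.94, 0.97), maq)$status,
    "normal")
  # arms disagreeing in direction never call
  expect_identical(
    score_whole_chromosome(c(1.2, 1.2), c(0.8, 0.8), maq)$status,
    "normal")
  # an empty arm is unevaluable
  expect_identical(
    score_whole_chromosome(numeric(), c(0.8, 0.8), maq)$status, "no_data")
  expect_identical(
    score_whole_chromosome(c(NA_real_, NA_real_), c(0.8, 0.8), maq)$status,
    "no_data")
  # symmetric gain
  expect_identical(
    score_whole_chromosome(c(1.12, 1.15, 1.09), c(1.13, 1.11), maq)$status,
    "gain")
})

test_that("MYCN amplification needs every required locus at a 3-fold increase", {
  maq <- maq_rules()
  expect_identical(score_mycn(c(12.1, 10.4, 15.0), maq)$status, "amplified")
  expect_identical(score_mycn(c(3.5, 4.2, 4.1), maq)$status, "normal")
  expect_identical(score_mycn(c(4.0, 4.0, 4.0), maq)$status, "amplified")
  expect_identical(score_mycn(c(12, 11, NA), maq)$status, "no_data")
  # the MLPA set needs only two measurable loci
  expect_identical(score_mycn(c(12, 11, NA), mlpa_rules())$status, "amplified")
  # alternative absolute reading as a config override
  abs_rules <- maq_rules(mycn_absolute = TRUE)
  expect_identical(score_mycn(c(3.2, 3.5, 3.1), abs_rules)$status, "amplified")
})

test_that("sample classification applies global segmental precedence", {
  # a segmental-looking tumor: 1p deep loss, MYCN high, 17q gain
  dq <- dq_from_values(list(
    `1p` = list(chromosome = "1", arm = "p", dq = c(0.55, 0.52, 0.5, 0.53)),
    `1q` = list(chromosome = "1", arm = "q", dq = c(1.0, 1.02, 0.98)),
    MYCN = list(chromosome = "2", arm = "p", dq = c(12.5, 11.8, 13.0)),
    `2q` = list(chromosome = "2", arm = "q", dq = c(1.0, 1.01, 0.99)),
    `17q` = list(chromosome = "17", arm = "q", dq = c(1.5, 1.45, 1.52)),
    `17p` = list(chromosome = "17", arm = "p", dq = c(1.0, 1.0, 1.0))
  ))
  cl <- classify_samples(dq, maq_rules())
  expect_identical(cl$category, "segmental")
  expect_true(cl$mycn_amplified)
  calls <- region_calls(cl)
  expect_false(any(calls$scope == "whole_chromosome"))
  expect_identical(calls$status[calls$region == "1p"], "loss")
  expect_identical(calls$status[calls$region == "17q"], "gain")

  # a numerical tumor: compressed whole-chromosome shifts, nothing segmental
  dqn <- dq_from_values(list(
    `1p` = list(chromosome = "1", arm = "p", dq = c(1.13, 1.11, 1.12)),
    `1q` = list(chromosome = "1", arm = "q", dq = c(1.12, 1.14, 1.11)),
    `3p` = list(chromosome = "3", arm = "p", dq = c(0.89, 0.88, 0.9)),
    `3q` = list(chromosome = "3", arm = "q", dq = c(0.88, 0.87, 0.89))
  ))
  cln <- classify_samples(dqn, maq_rules())
  expect_identical(cln$category, "numerical")
  callsn <- region_calls(cln)
  expect_identical(callsn$status[callsn$region == "1"], "gain")
  expect_identical(callsn$status[callsn$region == "3"], "loss")

  # a flat profile is neither
  dq0 <- dq_from_values(list(
    `1p` = list(chromosome = "1", arm = "p", dq = rep(1, 4)),
    `1q` = list(chromosome = "1", arm = "q", dq = rep(1, 3)),
    MYCN = list(chromosome = "2", arm = "p", dq = rep(1, 3)),
    `2q` = list(chromosome = "2", arm = "q", dq = rep(1, 3))
  ))
  cl0 <- classify_samples(dq0, maq_rules())
  expect_identical(cl0$category, "none")
  expect_false(cl0$mycn_amplified)
})

test_that("amplified MYCN loci are excluded from chromosome-2 ploidy assessment", {
  dq <- dq_from_values(list(
    MYCN = list(chromosome = "2", arm = "p", dq = c(15, 14, 16)),
    `2q` = list(chromosome = "2", arm = "q", dq = c(1.0, 1.0, 1.0, 1.0))
  ))
  cl <- classify_samples(dq, maq_rules())
  expect_true(cl$mycn_amplified)
  calls <- region_calls(cl)
  wc2 <- calls[calls$scope == "whole_chromosome" & calls$region == "2", ]
  # with the MYCN loci removed, chromosome 2 has no p arm left to assess
  expect_identical(wc2$status, "no_data")

  # without amplification the MYCN loci stand in as the 2p arm
  dq2 <- dq_from_values(list(
    MYCN = list(chromosome = "2", arm = "p", dq = c(1.12, 1.13, 1.11)),
    `2q` = list(chromosome = "2", arm = "q", dq = c(1.12, 1.11, 1.13, 1.12))
  ))
  cl2 <- classify_samples(dq2, maq_rules())
  calls2 <- region_calls(cl2)
  expect_identical(
    calls2$status[calls2$scope == "whole_chromosome" & calls2$region == "2"],
    "gain")
})

test_that("rule engine matches the literal-text oracle on a DQ grid", {
  grid <- c(0.70, 0.75, 0.78, 0.80, 0.85, 1.0, 1.15, 1.2, 1.25, 1.3)
  rulesets <- list(MAQ = maq_rules(), MLPA = mlpa_rules())
  # exhaustive at 2 loci, sampled at longer regions (the acceptance suite
  # runs the deeper scan)
  combos <- list()
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    combos[[length(combos) + 1]] <- grid[c(i, j)]
  }
  withr::with_seed(21, {
    for (len in 3:8) {
      for (k in 1:60) {
        combos[[length(combos) + 1]] <- sample(grid, len, replace = TRUE)
      }
    }
  })
  for (set in names(rulesets)) {
    got <- vapply(combos, function(dq) {
      score_segmental(dq, rulesets[[set]])$status
    }, character(1))
    want <- vapply(combos, oracle_segmental, character(1), set = set)
    expect_identical(got, want)
  }
})

test_that("whole-chromosome and MYCN scoring match their oracles on random grids", {
  grid <- c(0.70, 0.78, 0.85, 0.88, 0.9, 1.0, 1.08, 1.1, 1.15, 1.25, 3.9, 4.0, 5)
  maq <- maq_rules()
  withr::with_seed(22, {
    for (k in 1:300) {
      p <- sample(grid, sample(1:5, 1), replace = TRUE)
      q <- sample(grid, sample(1:5, 1), replace = TRUE)
      expect_identical(score_whole_chromosome(p, q, maq)$status,
                       oracle_whole_chromosome(p, q))
      m <- sample(grid, 3, replace = TRUE)
      expect_identical(score_mycn(m, maq)$status, oracle_mycn(m, "MAQ"))
      expect_identical(score_mycn(m[1:2], mlpa_rules())$status,
                       oracle_mycn(m[1:2], "MLPA"))
    }
  })
})

test_that("calls are monotone in the DQs and deterministic", {
  maq <- maq_rules()
  withr::with_seed(23, {
    for (k in 1:50) {
      dq <- runif(6, 0.5, 1.5)
      r1 <- score_segmental(dq, maq)
      expect_identical(score_segmental(dq, maq), r1)
      if (r1$status == "loss") {
        lower <- dq - runif(6, 0, 0.3)
        expect_identical(score_segmental(lower, maq)$status, "loss")
      }
      if (r1$status == "gain") {
        higher <- dq + runif(6, 0, 0.3)
        expect_identical(score_segmental(higher, maq)$status, "gain")
      }
    }
  })
})

test_that("rule sets round-trip through YAML and presets load by name", {
  f <- withr::local_tempfile(fileext = ".yaml")
  r <- mlpa_rules()
  write_rules(r, f)
  expect_identical(read_rules(f), r)
  expect_identical(as_ruleset("maq")$segmental_delta, 0.2)
  expect_identical(as_ruleset("MLPA")$mycn_required_loci, 2L)
  preset <- system.file("extdata", "rules_mlpa.yaml", package = "maqcna")
  expect_identical(read_rules(preset), mlpa_rules())
  expect_error(as_ruleset("nope"), class = "maq_config_error")
})
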