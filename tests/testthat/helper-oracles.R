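# independent brute-force oracles, written as plain loops straight from the
# method definitions; they share no code with the implementation

# mean/sd/count of the double ratio over every (reference, control) pair
oracle_dq <- function(sample_areas, control_areas, target_id, reference_ids) {
  vals <- c()
  for (ref in reference_ids) {
    for (ctrl in control_areas) {
      ts <- sample_areas[target_id]
      rs <- sample_areas[ref]
      tc <- ctrl[target_id]
      rc <- ctrl[ref]
      four <- c(ts, rs, tc, rc)
      if (length(four) == 4 && !anyNA(four) && all(four > 0)) {
        vals <- c(vals, (ts / rs) / (tc / rc))
      }
    }
  }
  list(
    mean = if (length(vals) > 0) mean(vals) else NA_real_,
    sd = if (length(vals) > 1) stats::sd(vals) else if (length(vals) == 1) 0 else NA_real_,
    n = length(vals)
  )
}

# literal transcription of the segmental scoring text: deletion/gain if the
# DQs of at least 2 consecutive loci are delta below/above 1; for the MLPA
# set additionally if more than 75% of the probes show a decrease/increase
# of at least 0.15
oracle_segmental <- function(dq, set = c("MAQ", "MLPA")) {
  set <- match.arg(set)
  delta <- if (set == "MAQ") 0.2 else 0.25
  if (sum(!is.na(dq)) < 2) return("no_data")
  n <- length(dq)
  for (i in seq_len(n - 1)) {
    a <- dq[i]; b <- dq[i + 1]
    if (!is.na(a) && !is.na(b)) {
      if (a <= 1 - delta && b <= 1 - delta) return("loss")
      if (a >= 1 + delta && b >= 1 + delta) return("gain")
    }
  }
  if (set == "MLPA") {
    num <- dq[!is.na(dq)]
    if (sum(num <= 1 - 0.15) / length(num) > 0.75) return("loss")
    if (sum(num >= 1 + 0.15) / length(num) > 0.75) return("gain")
  }
  "normal"
}

# literal transcription of the whole-chromosome text: at least 75% of the
# DQs of both arms below/above 1, and more than half of the DQs deviating
# by at least 0.1
oracle_whole_chromosome <- function(dq_p, dq_q) {
  p <- dq_p[!is.na(dq_p)]
  q <- dq_q[!is.na(dq_q)]
  if (length(p) == 0 || length(q) == 0) return("no_data")
  both <- c(p, q)
  if (sum(p < 1) / length(p) >= 0.75 && sum(q < 1) / length(q) >= 0.75 &&
      sum(both <= 0.9) / length(both) > 0.5) {
    return("loss")
  }
  if (sum(p > 1) / length(p) >= 0.75 && sum(q > 1) / length(q) >= 0.75 &&
      sum(both >= 1.1) / length(both) > 0.5) {
    return("gain")
  }
  "normal"
}

# literal transcription: the 3 (MAQ) / 2 (MLPA) MYCN DQs increase by >= 3
oracle_mycn <- function(dq, set = c("MAQ", "MLPA")) {
  set <- match.arg(set)
  need <- if (set == "MAQ") 3 else 2
  num <- dq[!is.na(dq)]
  if (length(num) < need) return("no_data")
  if (all(num >= 4)) "amplified" else "normal"
}

# probability that a random positive outscores a random negative, ties half
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  100 * tot / (length(pos) * length(neg))
}
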