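#' Scoring rule sets
#'
#' The two published threshold sets for rule-based calling on a linear DQ
#' scale. Both share the same structure; they differ in the segmental
#' deviation threshold, in the MLPA-only fraction clause, and in how many
#' MYCN loci must exceed the amplification threshold.
#'
#' * **Segmental** (arm region): loss/gain when at least
#'   `segmental_min_consecutive` (2) consecutive loci deviate from 1 by at
#'   least `segmental_delta` (MAQ 0.2, MLPA 0.25) in the same direction;
#'   MLPA additionally calls when *more than* `fraction_rule_fraction` (75%)
#'   of the region's loci deviate by at least `fraction_rule_delta` (0.15)
#'   in the same direction.
#' * **Whole chromosome** (evaluated only when the sample shows no segmental
#'   aberration): loss/gain when at least `numerical_arm_fraction` (75%) of
#'   the DQs of *both* arms lie below/above 1 *and* more than
#'   `numerical_majority_fraction` (half) of the chromosome's DQs deviate by
#'   at least `numerical_majority_delta` (0.1).
#' * **MYCN**: amplified when all of the designated MYCN-locus DQs
#'   (`mycn_required_loci`: MAQ 3, MLPA 2 must be measurable) show an
#'   increase of at least `mycn_delta` (3) over the normal baseline of 1,
#'   i.e. DQ >= 4. Set `mycn_absolute = TRUE` for the alternative reading
#'   DQ >= 3.
#'
#' All "at least" thresholds are inclusive; the 75% and one-half clauses
#' marked "more than" are strict.
#'
#' @param name Rule-set label.
#' @param segmental_delta,segmental_min_consecutive,fraction_rule_enabled,fraction_rule_fraction,fraction_rule_delta,numerical_arm_fraction,numerical_majority_delta,numerical_majority_fraction,mycn_delta,mycn_required_loci,mycn_absolute
#'   Threshold overrides, see above.
#' @return A `maq_ruleset` list.
#' @export
#' @examples
#' maq_rules()
#' mlpa_rules()
maq_rules <- function(name = "MAQ",
                      segmental_delta = 0.2,
                      segmental_min_consecutive = 2L,
                      fraction_rule_enabled = FALSE,
                      fraction_rule_fraction = 0.75,
                      fraction_rule_delta = 0.15,
                      numerical_arm_fraction = 0.75,
                      numerical_majority_delta = 0.1,
                      numerical_majority_fraction = 0.5,
                      mycn_delta = 3,
                      mycn_required_loci = 3L,
                      mycn_absolute = FALSE) {
  rules <- list(
    name = name,
    segmental_delta = segmental_delta,
    segmental_min_consecutive = as.integer(segmental_min_consecutive),
    fraction_rule_enabled = isTRUE(fraction_rule_enabled),
    fraction_rule_fraction = fraction_rule_fraction,
    fraction_rule_delta = fraction_rule_delta,
    numerical_arm_fraction = numerical_arm_fraction,
    numerical_majority_delta = numerical_majority_delta,
    numerical_majority_fraction = numerical_majority_fraction,
    mycn_delta = mycn_delta,
    mycn_required_loci = as.integer(mycn_required_loci),
    mycn_absolute = isTRUE(mycn_absolute)
  )
  validate_rules(rules)
  structure(rules, class = "maq_ruleset")
}

#' @rdname maq_rules
#' @export
mlpa_rules <- function(name = "MLPA",
                       segmental_delta = 0.25,
                       fraction_rule_enabled = TRUE,
                       mycn_required_loci = 2L,
                       ...) {
  maq_rules(name = name, segmental_delta = segmental_delta,
            fraction_rule_enabled = fraction_rule_enabled,
            mycn_required_loci = mycn_required_loci, ...)
}

validate_rules <- function(r) {
  stopifnot(
    r$segmental_delta > 0, r$fraction_rule_delta > 0,
    r$numerical_majority_delta > 0, r$mycn_delta > 0,
    r$segmental_min_consecutive >= 2,
    r$fraction_rule_fraction > 0, r$fraction_rule_fraction <= 1,
    r$numerical_arm_fraction > 0, r$numerical_arm_fraction <= 1,
    r$numerical_majority_fraction > 0, r$numerical_majority_fraction <= 1,
    r$mycn_required_loci >= 1
  )
  invisible(r)
}

#' @export
print.maq_ruleset <- function(x, ...) {
  cat("<maq_ruleset '", x$name, "'>\n", sep = "")
  cat("  segmental: >=", x$segmental_min_consecutive,
      "consecutive loci deviating >=", x$segmental_delta, "\n")
  if (x$fraction_rule_enabled) {
    cat("  fraction clause: >", 100 * x$fraction_rule_fraction,
        "% of loci deviating >=", x$fraction_rule_delta, "\n")
  }
  cat("  whole chromosome: >=", 100 * x$numerical_arm_fraction,
      "% of both arms off 1 and >", 100 * x$numerical_majority_fraction,
      "% deviating >=", x$numerical_majority_delta, "\n")
  cat("  MYCN: all of", x$mycn_required_loci, "loci with DQ >=",
      if (x$mycn_absolute) x$mycn_delta else 1 + x$mycn_delta, "\n")
  invisible(x)
}

#' Read or write a rule set as YAML
#'
#' Rule sets serialize to a flat YAML mapping of the fields documented in
#' [maq_rules()]. The two published presets ship with the package under
#' `system.file("extdata", package = "maqcna")`.
#'
#' @param path File path.
#' @return `read_rules()` a `maq_ruleset`; `write_rules()` the path,
#'   invisibly.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("rule file not found: ", path), class = "maq_io_error")
  }
  cfg <- yaml::read_yaml(path)
  do.call(maq_rules, cfg)
}

#' @rdname read_rules
#' @param rules A `maq_ruleset`.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' Fetch a rule set by name, file path, or pass one through
#'
#' @param ruleset `"MAQ"`, `"MLPA"`, a YAML path, or a `maq_ruleset`.
#' @return A `maq_ruleset`.
#' @export
as_ruleset <- function(ruleset) {
  if (inherits(ruleset, "maq_ruleset")) return(ruleset)
  if (is.character(ruleset) && length(ruleset) == 1) {
    if (toupper(ruleset) == "MAQ") return(maq_rules())
    if (toupper(ruleset) == "MLPA") return(mlpa_rules())
    if (file.exists(ruleset)) return(read_rules(ruleset))
  }
  abort("ruleset must be 'MAQ', 'MLPA', a YAML file path, or a maq_ruleset",
        class = "maq_config_error")
}
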