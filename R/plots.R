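#' Plot a sample's dosage-quotient profile
#'
#' One panel per chromosome, loci in genomic order, points at the mean DQ
#' with error bars of one standard deviation across the (reference, control)
#' combinations, and dashed guides at 1 and at the segmental thresholds of
#' the given rule set — the standard profile view used to eyeball calls.
#'
#' @param dq DQ tibble from [dq_profile()] (one or more kits bound).
#' @param sample Sample id to plot (default: first in the table).
#' @param rules Optional rule set; adds threshold guides when supplied.
#' @return A ggplot object.
#' @export
plot_dq_profile <- function(dq, sample = dq$sample_id[1], rules = NULL) {
  d <- dq %>%
    filter(.data$sample_id == sample, !is.na(.data$dq_mean)) %>%
    arrange(.data$chromosome, .data$arm, .data$position) %>%
    group_by(.data$chromosome) %>%
    mutate(locus = row_number()) %>%
    ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$dq_mean)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$dq_mean - .data$dq_sd,
                   ymax = .data$dq_mean + .data$dq_sd),
      width = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$arm), size = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "locus (genomic order)", y = "dosage quotient",
                  title = paste0("DQ profile: ", sample)) +
    ggplot2::theme_bw()
  if (!is.null(rules)) {
    rules <- as_ruleset(rules)
    p <- p + ggplot2::geom_hline(
      yintercept = c(1 - rules$segmental_delta, 1 + rules$segmental_delta),
      linetype = "dotted", colour = "firebrick"
    )
  }
  p
}

#' Plot per-region diagnostic performance
#'
#' Dot plot of sensitivity, specificity and AUC per region from a
#' performance object.
#'
#' @param object A `maq_performance` from [evaluate_performance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maq_performance <- function(object, ...) {
  d <- object$per_region %>%
    select(all_of(c("region", "sensitivity", "specificity", "auc"))) %>%
    tidyr::pivot_longer(-"region", names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_point(size = 3,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
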