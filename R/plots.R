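# ggplot2 methods for the result objects.

#' @describeIn flux_variability plot FVA ranges as horizontal segments
#'   per reaction (point = range of width zero, i.e. the invariant core).
#' @param object an `"fva_result"`.
#' @param ... unused.
#' @method autoplot fva_result
#' @export
autoplot.fva_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(reaction_id = factor(.data$reaction_id,
                                levels = rev(unique(.data$reaction_id))),
           invariant = abs(.data$max_flux - .data$min_flux) <= 1e-6)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$reaction_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min_flux,
                                       xend = .data$max_flux,
                                       yend = .data$reaction_id,
                                       colour = .data$invariant),
                          linewidth = 1.2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$min_flux,
                                     colour = .data$invariant), size = 1) +
    ggplot2::labs(x = "flux range at the optimum", y = NULL,
                  colour = "invariant") +
    ggplot2::theme_minimal()
}

#' @describeIn robustness_scan plot the objective as a function of the
#'   clamped flux.
#' @param object a `"robustness_curve"`.
#' @param ... unused.
#' @method autoplot robustness_curve
#' @export
autoplot.robustness_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fixed_flux,
                               y = .data$objective_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("fixed flux through ",
                             attr(object, "reaction")),
                  y = "objective value") +
    ggplot2::theme_minimal()
}

#' @describeIn score_model_vs_omics stacked per-pathway bars of the
#'   three-way breakdown (in-silico only / both / experimental only),
#'   faceted by gene vs enzyme sets.
#' @param object a `"concordance_report"`.
#' @method autoplot concordance_report
#' @export
autoplot.concordance_report <- function(object, ...) {
  long <- tidy(object) %>%
    tidyr::pivot_longer(c("in_silico_only", "both", "experimental_only"),
                        names_to = "category", values_to = "n") %>%
    mutate(category = factor(.data$category,
                             levels = c("in_silico_only", "both",
                                        "experimental_only")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pathway_id, y = .data$n,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~set_type, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "members", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn zscore_select rank plot of per-gene z-scores with the
#'   selection threshold.
#' @param object a `"selection_result"`.
#' @param ... unused.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- as_tibble(object) %>% arrange(.data$z) %>%
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$z,
                                   colour = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "gene rank", y = "z-score", colour = "selected") +
    ggplot2::theme_minimal()
}

#' @describeIn end_to_end_recovery detection-calibration plot: mean gene
#'   consistency coefficient against the simulated detection
#'   probability, with the identity line.
#' @param object a `"recovery_report"`.
#' @param ... unused.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$eta_curve,
                  ggplot2::aes(x = .data$detection_prob,
                               y = .data$mean_eta_genes)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_eta_genes - 1.96 * .data$se,
      ymax = .data$mean_eta_genes + 1.96 * .data$se)) +
    ggplot2::labs(x = "proteome detection probability",
                  y = "mean gene consistency coefficient") +
    ggplot2::theme_minimal()
}
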