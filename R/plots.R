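# ggplot2 helpers for the main result types.

#' Plot a 96-channel mutation catalogue
#'
#' Bars ordered by the canonical channel order, faceted by substitution
#' class.
#'
#' @param object A `catalogue96` tibble from [build_catalogue()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.catalogue96 <- function(object, ...) {
  df <- tibble::tibble(
    channel = factor(object$channel, levels = sbs96_channels()),
    count = object$count,
    class = substr(object$channel, 3, 5)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ class, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "mutations",
                  title = paste("Catalogue:", attr(object, "owner"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none")
}

#' Plot fitted signature exposures
#'
#' @param object An `exposure_fit` from [fit_exposures()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.exposure_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature, y = .data$exposure)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fitted exposure (mutations)") +
    ggplot2::theme_minimal()
}

#' Per-offspring endpoint rates with bootstrap intervals
#'
#' Point-range plot of the per-cohort mean per-offspring counts for each
#' endpoint of a study run.
#'
#' @param study A `study_tables` object from [run_study()].
#' @return A ggplot object.
#' @export
plot_endpoint_rates <- function(study) {
  ggplot2::ggplot(study$rates,
                  ggplot2::aes(x = .data$cohort, y = .data$mean,
                               ymin = .data$conf_low, ymax = .data$conf_high,
                               colour = .data$cohort)) +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean per offspring (95% bootstrap CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Chromosomal distribution of accepted mutations
#'
#' @param study A `study_tables` object from [run_study()].
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(study) {
  ggplot2::ggplot(study$chromosome_counts,
                  ggplot2::aes(x = .data$chrom, y = .data$n,
                               fill = .data$vclass)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~cohort, ncol = 1) +
    ggplot2::labs(x = NULL, y = "mutations") +
    ggplot2::theme_minimal()
}
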