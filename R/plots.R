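#' Plot a threshold sensitivity sweep
#'
#' Odds ratio (with its exact CI ribbon) against the number of
#' evidence-bearing pairs at each threshold, annotated with the threshold
#' values, mirroring the usual presentation of similarity-threshold
#' sensitivity analyses.
#'
#' @param object An `se_sweep` from [sweep_assoc_threshold()] or
#'   [sweep_indic_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.se_sweep <- function(object, ...) {
  lab <- if (identical(attr(object, "sweep"), "indic")) {
    "SE-indication similarity threshold"
  } else {
    "SE-trait similarity threshold"
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_evidence_pairs,
                               y = .data$or)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$theta),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "drug-SE pairs with genetic evidence",
                  y = "odds ratio",
                  title = paste("Sensitivity of enrichment to the", lab))
}

#' Forest plot of binned enrichment results
#'
#' @param object A `bin_results` tibble (from [specificity_bins()],
#'   [severity_bins()], [area_bins()] or [modifier_bins()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bin_results <- function(object, ...) {
  dat <- object[!is.na(object$or), , drop = FALSE]
  dat$bin <- factor(dat$bin, levels = rev(object$bin))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$bin)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL)
}

#' Base rate versus positive predictive value across bins
#'
#' @param bins A `bin_results` tibble with `base_rate` and `ppv` columns.
#' @return A ggplot object.
#' @export
plot_ppv_base_rate <- function(bins) {
  dat <- tidyr::pivot_longer(
    bins[, c("bin", "base_rate", "ppv")],
    cols = c("base_rate", "ppv"),
    names_to = "metric", values_to = "value"
  )
  dat$bin <- factor(dat$bin, levels = bins$bin)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$value,
                                    fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x,
                                                            "%")) +
    ggplot2::labs(x = NULL, y = "proportion of pairs observed")
}
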