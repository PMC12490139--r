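# ggplot2 presentations of the study results.

#' @method autoplot cfr_bias_grid
#' @export
autoplot.cfr_bias_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rel_bias_tr, y = .data$rel_bias_obs,
                               label = .data$case)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(vjust = -0.9, size = 3) +
    ggplot2::labs(
      x = "relative bias of transportability estimate",
      y = "relative bias of observational estimate",
      title = "Estimator bias under selective assumption violations"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot cfr_variance_study
#' @export
autoplot.cfr_variance_study <- function(object, ...) {
  object <- dplyr::mutate(object,
                          cell = paste0("n0=", .data$n0, ", n1=", .data$n1))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$analysis, y = .data$variance,
                               fill = .data$analysis)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~cell, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "empirical variance of the risk estimator",
                  title = "Efficiency of the three analyses") +
    ggplot2::theme_minimal()
}

#' @method autoplot cfr_cass_demo
#' @export
autoplot.cfr_cass_demo <- function(object, ...) {
  object <- dplyr::mutate(
    object,
    label = paste(.data$analysis, .data$estimator, sep = " / "),
    arm = factor(paste0("A = ", .data$a), levels = c("A = 1", "A = 0"))
  )
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate, y = .data$label,
                               colour = .data$analysis)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::facet_wrap(~arm, ncol = 1) +
    ggplot2::labs(x = "Brier risk in the target population", y = NULL,
                  colour = "analysis",
                  title = "Counterfactual Brier risk, all analyses and estimators") +
    ggplot2::theme_minimal()
}
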