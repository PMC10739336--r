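## ggplot2 views of the result tables.

#' Bar chart of species counts per MDC bin
#'
#' @param bins A tibble from [bin_species()].
#' @return A ggplot object.
#' @export
plot_mdc_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$n_species)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_species),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "MDCs per species", y = "Number of species") +
    ggplot2::theme_minimal()
}

#' Genus identity against mean MDC count
#'
#' @param summary A master summary tibble from [run_pipeline()] or rows
#'   from [summarize_genus()].
#' @return A ggplot object.
#' @export
plot_identity_vs_mdc <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$mean_identity_pct,
                               y = .data$mdc_mean)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$habitat)) +
    ggplot2::labs(x = "Mean pairwise identity (%)",
                  y = "Mean MDCs per species") +
    ggplot2::theme_minimal()
}

#' Observed counts against Poisson GLM fit
#'
#' @param object An `mdc_glm` from [poisson_glm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdc_glm <- function(object, ...) {
  d <- tibble(
    x = object$fit$model$lx,
    y = object$fit$model$y,
    fitted = object$fit$fitted.values
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = paste0("log", object$log_base, "(", object$predictor, ")"),
      y = object$response) +
    ggplot2::theme_minimal()
}
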