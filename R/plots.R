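#' Plot a population simulation
#'
#' Two-panel view of a run: the live fraction `N(t)` and the selection
#' ratio `<MGMT>/<REF>` over time.
#'
#' @param object a `phenosel_sim`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phenosel_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$series, "t", "N", "ratio"),
    cols = c("N", "ratio"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = c("N", "ratio"),
                        labels = c("live fraction N(t)",
                                   "ratio <MGMT>/<REF>"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = sprintf("%s dose %g uM, K = %d",
                                  object$schedule$kind,
                                  object$schedule$dose, object$K)) +
    ggplot2::theme_minimal()
}

#' Plot ABC posterior marginals
#'
#' Histograms of the accepted draws, one facet per parameter, on the
#' sampling scale (log where the prior is log-uniform).
#'
#' @param object a `phenosel_abc`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phenosel_abc <- function(object, ...) {
  x <- tibble::as_tibble(posterior_scaled(object))
  long <- tidyr::pivot_longer(x, cols = dplyr::everything(),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "accepted draws") +
    ggplot2::theme_minimal()
}

#' Plot a growth-curve fit
#'
#' Replicate counts with the best-fit exponential curve.
#'
#' @param object a `phenosel_growth_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phenosel_growth_fit <- function(object, ...) {
  reps <- grep("^rep", names(object$data), value = TRUE)
  long <- tidyr::pivot_longer(object$data, cols = dplyr::all_of(reps),
                              names_to = "replicate",
                              values_to = "count")
  grid <- tibble::tibble(
    time_h = seq(min(object$data$time_h), max(object$data$time_h),
                 length.out = 200)
  )
  grid$count <- object$N0 * exp(object$mu * grid$time_h)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$count)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$replicate)) +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "time (h)", y = "live cells",
                  title = sprintf("doubling time %.1f h",
                                  object$doubling_time)) +
    ggplot2::theme_minimal()
}

#' Plot a noise sweep
#'
#' Selection ratio and viability recovery against mRNA noise (log x
#' axis), the signature of noise-driven phenotypic selection.
#'
#' @param sweep a tibble from [noise_sweep()].
#' @return A ggplot object.
#' @export
plot_noise_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    dplyr::select(sweep, "mrna_noise", "ratio", "recovery"),
    cols = c("ratio", "recovery"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mrna_noise,
                                     y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "mRNA noise (CV^2)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
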