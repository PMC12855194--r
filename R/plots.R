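#' Plot particle-size distributions
#'
#' Kernel-density curves of the diameter distributions, one panel per
#' sample, with the small/large class boundary marked.
#'
#' @param data A particle tibble (`sample_id`, `time_h`, `diameter_um`).
#' @param threshold Class boundary to mark, um; `NULL` to omit.
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(data, threshold = 13) {
  .require_columns(data, "diameter_um", "particle table")
  keys <- intersect(c("sample_id", "time_h"), names(data))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$diameter_um)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::labs(x = "Diameter (µm)", y = "Density")
  if (length(keys) > 0) {
    p <- p + ggplot2::facet_wrap(keys, scales = "free_y",
                                 labeller = ggplot2::label_both)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  }
  p
}

#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, bins = 60, ...) {
  x <- object$data
  grid <- seq(min(x), max(x), length.out = 512)
  comp <- tibble(
    diameter_um = rep(grid, 2),
    density = c(object$weight_small * dnorm(grid, object$mean_small,
                                            object$sd_small),
                object$weight_large * dnorm(grid, object$mean_large,
                                            object$sd_large)),
    component = rep(c("small", "large"), each = length(grid))
  )
  ggplot2::ggplot(tibble(diameter_um = x),
                  ggplot2::aes(x = .data$diameter_um)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "Diameter (µm)", y = "Density",
                  colour = "Component")
}

#' @method autoplot switching_trajectory
#' @export
autoplot.switching_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object), c("M", "U", "fraction_small"),
    names_to = "series", values_to = "value"
  )
  long$series <- factor(long$series, levels = c("M", "U", "fraction_small"),
                        labels = c("Large clusters M", "Small clusters U",
                                   "Fraction small"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = NULL)
}

#' @method autoplot switching_fit
#' @export
autoplot.switching_fit <- function(object, ...) {
  p <- object$best_params
  traj <- simulate_switching(p, t_end = object$t_end, dt = object$dt)
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_line(data = as_tibble(traj),
                       ggplot2::aes(y = 100 * .data$fraction_small)) +
    ggplot2::geom_point(ggplot2::aes(y = 100 * .data$observed),
                        size = 2) +
    ggplot2::labs(x = "Time (h)", y = "Small clusters (%)",
                  title = sprintf(
                    "Best fit: alpha = %g, beta = %g, gamma = %g, k = %g",
                    p$alpha, p$beta, p$gamma, p$k))
}

#' @method autoplot overlap_matrix
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(
    cbind(tibble(sample_a = object$labels), as_tibble(object$eta)),
    -"sample_a", names_to = "sample_b", values_to = "eta"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                     fill = .data$eta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "η") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
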