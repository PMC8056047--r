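#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("prefactor", "exponent"),
                 estimate = c(x$a0, x$a1))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n, method = x$method)
}

#' @export
tidy.power_law_gof <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, xmin = x$xmin,
                 ks_statistic = x$ks_statistic, bootstrap_p = x$bootstrap_p,
                 n = x$n, n_resamples = x$n_resamples)
}

#' Plot a fitted power law over its data
#'
#' Log-log scatter of the fitted points with the `y = a0 * x^a1` line.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = exp(seq(log(min(object$data$x)), log(max(object$data$x)),
                length.out = 100))
  )
  grid$y <- object$a0 * grid$x^object$a1
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree k", y = "topological property",
      title = sprintf("y = %.3g k^%.3g", object$a0, object$a1)
    )
}

#' Plot the degree profile of a network
#'
#' Faceted log-log plot of each degree-aggregated topological property
#' against degree, the view in which power-law behaviour appears as a
#' straight line.
#'
#' @param profile A tibble from [aggregate_by_degree()].
#' @return A ggplot object.
#' @export
plot_degree_profile <- function(profile) {
  long <- profile |>
    dplyr::select(-"n_k") |>
    tidyr::pivot_longer(-"degree", names_to = "property",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value), .data$value > 0, .data$degree > 0)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$degree, y = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = NULL)
}

#' Plot a rich-club curve
#'
#' Raw and normalized rich-club coefficients against the degree cut, with
#' the conventional 1.1 extraction threshold marked.
#'
#' @param object A `rich_club_curve`.
#' @param threshold Threshold line to draw (default 1.1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rich_club_curve <- function(object, threshold = 1.1, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("k", raw = "phi", normalized = "phi_norm") |>
    tidyr::pivot_longer(-"k", names_to = "curve", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "degree cut k", y = expression(phi(k)),
                  colour = NULL)
}

#' Plot per-level summaries of a community tree
#'
#' Modularity, Hamiltonian energy and average LCP correlation against the
#' hierarchy level.
#'
#' @param object A `community_tree`.
#' @param gamma CPM resolution parameter (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.community_tree <- function(object, gamma = 0.5, ...) {
  long <- level_summary(object, gamma = gamma) |>
    dplyr::select("level", modularity = "mean_q",
                  `Hamiltonian energy` = "total_he",
                  `LCP correlation` = "mean_lcp_corr") |>
    tidyr::pivot_longer(-"level", names_to = "quantity",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "hierarchy level", y = NULL)
}
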