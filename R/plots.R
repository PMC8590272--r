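#' Curves of the heterogeneity measures against the variance
#'
#' Plots ICC, MOR and SOI (and optionally the IOR limits) as functions of
#' the between-cluster variance at a fixed cluster-covariate coefficient,
#' the standard way to visualise how the measures trade off.
#'
#' @param sigma2_max Right end of the variance axis.
#' @param alpha Cluster-covariate coefficient used for SOI and IOR.
#' @param include_ior Also draw the IOR limits.
#' @param n Number of grid points.
#' @return A ggplot object (facets per measure, free y scales).
#' @export
plot_measure_curves <- function(sigma2_max = 2, alpha = -0.3,
                                include_ior = TRUE, n = 200) {
  s2 <- seq(0, sigma2_max, length.out = n)
  rep_ <- heterogeneity_report(alpha, s2)
  long <- tidyr::pivot_longer(
    dplyr::select(rep_, dplyr::all_of(c(
      "sigma2_u", "icc", "mor", "soi",
      if (include_ior) c("ior_lower", "ior_upper")))),
    -"sigma2_u", names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$sigma2_u, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(
      x = expression(sigma[u]^2 ~ "(between-cluster variance)"),
      y = NULL,
      title = "Between-cluster heterogeneity measures",
      subtitle = sprintf("cluster-covariate coefficient alpha = %.2f", alpha)
    )
}

#' Plot a simulation study summary
#'
#' Displays the RMSE (or mean estimate) of each quantity against the number
#' of clusters, one line per cluster size, faceted by quantity and
#' random-effect variance. The expected pattern is RMSE shrinking as
#' clusters and cluster sizes grow.
#'
#' @param object A `"hetlogit_study"` tibble from [run_grid()].
#' @param value Which summary column to draw: `"rmse"` or `"mean"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hetlogit_study
#' @export
autoplot.hetlogit_study <- function(object, value = c("rmse", "mean"), ...) {
  value <- match.arg(value)
  ggplot2::ggplot(object, ggplot2::aes(
    .data$n_clusters, .data[[value]],
    colour = factor(.data$cluster_size), group = factor(.data$cluster_size)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$quantity), ggplot2::vars(.data$sigma2_u),
      scales = "free_y"
    ) +
    ggplot2::labs(x = "number of clusters", y = value,
                  colour = "cluster size")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
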