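#' Trace and density plots for a Gibbs chain
#'
#' @param object An `mb_chain`.
#' @param type `"trace"` or `"density"`.
#' @param components Components to display (default all eleven).
#' @param ... Ignored.
#' @return A ggplot object, faceted by component.
#' @method autoplot mb_chain
#' @export
autoplot.mb_chain <- function(object, type = c("trace", "density"),
                              components = mb_components(), ...) {
  type <- match.arg(type)
  long <- dplyr::filter(tidy(object), .data$component %in% components)
  long$component <- factor(long$component, levels = mb_components())
  if (type == "trace") {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration,
                                            y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.25, colour = "steelblue4") +
      ggplot2::labs(x = "iteration", y = "sampled value")
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "steelblue4", alpha = 0.3) +
      ggplot2::labs(x = "sampled value", y = "posterior density")
  }
  p + ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::theme_minimal()
}

#' Variance-partition bar chart
#'
#' Percent contribution of each source of variability to the direct and
#' maternal additive variance of a reference group.
#'
#' @param vc An `mb_varcomp` or named component vector.
#' @param group An [reference_group()]; default F2.
#' @return A ggplot object.
#' @export
plot_variance_partition <- function(vc, group = f2_group()) {
  vp <- dplyr::filter(variance_partition(vc, group),
                      .data$trait != "covariance")
  ggplot2::ggplot(vp, ggplot2::aes(x = .data$trait, y = .data$percent,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Dark2",
                               labels = c(A = "breed A", B = "breed B",
                                          S = "segregation")) +
    ggplot2::labs(x = NULL, y = "% of additive variance",
                  fill = "source") +
    ggplot2::theme_minimal()
}
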