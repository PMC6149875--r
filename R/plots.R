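#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation report
#'
#' Per-repeat metric values as points with the cross-repeat mean as a bar,
#' one facet-free panel over the four metrics (Se, Sp, BA, AUC).
#'
#' @param object A `som_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.som_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_repeat,
                              cols = c("se", "sp", "ba", "auc"),
                              names_to = "metric")
  long$metric <- factor(toupper(long$metric), c("SE", "SP", "BA", "AUC"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "bar", alpha = 0.35,
                          width = 0.6) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("%s (%s%s)", object$protocol$classifier,
                      object$protocol$name,
                      if (isTRUE(object$protocol$balance))
                        ", SMOTE-balanced" else ""),
      x = NULL, y = "metric value") +
    ggplot2::theme_minimal()
}

#' Descriptor-space map of a dataset
#'
#' Scatter of atoms in (P, Q) space coloured by SOM label; SMOTE-synthetic
#' rows, if present, are drawn with open symbols.
#'
#' @param dataset A dataset tibble with `P`, `Q`, `label` and optionally
#'   `synthetic`.
#' @return A ggplot object.
#' @export
plot_qna <- function(dataset) {
  stopifnot(all(c("P", "Q", "label") %in% names(dataset)))
  d <- dplyr::mutate(dataset,
    class = factor(ifelse(.data$label == 1L, "SOM", "non-SOM"),
                   c("non-SOM", "SOM")),
    origin = if ("synthetic" %in% names(dataset)) {
      ifelse(.data$synthetic, "synthetic", "observed")
    } else "observed")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$P, y = .data$Q,
                                  colour = .data$class,
                                  shape = .data$origin)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_shape_manual(values = c(observed = 16, synthetic = 1)) +
    ggplot2::labs(x = "P", y = "Q") +
    ggplot2::theme_minimal()
}
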