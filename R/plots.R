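#' Plot an assembly-process profile as stacked bars
#'
#' @param object An `assembly_profile` from [summarize_assembly()].
#' @param x Name of the grouping column mapped to the x axis (default the
#'   first grouping column, or a single overall bar).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assembly_profile <- function(object, x = NULL, ...) {
  group_cols <- setdiff(names(object),
                        c("process", "n_pairs", "percent", "n_classified", "n_undefined"))
  df <- tibble::as_tibble(object)
  if (is.null(x)) x <- if (length(group_cols) > 0) group_cols[1] else NULL
  if (is.null(x)) {
    df$.group <- "all"
    x <- ".group"
  }
  facet <- setdiff(group_cols, x)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$percent,
                                        fill = .data$process)) +
    ggplot2::geom_col(position = "stack", colour = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(y = "% of pairwise comparisons", fill = "process") +
    ggplot2::theme_minimal()
  if (length(facet) > 0) {
    p <- p + ggplot2::facet_wrap(facet)
  }
  p
}

#' Plot a Mantel correlogram
#'
#' Mantel r against phylogenetic distance-class centre; filled points mark
#' classes significant after progressive Holm correction, open points
#' non-significant, grey points untested (beyond the cutoff).
#'
#' @param object A `mantel_correlogram`.
#' @param alpha Significance level for the Holm-corrected p-values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mantel_correlogram <- function(object, alpha = 0.05, ...) {
  df <- object$classes
  df <- df[df$n_pairs > 0 & !is.na(df$mantel_r), , drop = FALSE]
  df$status <- dplyr::case_when(
    !df$tested ~ "untested",
    df$p_holm < alpha ~ "significant",
    TRUE ~ "not significant"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$mantel_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status, fill = .data$status),
                        size = 2.5) +
    ggplot2::scale_shape_manual(values = c(significant = 21,
                                           `not significant` = 21,
                                           untested = 4)) +
    ggplot2::scale_fill_manual(values = c(significant = "black",
                                          `not significant` = "white",
                                          untested = "grey60")) +
    ggplot2::labs(x = "phylogenetic distance (class centre)",
                  y = "Mantel r", shape = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.assembly_profile
#' @export
autoplot.assembly_analysis <- function(object, ...) {
  autoplot(object$profile, ...)
}

#' Plot a betaNTI-environment correlation
#'
#' @param object An `env_correlation`.
#' @param ... Unused.
#' @return A ggplot object (scatter with the fitted regression line).
#' @export
autoplot.env_correlation <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[object$variable]],
                                   y = .data$median_bnti)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = object$variable, y = "median betaNTI",
                  subtitle = sprintf("slope = %.2f, r = %.2f, p = %.3g",
                                     object$slope, object$r, object$p_value)) +
    ggplot2::theme_minimal()
}
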