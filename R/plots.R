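#' Plot a pairwise LD table
#'
#' Heatmap of r-squared (or D') over all variant pairs, the usual way to
#' eyeball LD blocks in a region.
#'
#' @param object A `mirtld_ld_table` from [ld_pairwise()].
#' @param statistic `"r2"` or `"d_prime"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirtld_ld_table <- function(object, statistic = c("r2", "d_prime"),
                                     ...) {
  statistic <- match.arg(statistic)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$id1, y = .data$id2,
                               fill = .data[[statistic]])) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[statistic]])), size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff7ec", high = "#d7301f",
                                 limits = c(0, 1), name = statistic) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Pairwise", statistic)) +
    ggplot2::theme_minimal()
}

#' Forest plot of association results
#'
#' Odds ratios with confidence intervals per genetic model, faceted by
#' variant and contrast; crude and adjusted estimates side by side.
#'
#' @param object A `mirtld_assoc` from [run_association_suite()].
#' @param contrasts Optional subset of contrast names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirtld_assoc <- function(object, contrasts = NULL, ...) {
  res <- object$results
  res <- filter(res, !is.na(.data$or_point))
  if (!is.null(contrasts)) res <- filter(res, .data$contrast %in% contrasts)
  res <- mutate(res, kind = ifelse(.data$adjusted, "adjusted", "crude"))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$or_point, y = .data$model,
                                    color = .data$kind)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$contrast),
                        cols = ggplot2::vars(.data$id)) +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of cumulative genotype frequencies
#'
#' @param object A `mirtld_cumulative` from [cumulative_genotypes()].
#' @param type `"genotype"` or `"haplotype"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirtld_cumulative <- function(object,
                                       type = c("genotype", "haplotype"),
                                       ...) {
  type <- match.arg(type)
  dat <- filter(object$frequencies, .data$type == !!type)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$frequency,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = paste0(object$id1, "/", object$id2), y = "frequency",
                  title = paste("Cumulative", type, "frequencies")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
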