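#' Histogram of per-core mosaicism scores
#'
#' @param scores Tibble with `percent_positive` (e.g. [quantify_cores()]).
#' @param binwidth Histogram bin width in percentage points.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, binwidth = 2) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$percent_positive)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "sienna",
                            colour = "white", na.rm = TRUE) +
    ggplot2::labs(x = "% MYL4+ myocyte area", y = "cores") +
    ggplot2::theme_minimal()
}

#' Residualised mosaicism by disease group
#'
#' Boxplots of the adjusted outcome (residuals of the age/sex/random-intercept
#' model) by disease category, the standard display for adjusted group
#' comparisons.
#'
#' @param residual_cohort Tibble from [compute_residuals()].
#' @return A ggplot object.
#' @export
plot_residuals_by_disease <- function(residual_cohort) {
  ggplot2::ggplot(residual_cohort,
                  ggplot2::aes(x = .data$disease, y = .data$residual)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey90") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "sqrt(%MYL4+) residual") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' @describeIn manual_vs_area_correlation Scatter plot of the matched pairs
#'   with the identity line.
#' @param object A `mosaic_concordance`.
#' @param ... Unused.
#' @method autoplot mosaic_concordance
#' @export
autoplot.mosaic_concordance <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$percent_positive_cells,
                               y = .data$percent_positive)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "% positive cells (manual count)",
                  y = "% positive area (automated)",
                  title = sprintf("Pearson r = %.3f (n = %d cores)",
                                  object$r, object$n_pairs)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_mixed_model Forest plot of fixed-effect estimates with
#'   95% normal-approximation intervals.
#' @param object A `mosaic_fit`.
#' @param ... Unused.
#' @method autoplot mosaic_fit
#' @export
autoplot.mosaic_fit <- function(object, ...) {
  co <- object$coefficients
  co <- co[co$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - qnorm(0.975) * .data$std.error,
      xmax = .data$estimate + qnorm(0.975) * .data$std.error)) +
    ggplot2::labs(x = "estimate (sqrt-fraction scale)", y = NULL,
                  title = object$spec$label) +
    ggplot2::theme_minimal()
}

#' Overlay a binary mask on a core image
#'
#' Renders the RGB core with mask pixels outlined in a translucent colour, for
#' visual QC of threshold selection.
#'
#' @param img RGB array `height x width x 3`.
#' @param mask Logical matrix of the same height/width.
#' @param colour Overlay colour.
#' @param alpha Overlay opacity.
#' @return A ggplot object (raster).
#' @export
plot_mask_overlay <- function(img, mask, colour = "red", alpha = 0.35) {
  stopifnot(identical(dim(img)[1:2], dim(mask)))
  rgb_col <- grDevices::col2rgb(colour) / 255
  over <- img
  for (ch in 1:3) {
    plane <- over[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * rgb_col[ch]
    over[, , ch] <- plane
  }
  df <- expand.grid(y = seq_len(nrow(mask)), x = seq_len(ncol(mask)))
  df$fill <- grDevices::rgb(as.vector(over[, , 1]), as.vector(over[, , 2]),
                            as.vector(over[, , 3]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::theme_void()
}
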