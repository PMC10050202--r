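#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a TPD functional space
#'
#' Density raster with highest-density-region contour outlines (thick lines
#' for the 0.5 and 0.99 regions, thin for the intermediate quantiles).
#'
#' @param object A `tpd_grid`.
#' @param qs Contour quantiles.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tpd_grid <- function(object, qs = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99),
                              ...) {
  cells <- tidy(object)
  masks <- quantile_contours(object, qs)
  # lowest retained density per mask = the contour level of that HDR
  levels <- vapply(masks, function(m) {
    min(object$density[m & object$density > 0])
  }, numeric(1))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$density),
                          breaks = sort(unique(levels)),
                          colour = "grey20", linewidth = 0.3) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkorange") +
    ggplot2::labs(x = "PC1 (fast-slow continuum)",
                  y = "PC2 (reproductive strategy)",
                  fill = "TPD") +
    ggplot2::theme_minimal()
}

#' Plot extinction-scenario losses against their null envelopes
#'
#' IUCN scenarios are drawn as a line over the cumulative gradient with the
#' null 5-95% ribbon; threat scenarios as point ranges.
#'
#' @param object An `fs_scenarios` tibble from [run_scenarios()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_scenarios <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$scenario <- factor(df$scenario, levels = df$scenario)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$null_p5,
                                         ymax = .data$null_p95),
                            colour = "orange", linewidth = 3, alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_p50), colour = "orange") +
    ggplot2::geom_point(ggplot2::aes(y = .data$loss_pct), colour = "darkred",
                        size = 2) +
    ggplot2::labs(x = NULL, y = "Loss of functional diversity (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a fitted risk surface
#'
#' Probability raster with the mean-probability contour in red; extrapolated
#' cells (outside the convex hull of the data) are blanked.
#'
#' @param object An `fs_surface`.
#' @param cells_per_dim Prediction-grid resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_surface <- function(object, cells_per_dim = 100, ...) {
  pr <- predict_surface(object, cells_per_dim = cells_per_dim)
  pr$prob[pr$extrapolated] <- NA
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$prob)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$prob),
                          breaks = attr(pr, "mean_prob"),
                          colour = "red", linewidth = 0.5) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "darkred",
                                  midpoint = attr(pr, "mean_prob"),
                                  na.value = "grey95") +
    ggplot2::labs(x = "PC1", y = "PC2", fill = "P(affected)") +
    ggplot2::theme_minimal()
}

#' Biplot of a (pooled) phylogenetic PCA
#'
#' Species scores with trait-loading arrows on the first two components.
#'
#' @param object An `fs_ppca` or `fs_ppca_pooled`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_ppca <- function(object, ...) {
  sc <- tibble::as_tibble(object$scores[, 1:2], rownames = "species")
  names(sc)[2:3] <- c("pc1", "pc2")
  ld <- tibble::as_tibble(object$loadings[, 1:2], rownames = "trait")
  names(ld)[2:3] <- c("pc1", "pc2")
  mult <- 0.8 * max(abs(unlist(sc[c("pc1", "pc2")]))) /
    max(abs(unlist(ld[c("pc1", "pc2")])))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$pc1 * mult,
                   yend = .data$pc2 * mult),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "darkred"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$pc1 * mult * 1.08, y = .data$pc2 * mult * 1.08,
                   label = .data$trait),
      colour = "darkred", size = 3
    ) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fs_ppca_pooled <- function(object, ...) autoplot(object$pooled, ...)
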