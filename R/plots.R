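# ggplot2 views of each result type.  Figures are derived artifacts; the
# tabular outputs next to them are the reproducible surface.

#' Heatmap of a metagene matrix
#'
#' Rows are genes ordered by window signal (min-max scaled per row for
#' display only), columns are anchored positions.
#'
#' @param object A `metagene_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_matrix <- function(object, ...) {
  m <- object$matrix
  rng <- apply(m, 1, function(v) diff(range(v)))
  scaled <- (m - apply(m, 1, min)) / ifelse(rng == 0, 1, rng)
  ord <- order(rowMeans(m), rownames(m))
  df <- tibble(gene = factor(rep(rownames(m)[ord], times = ncol(m)),
                             levels = rownames(m)[ord]),
               position = rep(object$bins$mid, each = nrow(m)),
               signal = as.vector(scaled[ord, ]))
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$gene,
                                   fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "scaled\nsignal") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "white") +
    ggplot2::labs(x = sprintf("position relative to %s (nt)",
                              toupper(object$anchor)), y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Line plot of one or several meta-profiles
#'
#' @param profile A profile tibble from [meta_profile()] (optionally with a
#'   `strain` column, e.g. from [equalize_upstream()]).
#' @return A ggplot object.
#' @export
plot_meta_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$position, .data$signal))
  if ("strain" %in% names(profile)) {
    p <- p + ggplot2::aes(colour = .data$strain)
  }
  if (all(c("lo", "hi") %in% names(profile))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                                  alpha = 0.2, colour = NA)
  }
  anchor <- attr(profile, "anchor") %||% "anchor"
  p + ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = sprintf("position relative to %s (nt)", toupper(anchor)),
                  y = "calibrated signal") +
    ggplot2::theme_minimal()
}

#' Boxplot of scaled termination indices by strain
#'
#' @param table Stacked scaled `termination_table` with a `strain` column.
#' @param value Column to plot (default `"scaled_b2"`).
#' @return A ggplot object.
#' @export
plot_termination_boxplot <- function(table, value = "scaled_b2") {
  stopifnot("strain" %in% names(table), value %in% names(table))
  ggplot2::ggplot(table, ggplot2::aes(.data$strain, .data[[value]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Titration data with the fitted binding curve
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$protein_nM, .data$anisotropy)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "protein (nM)", y = "anisotropy") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(protein_nM = 10^seq(log10(max(min(df$protein_nM[df$protein_nM > 0]) / 10, 1e-3)),
                                       log10(max(df$protein_nM) * 2), length.out = 200))
    grid$anisotropy <- object$A_free + (object$A_bound - object$A_free) *
      fraction_bound(grid$protein_nM, object$L, object$Kd)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
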