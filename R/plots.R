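# ggplot2 visualisations: contact-matrix heatmaps (linear scale for
# large-scale 500 bp matrices, log scale for fine-scale 20-50 bp matrices)
# and junction density plots.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point
#'   scale_fill_gradient scale_fill_gradient2 scale_colour_viridis_c
#'   coord_fixed labs theme_minimal
NULL

#' Heatmap of a contact matrix
#'
#' The display convention follows the scale of the structure being shown:
#' large-scale matrices (binsize >= 100 bp) are drawn on a linear colour
#' scale, fine-scale matrices (20-50 bp) on a log10 scale with a
#' pseudocount equal to the smallest positive entry. Differential matrices
#' use a diverging scale centred at zero.
#'
#' @param object A `contact_matrix`.
#' @param which Plot `"balanced"` (default if present) or `"counts"`.
#' @param scale `"auto"` (by binsize), `"linear"` or `"log"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_matrix <- function(object, which = NULL,
                                    scale = c("auto", "linear", "log"), ...) {
  scale <- match.arg(scale)
  if (is.null(which)) which <- if (!is.null(object$balanced)) "balanced" else "counts"
  df <- tidy(object)
  val <- df[[which]]
  df2 <- df
  df2[c("start1", "start2")] <- df[c("start2", "start1")]
  df <- bind_rows(df, df2[df2$bin1 != df2$bin2, , drop = FALSE])
  val <- df[[which]]
  if (identical(object$scale, "difference")) {
    p <- ggplot(df, aes(x = .data$start1, y = .data$start2, fill = val)) +
      geom_raster() +
      scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                           name = "difference")
  } else {
    use_log <- scale == "log" || (scale == "auto" && object$grid$binsize < 100)
    if (use_log) {
      pseudo <- min(val[val > 0], na.rm = TRUE)
      val <- log10(val + pseudo)
      name <- sprintf("log10(%s)", which)
    } else {
      name <- which
    }
    p <- ggplot(df, aes(x = .data$start1, y = .data$start2, fill = val)) +
      geom_raster() +
      scale_fill_gradient(low = "white", high = "darkred", name = name)
  }
  p + coord_fixed() + theme_minimal() +
    labs(x = sprintf("%s position (bp)", object$grid$chrom),
         y = sprintf("%s position (bp)", object$grid$chrom),
         title = sprintf("%s:%d-%d at %d bp resolution", object$grid$chrom,
                         object$grid$start, object$grid$end, object$grid$binsize))
}

#' Scatter plot of junction density points
#'
#' Exact junction locations coloured by local point density; points are
#' drawn in ascending density order so dense points draw last.
#'
#' @param points Tibble from [density_points()].
#' @return A ggplot object.
#' @export
plot_density_points <- function(points) {
  ggplot(points, aes(x = .data$x, y = .data$y, colour = .data$density)) +
    geom_point(size = 0.3) +
    scale_colour_viridis_c() +
    coord_fixed() + theme_minimal() +
    labs(x = "junction position 1 (bp)", y = "junction position 2 (bp)",
         colour = "density")
}
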