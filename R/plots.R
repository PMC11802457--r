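#' Plot fuzzy-cluster centre profiles across ages
#'
#' @param object A [fuzzy_cmeans()] result.
#' @param ... Unused.
#' @return A ggplot of centre profiles, one panel line per cluster,
#'   coloured by trend direction.
#' @exportS3Method
autoplot.fuzzy_clustering <- function(object, ...) {
  dirs <- apply(object$centers, 1, function(ctr) {
    if (all(diff(ctr) > 0)) "up" else if (all(diff(ctr) < 0)) "down" else
      "flat"
  })
  df <- tibble::as_tibble(object$centers, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "age",
                        values_to = "center") |>
    dplyr::mutate(age = factor(.data$age, levels = age_levels()),
                  direction = dirs[.data$cluster])
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$center,
                                   group = .data$cluster,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "standardized expression",
                  colour = "trend") +
    ggplot2::theme_minimal()
}

#' Plot cells along pseudotime in the first two PCs
#'
#' @param object A [fit_principal_curve()] result.
#' @param pca The [compute_pca()] result the curve was fitted on.
#' @param ... Unused.
#' @return A ggplot of cells coloured by pseudotime with the fitted
#'   curve overlaid.
#' @exportS3Method
autoplot.pseudotime_result <- function(object, pca, ...) {
  cells <- tibble::tibble(
    pc1 = pca$scores[object$cells$cell_id, 1],
    pc2 = pca$scores[object$cells$cell_id, 2],
    t = object$cells$t
  )
  curve <- tibble::tibble(pc1 = object$curve[, 1],
                          pc2 = object$curve[, 2])
  ggplot2::ggplot(cells, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$t), size = 0.8) +
    ggplot2::geom_path(data = curve, linewidth = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "pseudotime") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Plot the spot hierarchy on the array
#'
#' @param grid The [spot_grid()] the hierarchy was derived from.
#' @param hierarchy A [build_spot_hierarchy()] result.
#' @return A ggplot of spots at their pixel coordinates coloured by
#'   hierarchy class.
#' @export
plot_spot_hierarchy <- function(grid, hierarchy) {
  df <- dplyr::inner_join(grid$spots, tibble::as_tibble(hierarchy),
                          by = "spot_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$pxl_col, .data$pxl_row,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, colour = "spot class") +
    ggplot2::theme_minimal()
}

#' Plot microniche circles over the cell point pattern
#'
#' @param niches A [tile_sgz_circles()] (optionally counted) result.
#' @param cells The point table the circles were laid over.
#' @return A ggplot with cells as points (shaped by label) and circle
#'   outlines.
#' @export
plot_microniche <- function(niches, cells) {
  radius <- attr(niches, "radius")
  theta <- seq(0, 2 * pi, length.out = 60)
  rims <- purrr::map_dfr(seq_len(nrow(niches)), function(i) {
    tibble::tibble(circle_id = niches$circle_id[i],
                   x = niches$center_x[i] + radius * cos(theta),
                   y = niches$center_y[i] + radius * sin(theta))
  })
  pts <- dplyr::mutate(
    tibble::as_tibble(cells),
    label = dplyr::case_when(
      .data$label_a & .data$label_b ~ "A+B",
      .data$label_a ~ "A",
      .data$label_b ~ "B",
      TRUE ~ "unlabelled"
    )
  )
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 0.7) +
    ggplot2::geom_path(data = rims,
                       ggplot2::aes(group = .data$circle_id),
                       colour = "grey40", linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
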