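#' Call inflammatory spots from module scores
#'
#' A spot is inflammatory when its interferon-gamma-response module
#' score strictly exceeds `threshold` (default 0; a score of exactly 0
#' is not called).
#'
#' @param scores A [module_score()] result computed on spots.
#' @param threshold Strict lower bound for the call.
#' @return Tibble `spot_id`, `score`, `is_inflammatory`.
#' @export
call_inflammatory_spots <- function(scores, threshold = 0) {
  stopifnot(is.data.frame(scores), all(c("cell_id", "score") %in%
                                         names(scores)))
  tibble::tibble(
    spot_id = scores$cell_id,
    score = scores$score,
    is_inflammatory = scores$score > threshold
  )
}

#' Hexagonal adjacency of a Visium-style spot array
#'
#' Neighbours of `(r, c)` are the occupied positions among
#' `(r, c +/- 2)` and `(r +/- 1, c +/- 1)` -- the six nearest spots of
#' the hexagonally packed array in array coordinates, independent of the
#' pixel dialect.
#'
#' @param grid A [spot_grid()].
#' @return Named list: spot id -> character vector of neighbouring spot
#'   ids (symmetric by construction).
#' @export
hex_adjacency <- function(grid) {
  stopifnot(inherits(grid, "spot_grid"))
  sp <- grid$spots
  key <- paste(sp$array_row, sp$array_col)
  lookup <- stats::setNames(sp$spot_id, key)
  offsets <- rbind(c(0, 2), c(0, -2), c(1, 1), c(1, -1), c(-1, 1),
                   c(-1, -1))
  adj <- lapply(seq_len(nrow(sp)), function(i) {
    nb_keys <- paste(sp$array_row[i] + offsets[, 1],
                     sp$array_col[i] + offsets[, 2])
    unname(lookup[nb_keys[nb_keys %in% key]])
  })
  stats::setNames(adj, sp$spot_id)
}

#' Classify spots into the inflammatory neighbourhood hierarchy
#'
#' Breadth-first ring expansion from the inflammatory spots over the
#' hexagonal adjacency, restricted to a region mask: ring 1 spots are
#' nearest-neighbour spots (NNS), rings 2..(1 + n_ens_layers) are
#' extended-neighbour layers (ENS1, ENS2, ...), and remaining masked
#' spots are `other`. The classes partition the masked spots.
#'
#' @param is_calls A [call_inflammatory_spots()] tibble (or a logical
#'   vector named by spot id).
#' @param adjacency A [hex_adjacency()] list.
#' @param region_mask Optional character vector of spot ids to analyse
#'   (default: all spots in `adjacency`).
#' @param n_ens_layers Number of extended-neighbour rings.
#' @return Object of class `spot_hierarchy`: tibble `spot_id`, `class`
#'   (factor IS/NNS/ENS1/.../other) with the adjacency attached as an
#'   attribute.
#' @export
build_spot_hierarchy <- function(is_calls, adjacency, region_mask = NULL,
                                 n_ens_layers = 2) {
  if (is.data.frame(is_calls)) {
    is_mask <- stats::setNames(is_calls$is_inflammatory, is_calls$spot_id)
  } else {
    is_mask <- is_calls
  }
  spots <- if (is.null(region_mask)) names(adjacency) else
    intersect(names(adjacency), region_mask)
  ring_labels <- c("NNS", paste0("ENS", seq_len(n_ens_layers)))
  class <- stats::setNames(rep("other", length(spots)), spots)
  frontier <- spots[spots %in% names(is_mask)[is_mask]]
  class[frontier] <- "IS"
  if (!length(frontier)) {
    warning("no inflammatory spots; every masked spot is 'other'")
  }
  for (lab in ring_labels) {
    if (!length(frontier)) break
    nb <- unique(unlist(adjacency[frontier], use.names = FALSE))
    ring <- setdiff(intersect(nb, spots), names(class)[class != "other"])
    class[ring] <- lab
    frontier <- ring
  }
  out <- tibble::tibble(
    spot_id = spots,
    class = factor(unname(class),
                   levels = c("IS", ring_labels, "other"))
  )
  structure(out, adjacency = adjacency, n_ens_layers = n_ens_layers,
            class = c("spot_hierarchy", class(out)))
}

#' Pseudo-spatial ordering and gene modules of the inflammatory gradient
#'
#' Restricted to the hierarchy's spots, a principal curve over the
#' leading spot PCs gives each spot an ordering value `s`, oriented so
#' inflammatory spots sit at low `s` (below the outermost ring on
#' average). Gene modules along `s` come from [pseudotime_modules()] and
#' are numbered inside-out.
#'
#' @param grid A log-normalized [spot_grid()].
#' @param hierarchy A [build_spot_hierarchy()] result with at least 20
#'   spots.
#' @param n_modules Number of gene modules.
#' @param n_pcs PCs under the curve.
#' @param genes Optional gene subset for the modules (default all).
#' @param seed Integer seed.
#' @return Object of class `pseudo_space`: `spots` (tibble `spot_id`,
#'   `class`, `s`), `modules` (a `module_assignment`), `pseudotime` (the
#'   underlying `pseudotime_result`).
#' @export
pseudospatial_modules <- function(grid, hierarchy, n_modules = 4,
                                  n_pcs = 7, genes = NULL, seed = 1L) {
  stopifnot(inherits(grid, "spot_grid"),
            inherits(hierarchy, "spot_hierarchy"))
  if (is.null(grid$lognorm)) {
    stop("spot grid has no lognorm layer; run log_normalize() first",
         call. = FALSE)
  }
  masked <- hierarchy$spot_id
  if (length(masked) < 20) stop("need at least 20 masked spots",
                                call. = FALSE)
  m <- as_expression_matrix(grid)
  m <- subset_cells(m, match(masked, cell_ids(m)))
  n_pcs <- min(n_pcs, min(dim(m$lognorm)) - 1L)
  pca <- compute_pca(m, n_pcs = n_pcs)
  is_spots <- hierarchy$spot_id[hierarchy$class == "IS"]
  pt <- fit_principal_curve(pca, n_pcs = n_pcs, root_cells = is_spots)
  s <- stats::setNames(pt$cells$t, pt$cells$cell_id)
  # orient against the outermost populated non-IS class
  non_is <- setdiff(levels(hierarchy$class), "IS")
  populated <- non_is[non_is %in% as.character(hierarchy$class)]
  outer <- if (length(populated)) {
    hierarchy$spot_id[hierarchy$class == populated[length(populated)]]
  } else character()
  if (length(is_spots) && length(outer) &&
      mean(s[is_spots]) > mean(s[outer])) {
    s <- 1 - s
    pt$cells$t <- 1 - pt$cells$t
    pt$flipped <- !pt$flipped
  }
  modules <- pseudotime_modules(m, s, n_modules = n_modules,
                                genes = genes, seed = seed)
  spots <- tibble::tibble(
    spot_id = masked,
    class = hierarchy$class,
    s = unname(s[masked])
  )
  structure(list(spots = spots, modules = modules, pseudotime = pt),
            class = "pseudo_space")
}

#' @export
print.pseudo_space <- function(x, ...) {
  cls <- x$spots |>
    dplyr::summarise(mean_s = mean(.data$s), .by = "class") |>
    dplyr::arrange(.data$class)
  cat("<pseudo_space> mean ordering value by class:\n")
  for (i in seq_len(nrow(cls))) {
    cat(sprintf("  %-6s %.3f\n", cls$class[i], cls$mean_s[i]))
  }
  invisible(x)
}

#' Per-class summary of spot scores along the hierarchy
#'
#' Convenience join of a score table with hierarchy classes, averaged by
#' class; used to inspect the inflammatory gradient.
#'
#' @param hierarchy A [build_spot_hierarchy()] result.
#' @param scores A [module_score()] result on the same spots.
#' @return Tibble `class`, `n`, `mean_score`.
#' @export
hierarchy_score_summary <- function(hierarchy, scores) {
  tibble::tibble(spot_id = scores$cell_id, score = scores$score) |>
    dplyr::inner_join(tibble::as_tibble(hierarchy), by = "spot_id") |>
    dplyr::summarise(n = dplyr::n(), mean_score = mean(.data$score),
                     .by = "class") |>
    dplyr::arrange(.data$class)
}
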