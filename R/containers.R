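#' Ordered age labels used throughout the package
#'
#' The three cohort labels, in biological order. Cohorts correspond to
#' young adult, middle-aged and old mice.
#'
#' @return Character vector `c("young", "middle", "old")`.
#' @export
age_levels <- function() c("young", "middle", "old")

#' Coerce a vector to the ordered age factor
#'
#' @param x Character, factor or integer (0/1/2) vector of age labels.
#' @return Ordered factor with levels young < middle < old. Values outside
#'   the vocabulary become `NA`.
#' @export
age_factor <- function(x) {
  if (is.numeric(x)) x <- age_levels()[x + 1L]
  factor(as.character(x), levels = age_levels(), ordered = TRUE)
}

#' Construct a gene x cell expression container
#'
#' Holds raw counts (sparse-capable), an optional log-normalized layer of
#' identical shape, and per-cell metadata. Genes are rows, cells are
#' columns; spot data use the same orientation (see [spot_grid()]).
#'
#' @param counts Gene x cell matrix (base or `Matrix`) of non-negative
#'   integer counts with unique row and column names.
#' @param cell_meta Data frame with one row per cell. Must contain a
#'   `cell_id` column matching `colnames(counts)` (or row names are used);
#'   missing `cell_type`/`age` columns are filled with `"unknown"`.
#' @param lognorm Optional matrix of identical dimensions and dimnames.
#' @return An object of class `expression_matrix` with elements `counts`,
#'   `lognorm` and `cell_meta` (a tibble with `cell_id`, `cell_type`,
#'   `age` as an ordered factor, plus any extra columns).
#' @export
expression_matrix <- function(counts, cell_meta = NULL, lognorm = NULL) {
  counts <- methods::as(methods::as(as_sparse(counts), "generalMatrix"), "CsparseMatrix")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("counts must carry gene (row) and cell (column) names", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(cell_id = cell_ids)
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    stop("cell_meta must have a cell_id column", call. = FALSE)
  }
  if (!setequal(cell_meta$cell_id, cell_ids)) {
    stop("cell_meta cell ids do not match the count matrix", call. = FALSE)
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  if (!"cell_type" %in% names(cell_meta)) cell_meta$cell_type <- "unknown"
  if (!"age" %in% names(cell_meta)) cell_meta$age <- "unknown"
  cell_meta$age <- age_factor(cell_meta$age)
  if (!is.null(lognorm)) {
    if (!identical(dim(lognorm), dim(counts)) ||
        !identical(rownames(lognorm), gene_ids) ||
        !identical(colnames(lognorm), cell_ids)) {
      stop("lognorm layer must match counts in shape and dimnames", call. = FALSE)
    }
    if (min(lognorm) < 0) stop("lognorm values must be non-negative", call. = FALSE)
  }
  structure(
    list(counts = counts, lognorm = lognorm, cell_meta = cell_meta),
    class = "expression_matrix"
  )
}

as_sparse <- function(m) {
  if (inherits(m, "sparseMatrix")) m else Matrix::Matrix(as.matrix(m), sparse = TRUE)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d cells (%s lognorm layer)\n",
    nrow(x$counts), ncol(x$counts), if (is.null(x$lognorm)) "no" else "with"
  ))
  types <- table(x$cell_meta$cell_type)
  cat("cell types:", paste(sprintf("%s=%d", names(types), types), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Gene identifiers of an expression container
#' @param x An `expression_matrix` or `spot_grid`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) UseMethod("gene_ids")

#' @export
gene_ids.expression_matrix <- function(x) rownames(x$counts)

#' @export
gene_ids.spot_grid <- function(x) rownames(x$counts)

#' Cell (or spot) identifiers of an expression container
#' @param x An `expression_matrix` or `spot_grid`.
#' @return Character vector of cell or spot ids.
#' @export
cell_ids <- function(x) UseMethod("cell_ids")

#' @export
cell_ids.expression_matrix <- function(x) colnames(x$counts)

#' @export
cell_ids.spot_grid <- function(x) colnames(x$counts)

#' Construct a Visium-style spot grid container
#'
#' Spots live on a hexagonally packed array addressed by integer
#' `(array_row, array_col)` with the usual Visium parity convention
#' (occupied columns within a row share the parity of the row), plus
#' pixel/micrometre coordinates for plotting and distance work.
#' Expression is stored gene-major (genes x spots), the same orientation
#' as [expression_matrix()].
#'
#' @param counts Gene x spot count matrix with dimnames.
#' @param spots Data frame with columns `spot_id`, `array_row`,
#'   `array_col`, `pxl_row`, `pxl_col` and optionally `region`
#'   (default `"other"`).
#' @param lognorm Optional gene x spot matrix of identical shape.
#' @return Object of class `spot_grid` with elements `counts`, `lognorm`,
#'   `spots` (tibble, one row per spot in column order of `counts`).
#' @export
spot_grid <- function(counts, spots, lognorm = NULL) {
  counts <- methods::as(methods::as(as_sparse(counts), "generalMatrix"), "CsparseMatrix")
  spots <- tibble::as_tibble(spots)
  need <- c("spot_id", "array_row", "array_col", "pxl_row", "pxl_col")
  if (!all(need %in% names(spots))) {
    stop("spots table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"region" %in% names(spots)) spots$region <- "other"
  if (anyDuplicated(spots$spot_id)) stop("duplicate spot ids", call. = FALSE)
  if (anyDuplicated(spots[, c("array_row", "array_col")])) {
    stop("duplicate (array_row, array_col) positions", call. = FALSE)
  }
  parity_ok <- spots |>
    dplyr::mutate(par = (.data$array_row + .data$array_col) %% 2L) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$par) == 1L, .by = "array_row")
  if (!all(parity_ok$ok)) {
    stop("array column parity must be constant within each array row", call. = FALSE)
  }
  if (!setequal(spots$spot_id, colnames(counts))) {
    stop("spot ids do not match count matrix columns", call. = FALSE)
  }
  spots <- spots[match(colnames(counts), spots$spot_id), , drop = FALSE]
  if (!is.null(lognorm)) {
    lognorm <- as.matrix(lognorm)
    stopifnot(identical(dimnames(lognorm), dimnames(counts)))
  }
  structure(
    list(counts = counts, lognorm = lognorm, spots = spots),
    class = "spot_grid"
  )
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf(
    "<spot_grid> %d genes x %d spots, regions: %s\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$spots$region), collapse = ", ")
  ))
  invisible(x)
}

#' View a spot grid as an expression container
#'
#' Wraps the spot grid's matrices in an [expression_matrix()]-compatible
#' object so scoring and trajectory functions apply unchanged to spots
#' (spot ids play the role of cell ids; `cell_type` is the region label).
#'
#' @param grid A `spot_grid`.
#' @return An `expression_matrix` whose cells are the spots.
#' @export
as_expression_matrix <- function(grid) {
  stopifnot(inherits(grid, "spot_grid"))
  meta <- tibble::tibble(
    cell_id = grid$spots$spot_id,
    cell_type = grid$spots$region,
    age = "unknown"
  )
  m <- expression_matrix(grid$counts, cell_meta = meta)
  m$lognorm <- grid$lognorm
  m
}
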