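#' Read a 10x-style triplet directory into an expression container
#'
#' Expects `matrix.mtx[.gz]`, `features.tsv[.gz]` and `barcodes.tsv[.gz]`
#' in `dir_path`, plus an optional `cell_meta.csv` keyed by barcode.
#' Genes are keyed by feature id (first column of features.tsv); when the
#' same gene symbol maps to several feature ids the ids keep entries
#' distinct, so no collision handling is needed downstream.
#'
#' @param dir_path Directory containing the triplet files.
#' @return An [expression_matrix()].
#' @export
read_counts_10x <- function(dir_path) {
  mtx <- find_one(dir_path, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- find_one(dir_path, c("features.tsv", "features.tsv.gz",
                               "genes.tsv", "genes.tsv.gz"))
  bc <- find_one(dir_path, c("barcodes.tsv", "barcodes.tsv.gz"))
  counts <- Matrix::readMM(mtx)
  features <- readr::read_tsv(feat, col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)
  barcodes <- readr::read_tsv(bc, col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)
  if (nrow(features) != nrow(counts)) {
    stop("features.tsv has ", nrow(features), " rows but the matrix header ",
         "declares ", nrow(counts), " genes", call. = FALSE)
  }
  if (nrow(barcodes) != ncol(counts)) {
    stop("barcodes.tsv has ", nrow(barcodes), " rows but the matrix header ",
         "declares ", ncol(counts), " cells", call. = FALSE)
  }
  ids <- as.character(features[[1]])
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "-dup")
  }
  bcs <- as.character(barcodes[[1]])
  if (anyDuplicated(bcs)) stop("duplicate barcodes", call. = FALSE)
  dimnames(counts) <- list(ids, bcs)
  meta_path <- file.path(dir_path, "cell_meta.csv")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- readr::read_csv(meta_path, show_col_types = FALSE,
                            progress = FALSE)
    if (!"cell_id" %in% names(meta)) names(meta)[1] <- "cell_id"
  }
  expression_matrix(counts, cell_meta = meta)
}

find_one <- function(dir_path, candidates) {
  for (f in candidates) {
    p <- file.path(dir_path, f)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(candidates, collapse = "/"), " found in ",
       dir_path, call. = FALSE)
}

#' Write an expression container as a 10x-style triplet directory
#'
#' Inverse of [read_counts_10x()]; integer counts and ids round-trip
#' exactly. Cell metadata is written to `cell_meta.csv`.
#'
#' @param m An [expression_matrix()].
#' @param dir_path Output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_counts_10x <- function(m, dir_path) {
  stopifnot(inherits(m, "expression_matrix"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(dir_path, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(id = gene_ids(m), name = gene_ids(m),
                   type = "Gene Expression"),
    file.path(dir_path, "features.tsv"), col_names = FALSE
  )
  readr::write_tsv(tibble::tibble(barcode = cell_ids(m)),
                   file.path(dir_path, "barcodes.tsv"), col_names = FALSE)
  meta <- m$cell_meta
  meta$age <- as.character(meta$age)
  readr::write_csv(meta, file.path(dir_path, "cell_meta.csv"))
  invisible(dir_path)
}

#' Read a Visium-style spot grid
#'
#' The positions file follows the tissue-positions dialect: columns
#' `barcode, in_tissue, array_row, array_col, pxl_row, pxl_col`, with an
#' optional `region` column. Only `in_tissue == 1` spots are retained.
#' Expression comes from a 10x triplet directory whose barcodes name the
#' spots; the matrix is transposed to the package's gene-major layout if
#' needed (triplets are stored gene x spot already).
#'
#' @param positions_csv Path to the positions CSV.
#' @param counts_dir 10x triplet directory of spot counts.
#' @return A [spot_grid()].
#' @export
read_spot_grid <- function(positions_csv, counts_dir) {
  pos <- readr::read_csv(positions_csv, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row", "pxl_col")
  if (!all(need %in% names(pos))) {
    stop("positions file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pos[, c("array_row", "array_col")])) {
    stop("duplicate (array_row, array_col) in positions file", call. = FALSE)
  }
  pos <- dplyr::filter(pos, .data$in_tissue == 1)
  m <- read_counts_10x(counts_dir)
  missing <- setdiff(cell_ids(m), pos$barcode)
  if (length(missing)) {
    stop("barcodes present in counts but absent from positions: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  pos <- pos[match(cell_ids(m), pos$barcode), , drop = FALSE]
  spots <- tibble::tibble(
    spot_id = pos$barcode,
    array_row = as.integer(pos$array_row),
    array_col = as.integer(pos$array_col),
    pxl_row = pos$pxl_row,
    pxl_col = pos$pxl_col,
    region = if ("region" %in% names(pos)) pos$region else "other"
  )
  spot_grid(m$counts, spots)
}

#' Write a spot grid as positions CSV plus a 10x triplet directory
#'
#' @param grid A [spot_grid()].
#' @param positions_csv Output path for the positions CSV.
#' @param counts_dir Output triplet directory.
#' @return `positions_csv`, invisibly.
#' @export
write_spot_grid <- function(grid, positions_csv, counts_dir) {
  stopifnot(inherits(grid, "spot_grid"))
  pos <- tibble::tibble(
    barcode = grid$spots$spot_id,
    in_tissue = 1L,
    array_row = grid$spots$array_row,
    array_col = grid$spots$array_col,
    pxl_row = grid$spots$pxl_row,
    pxl_col = grid$spots$pxl_col,
    region = grid$spots$region
  )
  readr::write_csv(pos, positions_csv)
  write_counts_10x(as_expression_matrix(grid), counts_dir)
  invisible(positions_csv)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene ids.
#' Duplicate genes within a line are dropped, keeping the first
#' occurrence. Lines with fewer than three fields are a format error.
#'
#' @param gmt_path Path to a GMT file.
#' @return Named list of character vectors (one per set, in file order).
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-c(1, 2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param gmt_path Output path.
#' @param description Description field written per line.
#' @return `gmt_path`, invisibly.
#' @export
write_gene_sets <- function(sets, gmt_path, description = "nichetrack") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, gmt_path)
  invisible(gmt_path)
}
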