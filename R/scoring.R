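#' Log-normalize counts
#'
#' Adds a `lognorm` layer with
#' `ln(1 + counts[g, c] * scale_factor / total_counts[c])`, the standard
#' library-size normalization for UMI counts. Cells with zero total
#' counts get an all-zero column and a warning.
#'
#' @param m An [expression_matrix()] (or [spot_grid()], normalized in
#'   place on its matrices).
#' @param scale_factor Scale factor (default 10,000).
#' @return The input object with its `lognorm` layer set.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  obj <- m$counts
  totals <- Matrix::colSums(obj)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts; ",
            "their lognorm column is all zero")
    totals[totals == 0] <- 1
  }
  ln <- obj
  col_of <- rep(seq_len(ncol(obj)), diff(obj@p))
  ln@x <- log1p(obj@x * scale_factor / totals[col_of])
  m$lognorm <- ln
  m
}

lognorm_or_stop <- function(m) {
  if (is.null(m$lognorm)) {
    stop("no lognorm layer; run log_normalize() first", call. = FALSE)
  }
  m$lognorm
}

#' Select highly variable genes by standardized variance
#'
#' Ranks genes by the variance of their standardized counts: per gene,
#' counts are centred at the gene mean and scaled by an expected standard
#' deviation taken from a loess fit (span `loess_span`) of log10
#' count-variance on log10 count-mean; standardized values are clipped
#' above at `sqrt(n_cells)` before the variance is taken. Constant genes
#' get standardized variance 0 and rank last.
#'
#' @param m An [expression_matrix()] with at least 2 cells.
#' @param n Number of genes to return; `n >= n_genes` returns all genes
#'   in rank order.
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of gene ids, most variable first.
#' @export
select_hvgs <- function(m, n = 5000, loess_span = 0.3) {
  counts <- m$counts
  n_cells <- ncol(counts)
  if (n_cells < 2) stop("need at least 2 cells", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  mu <- Matrix::rowMeans(counts)
  ex2 <- Matrix::rowSums(counts^2)
  v <- (ex2 - n_cells * mu^2) / (n_cells - 1)
  v <- pmax(v, 0)
  std_var <- numeric(nrow(counts))
  fit_on <- v > 0 & mu > 0
  if (sum(fit_on) >= 5) {
    fit <- stats::loess(log10(v[fit_on]) ~ log10(mu[fit_on]),
                        span = loess_span, degree = 2)
    sd_exp <- sqrt(10^stats::predict(fit))
    clip <- sqrt(n_cells)
    # sparse-aware sum of squared standardized (clipped) values
    idx <- which(fit_on)
    gene_of <- counts@i + 1L
    keep <- gene_of %in% idx
    pos <- match(gene_of[keep], idx)
    z_nonzero <- (counts@x[keep] - mu[idx][pos]) / sd_exp[pos]
    z_nonzero <- pmin(z_nonzero, clip)
    ssq_nz <- tapply_sum(z_nonzero^2, pos, length(idx))
    n_nz <- tapply_sum(rep(1, length(pos)), pos, length(idx))
    z_zero <- -mu[idx] / sd_exp
    ssq <- ssq_nz + (n_cells - n_nz) * z_zero^2
    std_var[idx] <- ssq / (n_cells - 1)
  }
  ord <- order(-std_var, rownames(counts))
  rownames(counts)[ord][seq_len(min(n, nrow(counts)))]
}

tapply_sum <- function(x, index, n_out) {
  out <- numeric(n_out)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Gene-set module score with binned control genes
#'
#' Per cell, the mean log-normalized expression of the set genes minus
#' the mean over pooled control genes. All genes are placed in `n_bins`
#' equal-frequency bins of mean expression (ties broken by gene id);
#' each set gene draws `n_ctrl` controls from its own bin, excluding
#' itself, with replacement only when the bin holds fewer candidates.
#'
#' Sampling is canonical and fully reproducible: set genes are processed
#' in sorted gene-id order, each drawing from its bin's candidate list
#' (sorted by gene id) via `sample.int` under `seed`. Scores are
#' therefore invariant to gene and cell ordering of the input.
#'
#' @param m An [expression_matrix()] with a lognorm layer (use
#'   [as_expression_matrix()] for spot grids).
#' @param gene_set Character vector of gene ids (a [read_gene_sets()]
#'   element).
#' @param n_bins Number of expression bins.
#' @param n_ctrl Control genes per set gene.
#' @param seed Integer seed for the control draw.
#' @param set_name Label recorded in the output.
#' @return A tibble (`cell_id`, `set`, `score`) of class
#'   `module_score_result`, with attributes `controls` (named list:
#'   set gene -> control genes), `bins` (tibble `gene`, `bin`) and
#'   `seed`.
#' @export
module_score <- function(m, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L, set_name = "module") {
  ln <- lognorm_or_stop(m)
  if (n_bins < 1) stop("n_bins must be at least 1", call. = FALSE)
  genes <- rownames(ln)
  present <- sort(intersect(unique(gene_set), genes))
  if (!length(present)) {
    stop("no gene of set '", set_name, "' is present in the matrix",
         call. = FALSE)
  }
  means <- Matrix::rowMeans(ln)
  ord <- order(means, genes)
  n_genes <- length(genes)
  bin_along <- ceiling(seq_len(n_genes) * n_bins / n_genes)
  bin <- integer(n_genes)
  bin[ord] <- bin_along
  names(bin) <- genes

  controls <- withr::with_seed(seed, {
    lapply(stats::setNames(present, present), function(g) {
      candidates <- sort(setdiff(genes[bin == bin[[g]]], g))
      if (!length(candidates)) return(character())
      replace <- length(candidates) < n_ctrl
      candidates[sample.int(length(candidates), n_ctrl, replace = replace)]
    })
  })
  pool <- unlist(controls, use.names = FALSE)
  set_mean <- Matrix::colMeans(ln[present, , drop = FALSE])
  ctrl_mean <- if (length(pool)) {
    Matrix::colMeans(ln[pool, , drop = FALSE])
  } else rep(0, ncol(ln))
  out <- tibble::tibble(cell_id = colnames(ln), set = set_name,
                        score = as.numeric(set_mean - ctrl_mean))
  attr(out, "controls") <- controls
  attr(out, "bins") <- tibble::tibble(gene = genes, bin = unname(bin))
  attr(out, "seed") <- seed
  class(out) <- c("module_score_result", class(out))
  out
}

#' One-vs-rest marker genes by rank-sum test
#'
#' For each group, every gene is tested with a two-sided Wilcoxon
#' rank-sum test of in-group versus all other cells on log-normalized
#' expression; p-values are Benjamini-Hochberg adjusted across genes
#' within each group. `avg_log2fc` is
#' `log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`. Only rows
#' with `p_adj < alpha` and `avg_log2fc > lfc_min` are kept, ordered by
#' `avg_log2fc` within group.
#'
#' @param m An [expression_matrix()] with a lognorm layer.
#' @param labels Grouping vector (defaults to `cell_meta$cell_type`).
#' @param alpha Adjusted-p cutoff.
#' @param lfc_min Log2 fold-change cutoff (strict `>`).
#' @return Tibble `gene, group, avg_log2fc, p, p_adj`.
#' @export
rank_markers <- function(m, labels = NULL, alpha = 0.05, lfc_min = 0.25) {
  ln <- as.matrix(lognorm_or_stop(m))
  if (is.null(labels)) labels <- m$cell_meta$cell_type
  labels <- as.character(labels)
  counts_by <- table(labels)
  if (length(counts_by) < 2) stop("need at least 2 groups", call. = FALSE)
  small <- names(counts_by)[counts_by < 3]
  if (length(small)) {
    stop("groups with fewer than 3 cells: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  groups <- sort(names(counts_by))
  res <- purrr::map_dfr(groups, function(grp) {
    inside <- labels == grp
    expm_in <- rowMeans(expm1(ln[, inside, drop = FALSE]))
    expm_out <- rowMeans(expm1(ln[, !inside, drop = FALSE]))
    lfc <- log2((expm_in + 1) / (expm_out + 1))
    p <- vapply(seq_len(nrow(ln)), function(g) {
      x <- ln[g, inside]
      y <- ln[g, !inside]
      if (stats::var(c(x, y)) == 0) return(1)
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }, 0)
    tibble::tibble(gene = rownames(ln), group = grp, avg_log2fc = lfc,
                   p = p, p_adj = stats::p.adjust(p, "BH"))
  })
  res |>
    dplyr::filter(.data$p_adj < alpha, .data$avg_log2fc > lfc_min) |>
    dplyr::arrange(.data$group, dplyr::desc(.data$avg_log2fc))
}

#' Mean log-normalized expression per group
#'
#' @param m An [expression_matrix()] with a lognorm layer.
#' @param group_key Name of a `cell_meta` column, or a grouping vector of
#'   length `n_cells`.
#' @return Group x gene matrix of arithmetic means of `lognorm`.
#' @export
pseudobulk_by_group <- function(m, group_key = "cell_type") {
  ln <- lognorm_or_stop(m)
  groups <- if (length(group_key) == 1 && is.character(group_key)) {
    as.character(m$cell_meta[[group_key]])
  } else {
    as.character(group_key)
  }
  if (length(groups) != ncol(ln)) {
    stop("grouping length does not match cell count", call. = FALSE)
  }
  if (anyNA(groups)) stop("grouping contains missing values", call. = FALSE)
  lvls <- sort(unique(groups))
  out <- t(vapply(lvls, function(g) {
    Matrix::rowMeans(ln[, groups == g, drop = FALSE])
  }, numeric(nrow(ln))))
  rownames(out) <- lvls
  colnames(out) <- rownames(ln)
  out
}
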