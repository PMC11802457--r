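# Small builders shared across test files. All fixtures are constructed
# in code; nothing is read from disk.

toy_expression <- function(counts, cell_types = NULL, ages = NULL,
                           normalize = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  }
  meta <- tibble::tibble(
    cell_id = colnames(counts),
    cell_type = cell_types %||% "unknown",
    age = ages %||% "unknown"
  )
  m <- expression_matrix(counts, cell_meta = meta)
  if (normalize) m <- log_normalize(m) else m
}

# null matrix: independent Poisson counts, no structure
null_expression <- function(n_genes = 120, n_cells = 60, lambda = 5,
                            seed = 42) {
  withr::with_seed(seed, {
    counts <- matrix(stats::rpois(n_genes * n_cells, lambda),
                     n_genes, n_cells)
    toy_expression(counts)
  })
}

# independent brute-force recomputation of the binned-control module
# score, written as plain dense-matrix loops
oracle_module_score <- function(m, gene_set, n_bins, n_ctrl, seed) {
  ln <- as.matrix(m$lognorm)
  genes <- rownames(ln)
  means <- apply(ln, 1, mean)
  ord <- order(means, genes)
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(ord) * n_bins / length(genes))
  present <- sort(intersect(unique(gene_set), genes))
  controls <- withr::with_seed(seed, {
    out <- list()
    for (g in present) {
      cand <- sort(setdiff(genes[bin == bin[match(g, genes)]], g))
      repl <- length(cand) < n_ctrl
      out[[g]] <- cand[sample.int(length(cand), n_ctrl, replace = repl)]
    }
    out
  })
  pool <- unlist(controls, use.names = FALSE)
  score <- numeric(ncol(ln))
  for (j in seq_len(ncol(ln))) {
    score[j] <- mean(ln[present, j]) - mean(ln[pool, j])
  }
  score
}

# independent BFS ring labelling over a pixel-distance neighbour rule
# (contrast with the package's array-offset rule)
oracle_rings <- function(spots, is_ids, n_layers = 2, pitch = 100) {
  nb_of <- function(i) {
    d <- sqrt((spots$pxl_col - spots$pxl_col[i])^2 +
                (spots$pxl_row - spots$pxl_row[i])^2)
    spots$spot_id[d > 0 & d <= 1.1 * pitch]
  }
  lab <- stats::setNames(rep("other", nrow(spots)), spots$spot_id)
  lab[is_ids] <- "IS"
  frontier <- is_ids
  for (ring in c("NNS", paste0("ENS", seq_len(n_layers)))) {
    nxt <- character()
    for (id in frontier) {
      nxt <- c(nxt, nb_of(match(id, spots$spot_id)))
    }
    nxt <- setdiff(unique(nxt), names(lab)[lab != "other"])
    lab[nxt] <- ring
    frontier <- nxt
  }
  lab
}

# planted-lineage atlas at unit-test scale (small gene blocks)
small_atlas <- function(seed = 7, n = 60, n_genes = 200, n_markers = 10,
                        n_aging = 15, n_module_genes = 10, ...) {
  simulate_lineage_atlas(
    n_per_group = n, n_genes = n_genes, n_markers = n_markers,
    n_aging = n_aging, n_module_genes = n_module_genes, seed = seed, ...
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
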