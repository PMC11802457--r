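#' Principal component analysis of log-normalized expression
#'
#' Genes are centred and scaled to unit variance across cells before the
#' decomposition (zero-variance genes are dropped). The sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive, making results deterministic.
#'
#' @param m An [expression_matrix()] with a lognorm layer.
#' @param n_pcs Number of components to keep (at most
#'   `min(n_genes, n_cells) - 1`).
#' @param genes Optional gene subset (e.g. [select_hvgs()] output).
#' @return Object of class `pca_result`: `scores` (cell x PC),
#'   `loadings` (gene x PC, orthonormal), `var_explained` (proportion of
#'   total variance per kept PC), `sdev`.
#' @export
compute_pca <- function(m, n_pcs = 50, genes = NULL) {
  ln <- lognorm_or_stop(m)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(ln))
    if (length(missing)) {
      stop("genes not in matrix: ", paste(utils::head(missing, 5),
                                          collapse = ", "), call. = FALSE)
    }
    ln <- ln[genes, , drop = FALSE]
  }
  x <- as.matrix(ln)
  sds <- apply(x, 1, stats::sd)
  keep <- sds > 0
  x <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) /
    sds[keep]
  max_pcs <- min(dim(x)) - 1L
  if (n_pcs > max_pcs) {
    stop("n_pcs = ", n_pcs, " exceeds min(genes, cells) - 1 = ", max_pcs,
         call. = FALSE)
  }
  sv <- svd(t(x))
  flip <- vapply(seq_len(n_pcs), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(sv$u[, seq_len(n_pcs), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_pcs)], n_pcs), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(n_pcs), drop = FALSE], 2, flip, "*")
  rownames(scores) <- colnames(x)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(loadings) <- rownames(x)
  colnames(loadings) <- colnames(scores)
  ev <- sv$d^2 / (ncol(x) - 1)
  structure(
    list(scores = scores, loadings = loadings,
         var_explained = ev[seq_len(n_pcs)] / sum(ev),
         sdev = sqrt(ev[seq_len(n_pcs)])),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d cells x %d PCs; PC1 %.1f%% variance\n",
              nrow(x$scores), ncol(x$scores), 100 * x$var_explained[1]))
  invisible(x)
}

#' Fit a principal curve and derive pseudotime
#'
#' Hastie-Stuetzle alternation: initialize the ordering on PC1, then
#' repeatedly (i) smooth each PC coordinate against the current
#' arc-length position with a smoothing spline (df = 6), (ii) resample
#' the fitted curve at `n_arc` points, and (iii) project every cell to
#' its nearest curve segment to obtain the new arc-length position.
#' Iterations stop when the mean squared projection distance improves by
#' less than `tol` or after `max_iter` rounds; a round that would
#' increase it is rejected, so the recorded trace is decreasing.
#' Pseudotime `t` is the min-max-scaled arc position.
#'
#' @param pca A [compute_pca()] result.
#' @param n_pcs Number of leading PCs the curve lives in.
#' @param root_cells Optional cell ids that should sit at low `t`; the
#'   axis is flipped (with a message) if their mean `t` is in the upper
#'   half.
#' @param df Degrees of freedom of the coordinate smoother.
#' @param n_arc Arc-length sample points of the curve.
#' @param tol Convergence tolerance on mean squared projection distance.
#' @param max_iter Maximum iterations.
#' @return Object of class `pseudotime_result`: `cells` (tibble
#'   `cell_id`, `t`, `proj_dist`), `curve` (ordered n_arc x n_pcs
#'   matrix), `n_pcs`, `mse_trace`, `flipped`.
#' @export
fit_principal_curve <- function(pca, n_pcs = 7, root_cells = NULL,
                                df = 6, n_arc = 200, tol = 1e-4,
                                max_iter = 50) {
  stopifnot(inherits(pca, "pca_result"))
  if (n_pcs > ncol(pca$scores)) {
    stop("n_pcs exceeds available PCs", call. = FALSE)
  }
  x <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  if (nrow(x) < 10) stop("need at least 10 cells", call. = FALSE)
  if (all(apply(x, 2, stats::sd) == 0)) {
    stop("degenerate input: all points identical", call. = FALSE)
  }
  lambda <- x[, 1]
  state <- NULL
  mse_trace <- numeric()
  prev_mse <- Inf
  for (iter in seq_len(max_iter)) {
    curve <- smooth_curve(lambda, x, df = df, n_arc = n_arc)
    proj <- project_to_polyline(x, curve)
    mse <- mean(proj$dist2)
    if (mse > prev_mse) break
    state <- list(curve = curve, lambda = proj$arc,
                  dist = sqrt(proj$dist2))
    mse_trace <- c(mse_trace, mse)
    if (prev_mse - mse < tol) break
    prev_mse <- mse
    lambda <- proj$arc
  }
  rng <- range(state$lambda)
  if (diff(rng) == 0) stop("degenerate curve: single arc position",
                           call. = FALSE)
  t <- (state$lambda - rng[1]) / diff(rng)
  flipped <- FALSE
  if (!is.null(root_cells)) {
    root <- intersect(root_cells, rownames(x))
    if (length(root) && mean(t[root]) > mean(t)) {
      t <- 1 - t
      state$curve <- state$curve[rev(seq_len(nrow(state$curve))), ,
                                 drop = FALSE]
      flipped <- TRUE
      message("pseudotime orientation flipped so root cells sit at low t")
    }
  }
  structure(
    list(
      cells = tibble::tibble(cell_id = rownames(x), t = unname(t),
                             proj_dist = unname(state$dist)),
      curve = state$curve, n_pcs = n_pcs, mse_trace = mse_trace,
      flipped = flipped
    ),
    class = "pseudotime_result"
  )
}

smooth_curve <- function(lambda, x, df, n_arc) {
  grid <- seq(min(lambda), max(lambda), length.out = n_arc)
  n_unique <- length(unique(lambda))
  curve <- vapply(seq_len(ncol(x)), function(j) {
    if (n_unique >= 8) {
      fit <- stats::smooth.spline(lambda, x[, j],
                                  df = min(df, n_unique - 1))
      stats::predict(fit, grid)$y
    } else {
      fit <- stats::lm(x[, j] ~ lambda)
      stats::predict(fit, data.frame(lambda = grid))
    }
  }, numeric(n_arc))
  curve
}

project_to_polyline <- function(x, curve) {
  n <- nrow(x)
  seg_len <- sqrt(rowSums(diff(curve)^2))
  arc_at <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, n)
  best_arc <- numeric(n)
  for (i in seq_len(nrow(curve) - 1)) {
    p <- curve[i, ]
    d <- curve[i + 1, ] - p
    len2 <- sum(d^2)
    w <- sweep(x, 2, p)
    tt <- if (len2 > 0) pmin(pmax((w %*% d) / len2, 0), 1) else
      matrix(0, n, 1)
    resid <- w - tcrossprod(tt[, 1], d)
    d2 <- rowSums(resid^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- arc_at[i] + tt[upd, 1] * sqrt(len2)
  }
  list(arc = stats::setNames(best_arc, rownames(x)), dist2 = best_d2)
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf(
    "<pseudotime_result> %d cells on %d PCs; %d iterations, final MSE %.4g%s\n",
    nrow(x$cells), x$n_pcs, length(x$mse_trace),
    utils::tail(x$mse_trace, 1), if (x$flipped) " (flipped)" else ""
  ))
  invisible(x)
}

#' @exportS3Method
tidy.pseudotime_result <- function(x, ...) x$cells

#' @exportS3Method
glance.pseudotime_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells), n_pcs = x$n_pcs,
    iterations = length(x$mse_trace),
    mse = utils::tail(x$mse_trace, 1), flipped = x$flipped
  )
}

#' Order genes into pseudotime modules
#'
#' Each gene's log-normalized expression is smoothed against pseudotime
#' with a cubic smoothing spline (df = 6), evaluated on a 100-point grid
#' and z-scored; profiles are clustered with seeded k-means (10
#' restarts) and the modules renumbered by the mean position of their
#' profile peaks, so module 1 peaks earliest. Constant genes cannot be
#' profiled and are reported as unassigned.
#'
#' @param m An [expression_matrix()] with a lognorm layer.
#' @param pt A [fit_principal_curve()] result, or a numeric pseudotime
#'   vector named by cell id.
#' @param n_modules Number of modules (>= 2).
#' @param genes Genes to assign (default: all genes in the matrix).
#' @param seed Integer seed for k-means.
#' @return Object of class `module_assignment`: `assignment` (tibble
#'   `gene`, `module`, `peak_position`), `profiles` (gene x 100 z-scored
#'   matrix), `grid`, `unassigned` (character).
#' @export
pseudotime_modules <- function(m, pt, n_modules = 4, genes = NULL,
                               seed = 1L) {
  ln <- lognorm_or_stop(m)
  if (n_modules < 2) stop("n_modules must be at least 2", call. = FALSE)
  t <- if (inherits(pt, "pseudotime_result")) {
    stats::setNames(pt$cells$t, pt$cells$cell_id)
  } else pt
  common <- intersect(colnames(ln), names(t))
  if (length(common) < 10) stop("too few cells with pseudotime",
                                call. = FALSE)
  ln <- as.matrix(ln[, common, drop = FALSE])
  t <- t[common]
  if (is.null(genes)) genes <- rownames(ln)
  missing <- setdiff(genes, rownames(ln))
  if (length(missing)) {
    stop("genes not in matrix: ", paste(utils::head(missing, 5),
                                        collapse = ", "), call. = FALSE)
  }
  grid <- seq(min(t), max(t), length.out = 100)
  profs <- matrix(NA_real_, length(genes), 100,
                  dimnames = list(genes, NULL))
  for (g in genes) {
    y <- ln[g, ]
    if (stats::var(y) == 0) next
    fit <- stats::smooth.spline(t, y, df = min(6, length(unique(t)) - 1))
    prof <- stats::predict(fit, grid)$y
    if (stats::sd(prof) == 0) next
    profs[g, ] <- (prof - mean(prof)) / stats::sd(prof)
  }
  unassigned <- genes[!stats::complete.cases(profs)]
  profs <- profs[stats::complete.cases(profs), , drop = FALSE]
  if (nrow(profs) < n_modules) {
    stop("fewer profiled genes than modules", call. = FALSE)
  }
  km <- withr::with_seed(seed, {
    stats::kmeans(profs, centers = n_modules, nstart = 10,
                  iter.max = 100)
  })
  peak <- grid[apply(profs, 1, which.max)]
  mean_peak <- tapply(peak, km$cluster, mean)
  renumber <- match(seq_len(n_modules), order(mean_peak))
  assignment <- tibble::tibble(
    gene = rownames(profs),
    module = renumber[km$cluster],
    peak_position = unname(peak)
  )
  if (length(unassigned)) {
    message(length(unassigned), " constant gene(s) left unassigned")
  }
  structure(
    list(assignment = assignment, profiles = profs, grid = grid,
         unassigned = unassigned),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- table(x$assignment$module)
  cat(sprintf("<module_assignment> %d genes in %d modules (%s); %d unassigned\n",
              nrow(x$assignment), length(sizes),
              paste(sizes, collapse = "/"), length(x$unassigned)))
  invisible(x)
}

#' @exportS3Method
tidy.module_assignment <- function(x, ...) x$assignment

#' Genes belonging to the given modules
#'
#' @param modules A [pseudotime_modules()] result.
#' @param ids Module numbers.
#' @return Character vector of gene ids.
#' @export
module_genes <- function(modules, ids) {
  stopifnot(inherits(modules, "module_assignment"))
  modules$assignment$gene[modules$assignment$module %in% ids]
}
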