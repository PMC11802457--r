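#' Train the differentiation-score regression
#'
#' Reproduces the differentiation-score procedure on the whole neurogenic
#' lineage: (1) one-vs-rest markers between the lineage stages, keeping
#' the top `markers_per_class` per stage by fold change; (2) a
#' pseudo-differentiation target from a principal curve over the first
#' `n_pcs_curve` PCs, scaled to \[0, 1\] and oriented so the quiescent
#' stage (first element of `lineage_labels`) sits low; (3) a random
#' forest regression (`num_trees` trees, impurity importance) of the
#' target on the marker genes; (4) retention of the `rf_top_features`
#' most important features; (5) a refit on that core feature set, which
#' is the model used for prediction.
#'
#' @param m An [expression_matrix()] with a lognorm layer.
#' @param lineage_labels The three lineage stages in differentiation
#'   order (first = root); each needs at least 30 cells.
#' @param n_pcs_curve PCs under the principal curve.
#' @param markers_per_class Markers kept per stage before importance
#'   filtering.
#' @param rf_top_features Features kept in the refit; when fewer markers
#'   are available, all are kept with a warning.
#' @param num_trees Trees in each forest.
#' @param alpha,lfc_min Marker-table cutoffs, as in [rank_markers()].
#' @param seed Integer seed (forest and curve are deterministic given
#'   it).
#' @return Object of class `diff_score_model`: `features`, `rf` (the
#'   refitted ranger forest), `importance` (tibble over all markers),
#'   `train` (tibble `cell_id`, `cell_type`, `t`, `pred`), `meta`.
#' @export
train_differentiation_model <- function(m,
                                        lineage_labels = c("qNSC", "aNSPC",
                                                           "NB/IMN"),
                                        n_pcs_curve = 7,
                                        markers_per_class = 50,
                                        rf_top_features = 100,
                                        num_trees = 500,
                                        alpha = 0.05,
                                        lfc_min = 0.25,
                                        seed = 1L) {
  keep <- m$cell_meta$cell_type %in% lineage_labels
  counts_by <- table(m$cell_meta$cell_type[keep])
  absent <- setdiff(lineage_labels, names(counts_by))
  if (length(absent) || any(counts_by[lineage_labels] < 30)) {
    stop("each lineage stage needs at least 30 cells", call. = FALSE)
  }
  sub <- subset_cells(m, keep)
  markers <- rank_markers(sub, alpha = alpha, lfc_min = lfc_min)
  marker_genes <- markers |>
    dplyr::slice_max(.data$avg_log2fc, n = markers_per_class,
                     by = "group", with_ties = FALSE) |>
    dplyr::pull("gene") |>
    unique() |>
    sort()
  if (length(marker_genes) < 2) {
    stop("too few marker genes to train on", call. = FALSE)
  }
  pca <- compute_pca(sub, n_pcs = n_pcs_curve)
  root <- sub$cell_meta$cell_id[sub$cell_meta$cell_type ==
                                  lineage_labels[1]]
  pt <- fit_principal_curve(pca, n_pcs = n_pcs_curve, root_cells = root)
  target <- stats::setNames(pt$cells$t, pt$cells$cell_id)

  x <- feature_frame(sub, marker_genes)
  full <- ranger::ranger(x = x$df, y = target[rownames(x$df)],
                         num.trees = num_trees, importance = "impurity",
                         seed = seed)
  imp <- tibble::tibble(
    gene = x$genes[match(names(full$variable.importance), x$keys)],
    importance = unname(full$variable.importance)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  n_keep <- min(rf_top_features, nrow(imp))
  if (n_keep < rf_top_features) {
    warning("only ", n_keep, " marker genes available; keeping all of them")
  }
  features <- sort(imp$gene[seq_len(n_keep)])
  x2 <- feature_frame(sub, features)
  refit <- ranger::ranger(x = x2$df, y = target[rownames(x2$df)],
                          num.trees = num_trees, importance = "impurity",
                          seed = seed)
  train_pred <- stats::predict(refit, data = x2$df)$predictions
  structure(
    list(
      features = features, rf = refit, importance = imp,
      train = tibble::tibble(
        cell_id = rownames(x2$df),
        cell_type = sub$cell_meta$cell_type,
        t = unname(target[rownames(x2$df)]),
        pred = unname(train_pred)
      ),
      meta = list(seed = seed, num_trees = num_trees,
                  n_pcs_curve = n_pcs_curve,
                  marker_hash = rlang::hash(markers),
                  lineage_labels = lineage_labels,
                  flipped = pt$flipped)
    ),
    class = "diff_score_model"
  )
}

#' Subset an expression container to selected cells
#'
#' @param m An [expression_matrix()].
#' @param keep Cell ids, or a logical/integer index over columns.
#' @return The container restricted to those cells (layers and metadata
#'   stay aligned).
#' @export
subset_cells <- function(m, keep) {
  if (is.character(keep)) {
    keep <- match(keep, cell_ids(m))
    if (anyNA(keep)) stop("unknown cell ids", call. = FALSE)
  }
  sub <- m
  sub$counts <- m$counts[, keep, drop = FALSE]
  if (!is.null(m$lognorm)) sub$lognorm <- m$lognorm[, keep, drop = FALSE]
  sub$cell_meta <- m$cell_meta[keep, , drop = FALSE]
  sub
}

feature_frame <- function(m, genes) {
  mat <- t(as.matrix(m$lognorm[genes, , drop = FALSE]))
  keys <- make.names(genes, unique = TRUE)
  df <- as.data.frame(mat)
  names(df) <- keys
  rownames(df) <- colnames(m$lognorm)
  list(df = df, genes = genes, keys = keys)
}

#' @export
print.diff_score_model <- function(x, ...) {
  cat(sprintf("<diff_score_model> %d core features, %d trees, train R^2 %.3f\n",
              length(x$features), x$rf$num.trees, x$rf$r.squared))
  invisible(x)
}

#' @exportS3Method
tidy.diff_score_model <- function(x, ...) x$importance

#' @exportS3Method
glance.diff_score_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features), num_trees = x$rf$num.trees,
    r_squared = x$rf$r.squared, oob_mse = x$rf$prediction.error
  )
}

#' Predict differentiation scores for query cells
#'
#' @param model A [train_differentiation_model()] fit.
#' @param m An [expression_matrix()] with a lognorm layer containing all
#'   model features (missing features are an error).
#' @param cells Optional cell ids to restrict to.
#' @return Tibble `cell_id`, `cell_type`, `age`, `score`.
#' @export
predict_differentiation <- function(model, m, cells = NULL) {
  stopifnot(inherits(model, "diff_score_model"))
  missing <- setdiff(model$features, rownames(m$lognorm))
  if (length(missing)) {
    stop("model features absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(cells)) cells <- cell_ids(m)
  sub <- subset_cells(m, match(cells, cell_ids(m)))
  x <- feature_frame(sub, model$features)
  pred <- stats::predict(model$rf, data = x$df)$predictions
  tibble::tibble(
    cell_id = cells,
    cell_type = sub$cell_meta$cell_type,
    age = sub$cell_meta$age,
    score = unname(pred)
  )
}

#' Train the elastic-net multinomial age classifier
#'
#' Highly variable genes are selected, a class-balanced training set is
#' drawn (`train_frac` of the least-populated age class, the same count
#' from every other class), and a multinomial elastic net is tuned by
#' `cv_folds`-fold cross-validated misclassification over a grid of
#' mixing values and 20 log-spaced penalties per mixing value. The best
#' pair is refit and evaluated on the held-out cells.
#'
#' @param m An [expression_matrix()] with a lognorm layer and all three
#'   ages in `cell_meta$age`; every class needs at least 10 cells.
#' @param n_hvg Variable genes used as predictors.
#' @param train_frac Training fraction of the least-populated class.
#' @param cv_folds Cross-validation folds.
#' @param alphas Elastic-net mixing values searched.
#' @param seed Integer seed (split and fold assignment).
#' @return Object of class `age_classifier`: `fit` (the selected
#'   `cv.glmnet`), `alpha`, `lambda`, `hvgs`, `train_ids`, `test_ids`,
#'   `confusion` (tibble `age`, `predicted`, `n`), `accuracy`, `seed`.
#' @export
train_age_classifier <- function(m, n_hvg = 5000, train_frac = 0.7,
                                 cv_folds = 10,
                                 alphas = c(0.1, 0.5, 0.9),
                                 seed = 1L) {
  ages <- m$cell_meta$age
  if (anyNA(ages) || length(setdiff(age_levels(), as.character(ages)))) {
    stop("all three age groups must be present", call. = FALSE)
  }
  sizes <- table(as.character(ages))
  if (any(sizes < 10)) {
    stop("age class(es) with fewer than 10 cells: ",
         paste(names(sizes)[sizes < 10], collapse = ", "), call. = FALSE)
  }
  hvgs <- select_hvgs(m, n_hvg)
  n_train <- floor(train_frac * min(sizes))
  ids_by_class <- split(m$cell_meta$cell_id, as.character(ages))
  train_ids <- withr::with_seed(seed, {
    sort(unlist(lapply(ids_by_class, function(ids) {
      sample(sort(ids), n_train)
    }), use.names = FALSE))
  })
  test_ids <- setdiff(m$cell_meta$cell_id, train_ids)
  x_all <- t(as.matrix(m$lognorm[hvgs, , drop = FALSE]))
  y_all <- stats::setNames(age_factor(ages), m$cell_meta$cell_id)
  foldid <- withr::with_seed(seed + 1L, {
    sample(rep(seq_len(cv_folds), length.out = length(train_ids)))
  })
  fits <- lapply(alphas, function(a) {
    glmnet::cv.glmnet(
      x_all[train_ids, , drop = FALSE], y_all[train_ids],
      family = "multinomial", alpha = a, nlambda = 20,
      foldid = foldid, type.measure = "class"
    )
  })
  best_cv <- vapply(fits, function(f) min(f$cvm), 0)
  pick <- which.min(best_cv)
  fit <- fits[[pick]]
  pred <- as.character(stats::predict(fit, x_all[test_ids, , drop = FALSE],
                                      s = "lambda.min", type = "class"))
  confusion <- tibble::tibble(age = as.character(y_all[test_ids]),
                              predicted = pred) |>
    dplyr::count(.data$age, .data$predicted, name = "n")
  structure(
    list(
      fit = fit, alpha = alphas[pick], lambda = fit$lambda.min,
      hvgs = hvgs, train_ids = train_ids, test_ids = test_ids,
      confusion = confusion,
      accuracy = mean(pred == as.character(y_all[test_ids])),
      seed = seed
    ),
    class = "age_classifier"
  )
}

#' @export
print.age_classifier <- function(x, ...) {
  cat(sprintf(
    "<age_classifier> alpha = %.2f, lambda = %.4g, held-out accuracy %.3f (%d train / %d test cells)\n",
    x$alpha, x$lambda, x$accuracy, length(x$train_ids), length(x$test_ids)
  ))
  invisible(x)
}

#' @exportS3Method
tidy.age_classifier <- function(x, ...) x$confusion

#' @exportS3Method
glance.age_classifier <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, alpha = x$alpha, lambda = x$lambda,
    n_train = length(x$train_ids), n_test = length(x$test_ids),
    n_features = length(x$hvgs)
  )
}

#' Predict ages for query cells
#'
#' @param object An [train_age_classifier()] fit.
#' @param m An [expression_matrix()] with a lognorm layer.
#' @param cells Optional cell ids (default: all).
#' @param ... Unused.
#' @return Tibble `cell_id`, `predicted_age`.
#' @export
predict.age_classifier <- function(object, m, cells = NULL, ...) {
  if (is.null(cells)) cells <- cell_ids(m)
  x <- t(as.matrix(m$lognorm[object$hvgs, cells, drop = FALSE]))
  pred <- as.character(stats::predict(object$fit, x, s = "lambda.min",
                                      type = "class"))
  tibble::tibble(cell_id = cells, predicted_age = pred)
}
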