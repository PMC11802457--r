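fake_pca <- function(scores) {
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  if (is.null(rownames(scores))) {
    rownames(scores) <- sprintf("c%03d", seq_len(nrow(scores)))
  }
  structure(list(scores = scores,
                 loadings = diag(ncol(scores)),
                 var_explained = rep(1 / ncol(scores), ncol(scores)),
                 sdev = rep(1, ncol(scores))),
            class = "pca_result")
}

test_that("PCA recovers rank structure and reconstructs the data", {
  withr::local_seed(31)
  # rank-one lognorm layer: one axis carries all the variance
  m <- null_expression(n_genes = 25, n_cells = 40, seed = 31)
  m$lognorm <- outer(abs(stats::rnorm(25)) + 0.5, stats::runif(40, 1, 3))
  dimnames(m$lognorm) <- dimnames(m$counts)
  p <- compute_pca(m, n_pcs = 5)
  expect_gt(p$var_explained[1], 0.999)

  m2 <- null_expression(n_genes = 40, n_cells = 25, seed = 32)
  n_pcs <- 24
  p2 <- compute_pca(m2, n_pcs = n_pcs)
  # loadings orthonormal, variances non-increasing
  expect_equal(crossprod(p2$loadings), diag(n_pcs), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_false(is.unsorted(rev(p2$var_explained)))
  # full reconstruction of the scaled data
  ln <- as.matrix(m2$lognorm)
  sds <- apply(ln, 1, stats::sd)
  scaled <- (ln - rowMeans(ln)) / sds
  recon <- p2$scores %*% t(p2$loadings)
  expect_equal(unname(recon), unname(t(scaled)), tolerance = 1e-6)
  expect_error(compute_pca(m2, n_pcs = 30), "exceeds")
})

test_that("PCA agrees with a dense eigendecomposition oracle", {
  m <- null_expression(n_genes = 30, n_cells = 40, seed = 33)
  p <- compute_pca(m, n_pcs = 6)
  ln <- as.matrix(m$lognorm)
  scaled <- (ln - rowMeans(ln)) / apply(ln, 1, stats::sd)
  eig <- eigen(stats::cov(t(scaled)))
  ev <- eig$values / sum(eig$values)
  expect_equal(p$var_explained, ev[1:6], tolerance = 1e-8)
  for (k in 1:6) {
    expect_equal(abs(sum(p$loadings[, k] * eig$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
})

test_that("a line is its own principal curve, recovered exactly", {
  withr::local_seed(34)
  pos <- sort(stats::runif(40, -3, 5))
  dirn <- c(2, 1, -1) / sqrt(6)
  scores <- outer(pos, dirn)
  pt <- fit_principal_curve(fake_pca(scores), n_pcs = 3)
  expected <- (pos - min(pos)) / diff(range(pos))
  err <- min(max(abs(pt$cells$t - expected)),
             max(abs((1 - pt$cells$t) - expected)))
  expect_lt(err, 1e-6)
  expect_lt(max(pt$cells$proj_dist), 1e-8)
})

test_that("pseudotime tracks the latent coordinate on a noisy arc", {
  withr::local_seed(35)
  n <- 500
  lat <- stats::runif(n)
  extent <- 10
  x <- extent * lat
  y <- extent * (lat - 0.5)^2 * 2
  sigma <- 0.05 * extent
  scores <- cbind(x + stats::rnorm(n, 0, sigma),
                  y + stats::rnorm(n, 0, sigma),
                  stats::rnorm(n, 0, sigma))
  pt <- fit_principal_curve(fake_pca(scores), n_pcs = 3)
  expect_gte(abs(stats::cor(pt$cells$t, lat, method = "spearman")), 0.95)
  expect_true(all(diff(pt$mse_trace) < 0))
})

test_that("pseudotime orders the simulated lineage and respects the root", {
  sim <- small_atlas(seed = 36, n = 80)
  m <- log_normalize(sim$matrix)
  pca <- compute_pca(m, n_pcs = 7)
  root <- sim$truth_cells$cell_id[sim$truth_cells$cell_type == "qNSC"]
  pt <- fit_principal_curve(pca, n_pcs = 7, root_cells = root)
  by_type <- tapply(
    stats::setNames(pt$cells$t, pt$cells$cell_id)[sim$truth_cells$cell_id],
    sim$truth_cells$cell_type, mean
  )
  expect_lt(by_type[["qNSC"]], by_type[["aNSPC"]])
  expect_lt(by_type[["aNSPC"]], by_type[["NB/IMN"]])
})

test_that("pseudotime is invariant to cell permutation (up to flip)", {
  m <- null_expression(n_genes = 40, n_cells = 60, seed = 37)
  pca <- compute_pca(m, n_pcs = 4)
  pt1 <- fit_principal_curve(pca, n_pcs = 4)
  perm <- withr::with_seed(38, sample(nrow(pca$scores)))
  pca2 <- pca
  pca2$scores <- pca$scores[perm, ]
  pt2 <- fit_principal_curve(pca2, n_pcs = 4)
  t1 <- stats::setNames(pt1$cells$t, pt1$cells$cell_id)
  t2 <- stats::setNames(pt2$cells$t, pt2$cells$cell_id)[names(t1)]
  expect_lt(min(max(abs(t1 - t2)), max(abs(t1 - (1 - t2)))), 1e-8)
})

test_that("degenerate inputs are rejected", {
  scores <- matrix(1, 20, 3)
  expect_error(fit_principal_curve(fake_pca(scores), n_pcs = 3),
               "degenerate|identical")
})

test_that("pseudotime modules recover planted logistic blocks", {
  withr::local_seed(39)
  n <- 300
  t_true <- stats::runif(n)
  act <- function(mid) stats::plogis((t_true - mid) / 0.05)
  make_block <- function(midpoint, n_genes) {
    t(vapply(seq_len(n_genes), function(i) {
      mu <- 5 + 20 * act(midpoint)
      stats::rpois(n, mu)
    }, numeric(n)))
  }
  counts <- rbind(make_block(0.25, 30), make_block(0.75, 30))
  rownames(counts) <- c(sprintf("early%02d", 1:30),
                        sprintf("late%02d", 1:30))
  m <- toy_expression(counts)
  pt <- stats::setNames(t_true, colnames(m$counts))
  mod <- pseudotime_modules(m, pt, n_modules = 2, seed = 3)
  block <- ifelse(grepl("early", mod$assignment$gene), "early", "late")
  tab <- table(block, mod$assignment$module)
  purity <- (max(tab["early", ]) + max(tab["late", ])) / sum(tab)
  expect_gte(purity, 0.95)
  # modules numbered by peak position: early block must be module 1
  expect_equal(unname(which.max(tab["early", ])), 1L)
})

test_that("monotone genes land in the last module; constants are unassigned", {
  withr::local_seed(40)
  n <- 120
  t_true <- sort(stats::runif(n))
  counts <- rbind(
    t(vapply(1:10, function(i) stats::rpois(n, 4 + 30 * t_true),
             numeric(n))),
    t(vapply(1:10, function(i) stats::rpois(n, 4 + 30 * (1 - t_true)),
             numeric(n))),
    matrix(7, 3, n)
  )
  rownames(counts) <- c(sprintf("up%02d", 1:10), sprintf("down%02d", 1:10),
                        sprintf("const%02d", 1:3))
  m <- toy_expression(counts)
  # make the constant genes flat on the normalized layer too
  m$lognorm[sprintf("const%02d", 1:3), ] <- 1.5
  pt <- stats::setNames(t_true, colnames(m$counts))
  expect_message(
    mod <- pseudotime_modules(m, pt, n_modules = 2, seed = 4),
    "unassigned"
  )
  expect_setequal(mod$unassigned, sprintf("const%02d", 1:3))
  up_modules <- mod$assignment$module[grepl("up", mod$assignment$gene)]
  expect_true(all(up_modules == max(mod$assignment$module)))
  expect_error(pseudotime_modules(m, pt, n_modules = 1), "at least 2")
})
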