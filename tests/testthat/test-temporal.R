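make_trend_sets <- function(up = character(), down = character()) {
  structure(
    list(up_genes = up, down_genes = down,
         cluster_direction = c(cluster_1 = "up", cluster_2 = "down"),
         gene_info = tibble::tibble(
           gene = c(up, down),
           cluster = rep(c("cluster_1", "cluster_2"),
                         c(length(up), length(down))),
           membership = 1,
           direction = rep(c("up", "down"), c(length(up), length(down)))
         )),
    class = "trend_sets"
  )
}

test_that("age profiles standardize to the textbook z-scores", {
  withr::local_seed(41)
  # three age groups of cells whose lognorm means are exactly 1/2/3
  counts <- matrix(stats::rpois(5 * 90, 6), 5, 90)
  m <- toy_expression(counts, ages = rep(age_levels(), each = 30))
  m$lognorm <- rbind(
    matrix(rep(c(1, 2, 3), each = 30), 1, byrow = FALSE),
    matrix(rep(c(3, 2, 1), each = 30), 1),
    matrix(2, 1, 90),
    as.matrix(m$lognorm[4:5, ])
  )
  dimnames(m$lognorm) <- dimnames(m$counts)
  ap <- age_profiles(m)
  expect_equal(unname(ap$profiles["g001", ]),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(unname(ap$profiles["g002", ]),
               c(1.224745, 0, -1.224745), tolerance = 1e-6)
  # sample-sd convention on request
  ap_s <- age_profiles(m, sd_type = "sample")
  expect_equal(unname(ap_s$profiles["g001", ]), c(-1, 0, 1),
               tolerance = 1e-6)
  # the constant gene is flagged and excluded; rows centred at 0
  expect_true("g003" %in% ap$excluded$gene)
  expect_lt(max(abs(rowMeans(ap$profiles))), 1e-10)
})

test_that("a missing age group is an error naming it", {
  m <- null_expression(n_genes = 20, n_cells = 30, seed = 42)
  m$cell_meta$age <- age_factor(rep(c("young", "old"), 15))
  expect_error(age_profiles(m), "middle")
})

test_that("equidistant profiles get uniform membership", {
  # all profiles identical: centres coincide, membership exactly 1/c
  x <- matrix(rep(c(0.5, -1, 0.5), each = 12), 12, 3)
  expect_warning(same <- fuzzy_cmeans(x, c = 4, seed = 1), "distinct|evenly")
  expect_equal(unname(same$membership), matrix(0.25, 12, 4))
  expect_error(fuzzy_cmeans(x[1:2, ], c = 4), "at least c")
  # symmetric two-group data with one profile at the midpoint: the
  # midpoint profile is equidistant from both centres, membership 1/c
  withr::local_seed(48)
  grp <- matrix(rep(c(-1, 0, 1), each = 15), 15, 3) +
    matrix(stats::rnorm(45, 0, 0.01), 15, 3)
  x <- rbind(grp, -grp, 0)
  fit <- fuzzy_cmeans(x, c = 2, seed = 1)
  expect_true(all(abs(fit$membership[31, ] - 0.5) < 0.05))
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-8))
})

test_that("fuzzy c-means separates planted profile groups crisply", {
  withr::local_seed(43)
  z <- 1.224745
  up <- matrix(rep(c(-z, 0, z), each = 20), 20, 3) +
    matrix(stats::rnorm(60, 0, 0.02), 20, 3)
  down <- -up
  rownames(up) <- sprintf("up%02d", 1:20)
  rownames(down) <- sprintf("dn%02d", 1:20)
  fit <- fuzzy_cmeans(rbind(up, down), c = 2, m_fuzzifier = 1.25,
                      seed = 5)
  best <- apply(fit$membership, 1, max)
  expect_true(all(best > 0.9))
  grp <- apply(fit$membership, 1, which.max)
  expect_equal(length(unique(grp[1:20])), 1)
  expect_equal(length(unique(grp[21:40])), 1)
  expect_false(grp[1] == grp[21])
  expect_true(all(diff(fit$objective) <= 1e-9))
})

test_that("the objective trace is non-increasing on random inputs", {
  for (s in 1:5) {
    x <- withr::with_seed(s, matrix(stats::rnorm(70 * 3), 70, 3))
    fit <- fuzzy_cmeans(x, c = 6, seed = s)
    expect_true(all(diff(fit$objective) <= 1e-9))
    expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-8))
  }
})

test_that("near-crisp fuzzifier reproduces k-means on separated groups", {
  withr::local_seed(44)
  a <- matrix(stats::rnorm(45, 0, 0.05), 15, 3) +
    matrix(rep(c(-1, 0, 1), each = 15), 15, 3)
  b <- matrix(stats::rnorm(45, 0, 0.05), 15, 3) +
    matrix(rep(c(1, 0, -1), each = 15), 15, 3)
  x <- rbind(a, b)
  fit <- fuzzy_cmeans(x, c = 2, m_fuzzifier = 1.01, seed = 6)
  soft <- apply(fit$membership, 1, which.max)
  hard <- withr::with_seed(6, stats::kmeans(x, 2, nstart = 5))$cluster
  agree <- max(mean(soft == hard), mean(soft == (3 - hard)))
  expect_equal(agree, 1)
})

test_that("fuzzy memberships agree with an independent implementation", {
  withr::local_seed(45)
  x <- rbind(
    matrix(stats::rnorm(60, 0, 0.1), 20, 3) +
      matrix(rep(c(-1, 0, 1), each = 20), 20, 3),
    matrix(stats::rnorm(60, 0, 0.1), 20, 3) +
      matrix(rep(c(1, 0, -1), each = 20), 20, 3)
  )
  fit <- fuzzy_cmeans(x, c = 2, m_fuzzifier = 1.5, seed = 7)
  ref <- withr::with_seed(7, e1071::cmeans(x, 2, m = 1.5))
  # match clusters by centre proximity, then compare memberships
  d <- as.matrix(stats::dist(rbind(fit$centers, ref$centers)))[1:2, 3:4]
  map <- apply(d, 1, which.min)
  expect_false(map[1] == map[2])
  expect_lt(max(abs(fit$membership - ref$membership[, map])), 0.02)
})

test_that("trend direction follows strict monotonicity of centres", {
  fit <- structure(
    list(
      centers = rbind(c(-1.1, 0, 1.1), c(-1, 1, 0), c(1, 0.5, -0.2)),
      membership = matrix(c(0.95, 0.03, 0.02,
                            0.2, 0.55, 0.25,
                            0.1, 0.45, 0.45,
                            0.05, 0.05, 0.9), 4, 3, byrow = TRUE,
                          dimnames = list(paste0("g", 1:4), NULL)),
      fuzzifier = 1.25, objective = 1, iterations = 1
    ),
    class = "fuzzy_clustering"
  )
  dimnames(fit$centers) <- list(paste0("cluster_", 1:3), age_levels())
  colnames(fit$membership) <- rownames(fit$centers)
  ts <- monotone_trend_sets(fit, membership_threshold = 0.5)
  expect_identical(unname(ts$cluster_direction),
                   c("up", "flat", "down"))
  expect_identical(ts$up_genes, "g1")     # high membership in up cluster
  expect_identical(ts$down_genes, "g4")   # high membership in down cluster
  # g2 sits in a flat cluster, g3 is below the membership threshold
  expect_false(any(c("g2", "g3") %in% c(ts$up_genes, ts$down_genes)))
})

test_that("planted age trends are recovered from the simulated atlas", {
  sim <- simulate_lineage_atlas(n_per_group = 200, cell_types = "qNSC",
                                n_genes = 400, n_markers = 10,
                                n_module_genes = 20, n_aging = 40,
                                delta = 0.5, seed = 46)
  m <- log_normalize(sim$matrix)
  ts <- monotone_trend_sets(fuzzy_cmeans(age_profiles(m), c = 8, seed = 2))
  tg <- sim$truth_genes
  up <- tg$gene_id[tg$block == "aging_up"]
  down <- tg$gene_id[tg$block == "aging_down"]
  null_g <- tg$gene_id[tg$block == "null"]
  expect_gte(mean(up %in% ts$up_genes), 0.9)
  expect_gte(mean(down %in% ts$down_genes), 0.9)
  expect_lte(mean(null_g %in% c(ts$up_genes, ts$down_genes)), 0.05)
})

test_that("NAS is the intersection of real-time trends and modules", {
  realtime <- make_trend_sets(up = c("A", "B"), down = c("X", "Y", "Z"))
  modules <- structure(
    list(assignment = tibble::tibble(
      gene = c("B", "C", "X", "Q", "Z"),
      module = c(1L, 1L, 3L, 2L, 4L),
      peak_position = c(0.1, 0.15, 0.8, 0.5, 0.9)
    ), profiles = NULL, grid = seq(0, 1, length.out = 100),
    unassigned = character()),
    class = "module_assignment"
  )
  nas <- build_nas(realtime, modules)
  expect_identical(nas$up, "B")
  expect_setequal(nas$down, c("X", "Z"))
  expect_true(all(nzchar(nas$provenance$source)))

  empty <- make_trend_sets(up = "nope", down = "nada")
  expect_warning(nas0 <- build_nas(empty, modules), "empty")
  expect_length(nas0$up, 0)
  expect_length(nas0$down, 0)
})

test_that("CAS matches exhaustive enumeration and shrinks with min_shared", {
  withr::local_seed(47)
  genes <- paste0("g", 1:10)
  pops <- paste0("pop", 1:4)
  trends <- lapply(stats::setNames(pops, pops), function(p) {
    ord <- sample(genes)
    make_trend_sets(up = ord[1:4], down = ord[5:7])
  })
  ord <- sample(genes)
  st <- make_trend_sets(up = ord[1:5], down = ord[6:9])
  cas <- build_cas(trends, st, min_shared = 2)
  # exhaustive oracle over all genes and populations
  for (g in genes) {
    n_up <- sum(vapply(trends, function(tr) g %in% tr$up_genes, TRUE))
    expect_equal(g %in% cas$up, g %in% st$up_genes && n_up >= 2)
    n_dn <- sum(vapply(trends, function(tr) g %in% tr$down_genes, TRUE))
    expect_equal(g %in% cas$down, g %in% st$down_genes && n_dn >= 2)
  }
  # containment as the sharing requirement tightens
  sizes <- vapply(1:4, function(k) {
    ck <- build_cas(trends, st, min_shared = k)
    length(ck$up) + length(ck$down)
  }, 0L)
  expect_false(is.unsorted(rev(sizes)))
  for (k in 2:4) {
    expect_true(all(build_cas(trends, st, k)$up %in%
                      build_cas(trends, st, k - 1)$up))
  }
  expect_error(build_cas(trends, st, min_shared = 5), "exceeds")
})

test_that("boundary sharing: exactly min_shared populations suffice", {
  trends <- list(
    p1 = make_trend_sets(up = "shared2"),
    p2 = make_trend_sets(up = "shared2"),
    p3 = make_trend_sets(up = "shared1"),
    p4 = make_trend_sets()
  )
  st <- make_trend_sets(up = c("shared2", "shared1", "st_only"))
  cas <- build_cas(trends, st, min_shared = 2)
  expect_identical(cas$up, "shared2")
  expect_identical(cas$provenance$source[cas$provenance$gene == "shared2"],
                   "p1;p2")
})

test_that("signature pairs round-trip through GMT", {
  sig <- structure(list(name = "NAS", up = c("A", "B"), down = "C",
                        provenance = tibble::tibble(
                          gene = c("A", "B", "C"),
                          direction = c("up", "up", "down"),
                          source = "x")),
                   class = "signature_pair")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_signature_gmt(sig, path)
  sets <- read_gene_sets(path)
  expect_identical(sets$NAS_UP, c("A", "B"))
  expect_identical(sets$NAS_DOWN, "C")
})

test_that("end-to-end NAS recovers planted aging programs from the atlas", {
  sim <- simulate_lineage_atlas(n_per_group = 200, cell_types = "qNSC",
                                delta = 0.5, seed = 101)
  m <- log_normalize(sim$matrix)
  ts <- monotone_trend_sets(fuzzy_cmeans(age_profiles(m), c = 8,
                                         seed = 101))
  pca <- compute_pca(m, n_pcs = 7)
  root <- sim$truth_cells$cell_id[order(sim$truth_cells$latent_t)][1:100]
  pt <- fit_principal_curve(pca, n_pcs = 7, root_cells = root)
  tg <- sim$truth_genes
  dyn <- tg$gene_id[grepl("aging|module", tg$block)]
  mod <- pseudotime_modules(m, pt, n_modules = 4, genes = dyn, seed = 101)
  # this simulation plants six dynamic programs into four modules, so
  # the quiescence program may span the two earliest ones; intersect
  # with the early/late module unions
  nas <- build_nas(ts, mod, up_module_ids = 1:2, down_module_ids = 3:4)
  up <- tg$gene_id[tg$block == "aging_up"]
  down <- tg$gene_id[tg$block == "aging_down"]
  expect_gte(mean(up %in% nas$up), 0.9)
  expect_gte(mean(down %in% nas$down), 0.9)
  expect_length(intersect(nas$up, nas$down), 0)
  expect_false(any(tg$gene_id[tg$block == "null"] %in%
                     c(nas$up, nas$down)))
  # the default mapping always yields subsets of the real-time trends
  nas_def <- build_nas(ts, mod)
  expect_true(all(nas_def$up %in% ts$up_genes))
  expect_true(all(nas_def$down %in% ts$down_genes))
})

test_that("CAS module scores separate the age groups in both directions", {
  sim <- simulate_lineage_atlas(n_per_group = 200, cell_types = "qNSC",
                                delta = 0.5, seed = 105)
  m <- log_normalize(sim$matrix)
  ts <- monotone_trend_sets(fuzzy_cmeans(age_profiles(m), c = 8,
                                         seed = 105))
  sim2 <- simulate_lineage_atlas(n_per_group = 200,
                                 cell_types = "astrocyte", delta = 0.5,
                                 seed = 106)
  ts2 <- monotone_trend_sets(
    fuzzy_cmeans(age_profiles(log_normalize(sim2$matrix)), c = 8,
                 seed = 106)
  )
  cas <- build_cas(list(qNSC = ts, astrocyte = ts2), ts, min_shared = 2)
  expect_gt(length(cas$up), 0)
  expect_gt(length(cas$down), 0)
  score_by_age <- function(genes, name) {
    sc <- module_score(m, genes, seed = 1, set_name = name)
    tapply(sc$score, as.character(m$cell_meta$age), mean)[age_levels()]
  }
  up_means <- score_by_age(cas$up, "cas_up")
  down_means <- score_by_age(cas$down, "cas_down")
  expect_true(all(diff(up_means) > 0))
  expect_true(all(diff(down_means) < 0))
})
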