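full_lattice <- function(n_rows = 9, n_cols = 9, seed = 61) {
  simulate_spot_grid(n_rows = n_rows, n_cols = n_cols, seed = seed,
                     n_genes = 40, n_inflammatory = 10, amplitude = 0)
}

test_that("inflammatory calls use a strict threshold", {
  scores <- tibble::tibble(cell_id = c("s1", "s2", "s3", "s4"),
                           set = "ifng",
                           score = c(-0.2, 0, 1e-9, 0.4))
  calls <- call_inflammatory_spots(scores)
  expect_identical(calls$is_inflammatory, c(FALSE, FALSE, TRUE, TRUE))
  none <- call_inflammatory_spots(
    tibble::tibble(cell_id = "s1", set = "ifng", score = -1))
  expect_false(any(none$is_inflammatory))
})

test_that("hex adjacency yields six neighbours inside, symmetric always", {
  grid <- full_lattice()$grid
  adj <- hex_adjacency(grid)
  sp <- grid$spots
  interior <- sp$spot_id[sp$array_row == 4 & sp$array_col == 8]
  expect_length(adj[[interior]], 6)
  # explicit enumeration of the offset rule around (4, 8)
  expected <- sp$spot_id[paste(sp$array_row, sp$array_col) %in%
                           c("4 6", "4 10", "3 7", "3 9", "5 7", "5 9")]
  expect_setequal(adj[[interior]], expected)
  for (id in names(adj)) {
    for (nb in adj[[id]]) expect_true(id %in% adj[[nb]])
  }
  # isolated spot
  lone <- spot_grid(
    matrix(1, 1, 1, dimnames = list("g1", "s1")),
    tibble::tibble(spot_id = "s1", array_row = 0L, array_col = 0L,
                   pxl_row = 0, pxl_col = 0)
  )
  expect_length(hex_adjacency(lone)[["s1"]], 0)
})

test_that("a single interior IS grows 6/12/18 rings matching a BFS oracle", {
  sim <- full_lattice(11, 11)
  grid <- sim$grid
  centre <- grid$spots$spot_id[grid$spots$array_row == 5 &
                                 grid$spots$array_col == 11]
  is_mask <- stats::setNames(grid$spots$spot_id == centre,
                             grid$spots$spot_id)
  h <- build_spot_hierarchy(is_mask, hex_adjacency(grid))
  counts <- table(h$class)
  expect_equal(unname(counts[c("IS", "NNS", "ENS1", "ENS2")]),
               c(1L, 6L, 12L, 18L), ignore_attr = TRUE)
  # independent pixel-distance BFS oracle
  oracle <- oracle_rings(grid$spots, centre)
  got <- stats::setNames(as.character(h$class), h$spot_id)
  expect_identical(got[names(oracle)], oracle)
  # classes partition the masked spots
  expect_equal(sum(counts), nrow(grid$spots))
})

test_that("ring semantics: shared neighbours, empty IS, idempotence", {
  sim <- full_lattice()
  grid <- sim$grid
  adj <- hex_adjacency(grid)
  sp <- grid$spots
  two <- sp$spot_id[(sp$array_row == 4 & sp$array_col == 8) |
                      (sp$array_row == 4 & sp$array_col == 10)]
  is_mask <- stats::setNames(sp$spot_id %in% two, sp$spot_id)
  h <- build_spot_hierarchy(is_mask, adj)
  # two adjacent IS share neighbours, each counted once as NNS
  expect_equal(sum(h$class == "NNS"),
               length(setdiff(unique(unlist(adj[two])), two)))
  expect_equal(anyDuplicated(h$spot_id), 0)

  expect_warning(h0 <- build_spot_hierarchy(
    stats::setNames(rep(FALSE, nrow(sp)), sp$spot_id), adj), "no inflammatory")
  expect_true(all(h0$class == "other"))

  # spot order must not matter
  perm <- withr::with_seed(62, sample(nrow(sp)))
  h2 <- build_spot_hierarchy(is_mask[perm], adj[perm])
  joined <- dplyr::inner_join(tibble::as_tibble(h),
                              tibble::as_tibble(h2), by = "spot_id")
  expect_true(all(joined$class.x == joined$class.y))
})

test_that("region mask restricts the hierarchy and keeps the partition", {
  sim <- full_lattice()
  grid <- sim$grid
  adj <- hex_adjacency(grid)
  sp <- grid$spots
  mask <- sp$spot_id[sp$array_row <= 4]
  centre <- sp$spot_id[sp$array_row == 4 & sp$array_col == 8]
  is_mask <- stats::setNames(sp$spot_id == centre, sp$spot_id)
  h <- build_spot_hierarchy(is_mask, adj, region_mask = mask)
  expect_setequal(h$spot_id, mask)
  # rings cannot escape the mask: only 4 of 6 neighbours are masked
  expect_equal(sum(h$class == "NNS"), 4)
})

test_that("planted hotspots are recovered and graded by the hierarchy", {
  ss <- simulate_spot_grid(seed = 63, decay_um = 100,
                           hotspot_centers = list(c(2, 5), c(6, 14),
                                                  c(10, 4)))
  g <- log_normalize(ss$grid)
  sc <- module_score(as_expression_matrix(g), ss$inflammatory_genes,
                     seed = 1, set_name = "ifng")
  calls <- call_inflammatory_spots(sc)
  dist <- ss$truth$dist_to_hotspot_um[match(calls$spot_id,
                                            ss$truth$spot_id)]
  precision <- mean(dist[calls$is_inflammatory] <= 200)
  expect_gte(precision, 0.8)
  # score gradient decreases along the ring hierarchy
  h <- build_spot_hierarchy(calls, hex_adjacency(g))
  summ <- hierarchy_score_summary(h, sc)
  grad <- summ$mean_score[match(c("IS", "NNS", "ENS1", "ENS2"),
                                summ$class)]
  expect_true(all(diff(grad) < 0))
})

test_that("pseudo-spatial ordering runs inside-out with inner modules first", {
  ss <- simulate_spot_grid(seed = 64,
                           hotspot_centers = list(c(2, 5), c(9, 14)))
  g <- log_normalize(ss$grid)
  sc <- module_score(as_expression_matrix(g), ss$inflammatory_genes,
                     seed = 1, set_name = "ifng")
  h <- build_spot_hierarchy(call_inflammatory_spots(sc), hex_adjacency(g))
  ps <- suppressMessages(pseudospatial_modules(g, h, seed = 1))
  means <- ps$spots |>
    dplyr::summarise(s = mean(.data$s), .by = "class")
  ord <- means$s[match(c("IS", "NNS", "ENS1", "ENS2"), means$class)]
  expect_true(all(diff(ord) > 0))
  infl <- ps$modules$assignment$module[
    ps$modules$assignment$gene %in% ss$inflammatory_genes]
  expect_gte(mean(infl == 1), 0.9)
})

test_that("a featureless grid cannot produce a silent gradient", {
  flat <- matrix(5L, 30, 25,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("s%02d", 1:25)))
  spots <- tibble::tibble(
    spot_id = colnames(flat),
    array_row = rep(0:4, each = 5),
    array_col = as.integer(2 * (0:4)) + rep(0:4, each = 5) %% 2L,
    pxl_row = 0, pxl_col = 0
  )
  spots$array_col <- 2L * rep(0:4, 5) + rep(0:4, each = 5) %% 2L
  spots$pxl_col <- spots$array_col * 50
  spots$pxl_row <- spots$array_row * 87
  g <- log_normalize(spot_grid(flat, spots))
  h <- build_spot_hierarchy(
    stats::setNames(c(TRUE, rep(FALSE, 24)), spots$spot_id),
    hex_adjacency(g)
  )
  expect_error(suppressMessages(pseudospatial_modules(g, h, seed = 1)))
})
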