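#' Age-ordered expression profiles, row-standardized
#'
#' Computes the mean log-normalized expression per age group (optionally
#' within one cell population and on a gene subset), then z-scores each
#' gene across the three ordered ages. Because z-scoring rescales every
#' profile to the same magnitude, genes whose age variation is within
#' sampling noise of the group means would turn into spurious clean
#' trends; such rows are excluded before standardization — the analogue
#' of the low-variation filter customary before soft clustering of time
#' courses, made noise-aware. A gene is kept when its profile standard
#' deviation exceeds both an absolute floor (`min_profile_sd`) and
#' `noise_mult` times its estimated standard error of the age means
#' (`sqrt(mean_a(var_g within age a / n_a))`).
#'
#' @param m An [expression_matrix()] with a lognorm layer and ages in
#'   `cell_meta$age`.
#' @param population Optional cell type(s) to restrict to.
#' @param genes Optional gene subset (e.g. [select_hvgs()] output).
#' @param min_profile_sd Absolute floor on the profile standard
#'   deviation (lognorm units) before standardization.
#' @param noise_mult Multiple of the per-gene mean standard error the
#'   profile standard deviation must exceed.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1) standardization.
#' @return Object of class `age_profile_matrix`: `profiles` (gene x age
#'   z-matrix, columns young/middle/old), `excluded` (tibble `gene`,
#'   `profile_sd`, `noise_se`), `population`, `sd_type`.
#' @export
age_profiles <- function(m, population = NULL, genes = NULL,
                         min_profile_sd = 0.02, noise_mult = 2,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  keep <- rep(TRUE, ncol(m$counts))
  if (!is.null(population)) keep <- m$cell_meta$cell_type %in% population
  ages <- m$cell_meta$age[keep]
  missing <- setdiff(age_levels(), as.character(ages))
  if (length(missing)) {
    stop("missing age group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- m
  sub$counts <- m$counts[, keep, drop = FALSE]
  sub$lognorm <- m$lognorm[, keep, drop = FALSE]
  sub$cell_meta <- m$cell_meta[keep, , drop = FALSE]
  pb <- pseudobulk_by_group(sub, as.character(ages))
  pb <- t(pb[age_levels(), , drop = FALSE])  # gene x age
  # standard error of each age mean, averaged over ages
  se2 <- vapply(age_levels(), function(a) {
    cols <- as.character(ages) == a
    ln_a <- sub$lognorm[, cols, drop = FALSE]
    n_a <- sum(cols)
    mu_a <- Matrix::rowMeans(ln_a)
    v_a <- (Matrix::rowSums(ln_a^2) - n_a * mu_a^2) / max(n_a - 1, 1)
    pmax(v_a, 0) / n_a
  }, numeric(nrow(pb)))
  noise_se <- sqrt(rowMeans(se2))
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(pb))
    if (length(missing_g)) {
      stop("genes not in matrix: ",
           paste(utils::head(missing_g, 5), collapse = ", "), call. = FALSE)
    }
    noise_se <- noise_se[match(genes, rownames(pb))]
    pb <- pb[genes, , drop = FALSE]
  }
  mu <- rowMeans(pb)
  denom <- if (sd_type == "population") ncol(pb) else ncol(pb) - 1
  sds <- sqrt(rowSums((pb - mu)^2) / denom)
  low <- sds < pmax(min_profile_sd, noise_mult * noise_se)
  profiles <- (pb[!low, , drop = FALSE] - mu[!low]) / sds[!low]
  structure(
    list(
      profiles = profiles,
      excluded = tibble::tibble(gene = rownames(pb)[low],
                                profile_sd = unname(sds[low]),
                                noise_se = unname(noise_se[low])),
      population = if (is.null(population)) "all" else
        paste(population, collapse = "+"),
      sd_type = sd_type
    ),
    class = "age_profile_matrix"
  )
}

#' @export
print.age_profile_matrix <- function(x, ...) {
  cat(sprintf("<age_profile_matrix> %d genes x %d ages (%s; %d excluded)\n",
              nrow(x$profiles), ncol(x$profiles), x$population,
              nrow(x$excluded)))
  invisible(x)
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Minimizes `sum_ij u_ij^m ||x_i - c_j||^2` by the standard alternation:
#' memberships `u_ij = d_ij^(-2/(m-1)) / sum_k d_ik^(-2/(m-1))` given
#' centres, centres as `u^m`-weighted means given memberships. A profile
#' coinciding with a centre gets membership 1 there. Centres are
#' initialized by seeded k-means++. Convergence when the largest
#' membership change drops below `tol`; the per-iteration objective is
#' recorded and is non-increasing.
#'
#' @param profiles An [age_profiles()] result or a numeric matrix with
#'   one profile per row.
#' @param c Number of clusters (>= 2).
#' @param m_fuzzifier Fuzzifier m > 1 (1.25 gives fairly crisp
#'   memberships; larger values smear them).
#' @param seed Integer seed for the centre initialization.
#' @param tol Convergence tolerance on memberships.
#' @param max_iter Iteration cap.
#' @return Object of class `fuzzy_clustering`: `centers` (c x p),
#'   `membership` (n x c, rows sum to 1), `fuzzifier`, `objective`
#'   (trace), `iterations`.
#' @export
fuzzy_cmeans <- function(profiles, c = 8, m_fuzzifier = 1.25, seed = 1L,
                         tol = 1e-6, max_iter = 200) {
  x <- if (inherits(profiles, "age_profile_matrix")) profiles$profiles else
    as.matrix(profiles)
  if (c < 2) stop("c must be at least 2", call. = FALSE)
  if (m_fuzzifier <= 1) stop("fuzzifier must exceed 1", call. = FALSE)
  if (nrow(x) < c) {
    stop("need at least c = ", c, " profiles (have ", nrow(x), ")",
         call. = FALSE)
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct < c) {
    warning("only ", n_distinct, " distinct profiles for c = ", c,
            " clusters; centres will coincide and memberships split evenly")
  }
  centers <- withr::with_seed(seed, kmeanspp_init(x, c))
  expo <- 2 / (m_fuzzifier - 1)
  u_prev <- matrix(0, nrow(x), c)
  objective <- numeric()
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    u <- membership_from_dist(d2, expo)
    um <- u^m_fuzzifier
    centers <- (t(um) %*% x) / colSums(um)
    d2_new <- dist2_to_centers(x, centers)
    objective <- c(objective, sum(um * d2_new))
    if (max(abs(u - u_prev)) < tol) {
      u_prev <- u
      break
    }
    u_prev <- u
  }
  dimnames(centers) <- list(paste0("cluster_", seq_len(c)), colnames(x))
  dimnames(u_prev) <- list(rownames(x), rownames(centers))
  structure(
    list(centers = centers, membership = u_prev,
         fuzzifier = m_fuzzifier, objective = objective,
         iterations = length(objective)),
    class = "fuzzy_clustering"
  )
}

kmeanspp_init <- function(x, c) {
  n <- nrow(x)
  centers <- matrix(NA_real_, c, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  min_d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(c)[-1]) {
    prob <- if (sum(min_d2) > 0) min_d2 / sum(min_d2) else
      rep(1 / n, n)
    pick <- sample.int(n, 1, prob = prob)
    centers[j, ] <- x[pick, ]
    min_d2 <- pmin(min_d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

dist2_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  pmax(d2, 0)
}

# zero-distance ties split membership uniformly over the coinciding
# centres (a single exact hit therefore gets membership 1)
membership_from_dist <- function(d2, expo) {
  inv <- d2^(-expo / 2)
  zero <- d2 <= .Machine$double.eps
  u <- inv / rowSums(inv)
  hit <- which(rowSums(zero) > 0)
  for (i in hit) {
    u[i, ] <- zero[i, ] / sum(zero[i, ])
  }
  u
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_clustering> %d profiles, %d clusters, m = %.2f, %d iterations, objective %.4g\n",
    nrow(x$membership), nrow(x$centers), x$fuzzifier, x$iterations,
    utils::tail(x$objective, 1)
  ))
  invisible(x)
}

#' @exportS3Method
tidy.fuzzy_clustering <- function(x, ...) {
  tibble::as_tibble(x$membership, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cluster",
                        values_to = "membership")
}

#' @exportS3Method
glance.fuzzy_clustering <- function(x, ...) {
  tibble::tibble(
    n_profiles = nrow(x$membership), n_clusters = nrow(x$centers),
    fuzzifier = x$fuzzifier, iterations = x$iterations,
    objective = utils::tail(x$objective, 1)
  )
}

#' Extract monotone age-trend gene sets from a fuzzy clustering
#'
#' A cluster is "up" when its centre increases strictly across
#' young/middle/old and "down" when it decreases strictly. Each gene goes
#' to its highest-membership cluster, and is listed only when that
#' membership reaches `membership_threshold`.
#'
#' @param clust A [fuzzy_cmeans()] result over the three ordered ages.
#' @param membership_threshold Minimum max-membership in (0, 1].
#' @return Object of class `trend_sets`: `up_genes`, `down_genes`,
#'   `cluster_direction` (named character), `gene_info` (tibble `gene`,
#'   `cluster`, `membership`, `direction`).
#' @export
monotone_trend_sets <- function(clust, membership_threshold = 0.5) {
  stopifnot(inherits(clust, "fuzzy_clustering"))
  direction <- apply(clust$centers, 1, function(ctr) {
    if (all(diff(ctr) > 0)) "up" else if (all(diff(ctr) < 0)) "down" else
      "flat"
  })
  best <- apply(clust$membership, 1, which.max)
  best_u <- clust$membership[cbind(seq_len(nrow(clust$membership)), best)]
  info <- tibble::tibble(
    gene = rownames(clust$membership),
    cluster = rownames(clust$centers)[best],
    membership = unname(best_u),
    direction = unname(direction[best])
  )
  assigned <- info$membership >= membership_threshold
  structure(
    list(
      up_genes = info$gene[assigned & info$direction == "up"],
      down_genes = info$gene[assigned & info$direction == "down"],
      cluster_direction = direction,
      gene_info = info
    ),
    class = "trend_sets"
  )
}

#' @export
print.trend_sets <- function(x, ...) {
  cat(sprintf("<trend_sets> %d up, %d down (%d clusters: %s)\n",
              length(x$up_genes), length(x$down_genes),
              length(x$cluster_direction),
              paste(x$cluster_direction, collapse = "/")))
  invisible(x)
}

new_signature_pair <- function(name, up, down, provenance) {
  stopifnot(!length(intersect(up, down)))
  structure(list(name = name, up = up, down = down,
                 provenance = provenance),
            class = "signature_pair")
}

#' @export
print.signature_pair <- function(x, ...) {
  cat(sprintf("<signature_pair> %s: %d up, %d down\n", x$name,
              length(x$up), length(x$down)))
  invisible(x)
}

#' Neurogenic aging signature from real-time and pseudotime structure
#'
#' Intersects the real-time (age-ordered) trend genes with pseudotime
#' module genes of the quiescent-stem-cell activation trajectory: the
#' up signature with the early, stem-enriched module(s), the down
#' signature with the late, fate-committed module(s).
#'
#' @param realtime A [monotone_trend_sets()] result.
#' @param modules A [pseudotime_modules()] result on the activation
#'   trajectory.
#' @param up_module_ids Module numbers intersected with the real-time up
#'   genes (default module 1).
#' @param down_module_ids Module numbers intersected with the real-time
#'   down genes (default modules 3 and 4).
#' @return A `signature_pair` named `"NAS"` with per-gene provenance.
#' @export
build_nas <- function(realtime, modules, up_module_ids = 1,
                      down_module_ids = c(3, 4)) {
  stopifnot(inherits(realtime, "trend_sets"),
            inherits(modules, "module_assignment"))
  up <- sort(intersect(realtime$up_genes, module_genes(modules, up_module_ids)))
  down <- sort(intersect(realtime$down_genes,
                         module_genes(modules, down_module_ids)))
  if (!length(up) && !length(down)) {
    warning("empty NAS: real-time trends and pseudotime modules do not overlap")
  }
  mod_of <- stats::setNames(modules$assignment$module,
                            modules$assignment$gene)
  provenance <- dplyr::bind_rows(
    tibble::tibble(gene = up, direction = "up",
                   source = paste0("realtime_up+module_", mod_of[up])),
    tibble::tibble(gene = down, direction = "down",
                   source = paste0("realtime_down+module_", mod_of[down]))
  )
  new_signature_pair("NAS", up, down, provenance)
}

#' Core aging signature shared across niche populations
#'
#' A gene enters the up (down) signature when it has an up (down)
#' real-time trend in the whole-tissue spatial pseudobulk and the same
#' trend in at least `min_shared` of the niche cell populations.
#'
#' @param celltype_trends Named list of [monotone_trend_sets()] results,
#'   one per niche population.
#' @param st_trend A [monotone_trend_sets()] result from the whole-DG
#'   spot pseudobulk.
#' @param min_shared Minimum number of populations sharing the trend.
#' @return A `signature_pair` named `"CAS"`; provenance records the
#'   contributing populations per gene.
#' @export
build_cas <- function(celltype_trends, st_trend, min_shared = 2) {
  stopifnot(inherits(st_trend, "trend_sets"),
            all(vapply(celltype_trends, inherits, TRUE, "trend_sets")))
  if (min_shared > length(celltype_trends)) {
    stop("min_shared = ", min_shared, " exceeds the ",
         length(celltype_trends), " supplied populations", call. = FALSE)
  }
  pops <- names(celltype_trends)
  pick <- function(side) {
    st_genes <- if (side == "up") st_trend$up_genes else st_trend$down_genes
    support <- lapply(stats::setNames(st_genes, st_genes), function(g) {
      pops[vapply(celltype_trends, function(tr) {
        g %in% (if (side == "up") tr$up_genes else tr$down_genes)
      }, TRUE)]
    })
    keep <- vapply(support, length, 1L) >= min_shared
    list(genes = sort(st_genes[keep]), support = support[keep])
  }
  up <- pick("up")
  down <- pick("down")
  provenance <- dplyr::bind_rows(
    tibble::tibble(gene = up$genes, direction = "up",
                   source = unname(vapply(up$support[up$genes], paste,
                                          "", collapse = ";"))),
    tibble::tibble(gene = down$genes, direction = "down",
                   source = unname(vapply(down$support[down$genes], paste,
                                          "", collapse = ";")))
  )
  new_signature_pair("CAS", up$genes, down$genes, provenance)
}

#' Write a signature pair as a two-line GMT file
#'
#' @param sig A `signature_pair`.
#' @param gmt_path Output path.
#' @param provenance_csv Optional path for the provenance table.
#' @return `gmt_path`, invisibly.
#' @export
write_signature_gmt <- function(sig, gmt_path, provenance_csv = NULL) {
  stopifnot(inherits(sig, "signature_pair"))
  sets <- stats::setNames(list(sig$up, sig$down),
                          paste0(sig$name, c("_UP", "_DOWN")))
  write_gene_sets(sets, gmt_path)
  if (!is.null(provenance_csv)) {
    readr::write_csv(sig$provenance, provenance_csv)
  }
  invisible(gmt_path)
}
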