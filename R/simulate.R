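#' Simulate a lineage-structured single-cell atlas with planted truth
#'
#' Generates negative-binomial counts for a neurogenic lineage sampled at
#' three ages, with four kinds of planted structure:
#'
#' * per-type marker blocks (multiplicative effect for cells of that type);
#' * a latent activation/differentiation coordinate `t` in \[0, 1\] per
#'   cell, low for quiescent stem cells, mid for active progenitors, high
#'   for neuroblasts, driving four sequential lineage gene modules
#'   (logistic activations of `t`; module 1 decreasing, the rest
#'   increasing with staggered midpoints);
#' * age-regulated blocks whose log-rate shifts monotonically across
#'   young/middle/old (total shift `2*delta` per gene, split between the
#'   two age steps by a per-gene breakpoint so trend shapes vary);
#' * optional coupling of the age blocks to `t`: up-regulated aging
#'   genes share the quiescence-program activation shape (high at low
#'   `t`) and down-regulated ones the fate-committed shape, reproducing
#'   the overlap between real-time trends and the early/late pseudotime
#'   modules seen in quiescent-stem-cell trajectories.
#'
#' Counts for gene g in cell c are NB(mu, size = theta) with
#' `mu = libsize_c * rate_gc / sum_g rate_gc`.
#'
#' @param n_per_group Cells per (cell_type, age) combination: a single
#'   integer, or a data frame with columns `cell_type`, `age`, `n`.
#' @param cell_types Lineage stages in differentiation order.
#' @param n_genes Total genes.
#' @param n_markers Marker genes per cell type.
#' @param marker_effect Natural-log fold effect of a marker in its type.
#' @param n_module_genes Genes per lineage module (4 modules).
#' @param module_amplitude Natural-log amplitude of module activation.
#' @param n_aging Genes per age-regulated block (up and down).
#' @param delta Mean natural-log shift per age step for aging blocks.
#' @param couple_aging_to_latent If `TRUE`, aging-up genes also follow
#'   the early (quiescence) activation shape along `t` and aging-down
#'   genes the late (fate-committed) shape.
#' @param aging_latent_slope Natural-log amplitude of that coupling.
#' @param quiescence_deepening Downward shift of the latent coordinate of
#'   the first (quiescent) cell type per age step, emulating deeper
#'   quiescence in old animals.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size
#'   parameters.
#' @param theta Negative-binomial dispersion (shared within blocks).
#' @param seed Integer seed.
#' @return A list of class `lineage_sim` with elements `matrix` (an
#'   [expression_matrix()]), `truth_cells` (tibble: `cell_id`,
#'   `cell_type`, `age`, `latent_t`), `truth_genes` (tibble: `gene_id`,
#'   `block`) and `params`.
#' @export
simulate_lineage_atlas <- function(n_per_group = 100,
                                   cell_types = c("qNSC", "aNSPC", "NB/IMN"),
                                   n_genes = 800,
                                   n_markers = 40,
                                   marker_effect = 1.5,
                                   n_module_genes = 40,
                                   module_amplitude = 1.2,
                                   n_aging = 60,
                                   delta = 0.5,
                                   couple_aging_to_latent = TRUE,
                                   aging_latent_slope = 1.0,
                                   quiescence_deepening = 0.05,
                                   libsize_meanlog = log(2500),
                                   libsize_sdlog = 0.3,
                                   theta = 2,
                                   seed = 1L) {
  if (delta < 0 || theta <= 0) stop("delta must be >= 0 and theta > 0",
                                    call. = FALSE)
  design <- lineage_design(n_per_group, cell_types)
  n_modules <- 4L
  needed <- length(cell_types) * n_markers + 2L * n_aging +
    n_modules * n_module_genes
  if (needed > n_genes) {
    stop("n_genes too small for the requested disjoint gene blocks",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    block <- rep("null", n_genes)
    idx <- 0L
    take <- function(k) {
      out <- idx + seq_len(k)
      idx <<- idx + k
      out
    }
    marker_idx <- stats::setNames(
      lapply(cell_types, function(ct) take(n_markers)), cell_types)
    for (ct in cell_types) block[marker_idx[[ct]]] <- paste0("marker_", ct)
    up_idx <- take(n_aging); block[up_idx] <- "aging_up"
    down_idx <- take(n_aging); block[down_idx] <- "aging_down"
    module_idx <- lapply(seq_len(n_modules), function(m) take(n_module_genes))
    for (m in seq_len(n_modules)) block[module_idx[[m]]] <- paste0("module_", m)

    baseline <- stats::rnorm(n_genes, 0, 0.5)

    n_cells <- sum(design$n)
    cells <- design[rep(seq_len(nrow(design)), design$n), c("cell_type", "age")]
    cells$cell_id <- sprintf("c%05d", seq_len(n_cells))
    age_idx <- as.integer(age_factor(cells$age)) - 1L
    type_i <- match(cells$cell_type, cell_types)
    # latent activation: early types low, late types high; quiescent type
    # drifts deeper into quiescence with age
    t_centre <- (type_i - 0.5) / length(cell_types)
    t_centre <- t_centre - quiescence_deepening * age_idx * (type_i == 1L)
    latent_t <- pmin(pmax(stats::rnorm(n_cells, t_centre, 0.08), 0), 1)

    # per-gene age-response breakpoint: fraction of the total 2*delta
    # shift taken in the young -> middle step
    w_up <- stats::runif(n_aging, 0.25, 0.75)
    w_down <- stats::runif(n_aging, 0.25, 0.75)
    shift_at <- function(w, a) 2 * delta * (w * pmin(a, 1) + (1 - w) * pmax(a - 1, 0))

    midpoints <- c(0.2, 0.35, 0.55, 0.75)
    width <- 0.08
    logit <- function(t, mid) stats::plogis((t - mid) / width)

    log_rate <- matrix(baseline, n_genes, n_cells)
    for (ct in cell_types) {
      log_rate[marker_idx[[ct]], cells$cell_type == ct] <-
        log_rate[marker_idx[[ct]], cells$cell_type == ct] + marker_effect
    }
    for (m in seq_len(n_modules)) {
      act <- if (m == 1L) 1 - logit(latent_t, midpoints[m]) else
        logit(latent_t, midpoints[m])
      log_rate[module_idx[[m]], ] <- log_rate[module_idx[[m]], ] +
        module_amplitude * rep(act, each = n_module_genes)
    }
    log_rate[up_idx, ] <- log_rate[up_idx, ] +
      outer(w_up, age_idx, function(w, a) shift_at(w, a))
    log_rate[down_idx, ] <- log_rate[down_idx, ] -
      outer(w_down, age_idx, function(w, a) shift_at(w, a))
    if (couple_aging_to_latent) {
      # age-upregulated genes follow the quiescence-program shape
      # (high at low activation), age-downregulated genes the
      # fate-committed shape, so real-time trends overlap the early and
      # late pseudotime modules as in the neurogenic niche
      act_stem <- 1 - logit(latent_t, midpoints[1])
      act_late <- logit(latent_t, midpoints[3])
      log_rate[up_idx, ] <- log_rate[up_idx, ] +
        aging_latent_slope * rep(act_stem, each = n_aging)
      log_rate[down_idx, ] <- log_rate[down_idx, ] +
        aging_latent_slope * rep(act_late, each = n_aging)
    }

    rate <- exp(log_rate)
    rate <- sweep(rate, 2, colSums(rate), "/")
    libsize <- stats::rlnorm(n_cells, libsize_meanlog, libsize_sdlog)
    mu <- sweep(rate, 2, libsize, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = theta),
                     n_genes, n_cells, dimnames = list(gene_id, cells$cell_id))

    meta <- tibble::tibble(cell_id = cells$cell_id,
                           cell_type = cells$cell_type, age = cells$age)
    m <- expression_matrix(counts, cell_meta = meta)
    truth_cells <- tibble::tibble(cell_id = cells$cell_id,
                                  cell_type = cells$cell_type,
                                  age = age_factor(cells$age),
                                  latent_t = latent_t)
    truth_genes <- tibble::tibble(gene_id = gene_id, block = block)
    params <- list(
      n_per_group = n_per_group, cell_types = cell_types, n_genes = n_genes,
      n_markers = n_markers, marker_effect = marker_effect,
      n_module_genes = n_module_genes, module_amplitude = module_amplitude,
      n_aging = n_aging, delta = delta,
      couple_aging_to_latent = couple_aging_to_latent,
      aging_latent_slope = aging_latent_slope,
      quiescence_deepening = quiescence_deepening,
      libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
      theta = theta, seed = seed
    )
    structure(list(matrix = m, truth_cells = truth_cells,
                   truth_genes = truth_genes, params = params),
              class = "lineage_sim")
  })
}

lineage_design <- function(n_per_group, cell_types) {
  if (is.data.frame(n_per_group)) {
    design <- tibble::as_tibble(n_per_group)
    stopifnot(all(c("cell_type", "age", "n") %in% names(design)))
  } else {
    design <- tidyr::expand_grid(cell_type = cell_types,
                                 age = age_levels())
    design$n <- as.integer(n_per_group)
  }
  if (any(design$n <= 0)) stop("cell counts must be positive", call. = FALSE)
  design
}

#' Simulate a hexagonal spot lattice with inflammatory hotspots
#'
#' Builds a Visium-like array (columns within a row share the row's
#' parity; centre pitch `pitch_um`), plants hotspot centres, and
#' multiplies the rate of an inflammatory gene block by
#' `1 + amplitude * exp(-d / decay_um)` where `d` is the distance to the
#' nearest hotspot centre. All other genes are flat across the lattice.
#'
#' @param n_rows,n_cols Lattice extent (rows x occupied columns per row).
#' @param pitch_um Centre-to-centre spacing of neighbouring spots, in
#'   micrometres.
#' @param hotspot_centers List of `c(array_row, array_col)` pairs; `NULL`
#'   draws `n_hotspots` occupied positions at random.
#' @param n_hotspots Number of random hotspot centres when
#'   `hotspot_centers` is `NULL`.
#' @param decay_um Exponential decay length of the hotspot signal.
#' @param amplitude Peak fold-increase (`A` in `1 + A exp(-d/lambda)`).
#' @param n_genes Total genes; the first `n_inflammatory` form the
#'   inflammatory block.
#' @param n_inflammatory Inflammatory block size.
#' @param region Region label given to every spot.
#' @param libsize_meanlog,libsize_sdlog,theta Count-model parameters as in
#'   [simulate_lineage_atlas()].
#' @param seed Integer seed.
#' @return List of class `spot_sim`: `grid` (a [spot_grid()]), `truth`
#'   (tibble with per-spot `dist_to_hotspot_um`), `inflammatory_genes`,
#'   `centers`, `params`.
#' @export
simulate_spot_grid <- function(n_rows = 12,
                               n_cols = 12,
                               pitch_um = 100,
                               hotspot_centers = NULL,
                               n_hotspots = 2,
                               decay_um = 250,
                               amplitude = 2,
                               n_genes = 600,
                               n_inflammatory = 150,
                               region = "DG",
                               libsize_meanlog = log(20000),
                               libsize_sdlog = 0.25,
                               theta = 10,
                               seed = 1L) {
  if (n_rows < 1 || n_cols < 1) stop("empty lattice", call. = FALSE)
  if (decay_um <= 0) stop("decay_um must be positive", call. = FALSE)
  lattice <- tidyr::expand_grid(array_row = seq_len(n_rows) - 1L,
                                j = seq_len(n_cols) - 1L) |>
    dplyr::mutate(array_col = 2L * .data$j + .data$array_row %% 2L) |>
    dplyr::select(-"j")
  withr::with_seed(seed, {
    if (is.null(hotspot_centers)) {
      pick <- sample.int(nrow(lattice), n_hotspots)
      hotspot_centers <- lapply(pick, function(i) {
        c(lattice$array_row[i], lattice$array_col[i])
      })
    }
    centers <- do.call(rbind, hotspot_centers)
    inside <- centers[, 1] >= 0 & centers[, 1] < n_rows &
      centers[, 2] >= 0 & centers[, 2] < 2L * n_cols
    if (!all(inside)) stop("hotspot centers outside lattice", call. = FALSE)

    xy <- cbind(lattice$array_col * pitch_um / 2,
                lattice$array_row * pitch_um * sqrt(3) / 2)
    cxy <- cbind(centers[, 2] * pitch_um / 2,
                 centers[, 1] * pitch_um * sqrt(3) / 2)
    d <- apply(cxy, 1, function(ctr) sqrt(colSums((t(xy) - ctr)^2)))
    dist_hot <- if (is.matrix(d)) apply(d, 1, min) else d

    n_spots <- nrow(lattice)
    gene_id <- sprintf("s%04d", seq_len(n_genes))
    block <- c(rep("inflammatory", n_inflammatory),
               rep("background", n_genes - n_inflammatory))
    baseline <- exp(stats::rnorm(n_genes, 0, 0.5))
    boost <- 1 + amplitude * exp(-dist_hot / decay_um)
    rate <- matrix(baseline, n_genes, n_spots)
    rate[block == "inflammatory", ] <-
      rate[block == "inflammatory", ] * rep(boost, each = n_inflammatory)
    rate <- sweep(rate, 2, colSums(rate), "/")
    libsize <- stats::rlnorm(n_spots, libsize_meanlog, libsize_sdlog)
    mu <- sweep(rate, 2, libsize, "*")
    spot_id <- sprintf("spot-%03d", seq_len(n_spots))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = theta),
                     n_genes, n_spots, dimnames = list(gene_id, spot_id))
    spots <- tibble::tibble(
      spot_id = spot_id,
      array_row = lattice$array_row,
      array_col = lattice$array_col,
      pxl_row = xy[, 2],
      pxl_col = xy[, 1],
      region = region
    )
    grid <- spot_grid(counts, spots)
    truth <- tibble::tibble(spot_id = spot_id,
                            dist_to_hotspot_um = dist_hot)
    params <- list(n_rows = n_rows, n_cols = n_cols, pitch_um = pitch_um,
                   decay_um = decay_um, amplitude = amplitude,
                   n_genes = n_genes, n_inflammatory = n_inflammatory,
                   theta = theta, seed = seed)
    structure(list(grid = grid, truth = truth,
                   inflammatory_genes = gene_id[block == "inflammatory"],
                   centers = centers, params = params),
              class = "spot_sim")
  })
}

#' Simulate a tissue point pattern with two binary cell labels
#'
#' Cells are placed uniformly in a rectangular window. Label A is always
#' i.i.d. Bernoulli. Under `regime = "independent"` label B is too; under
#' `"exclusive"` B-labelled cells are relocated until no A-B pair lies
#' within `exclusion_radius` (labels are disjoint in this regime); under
#' `"attractive"` B labels are drawn with probability weights
#' `1 + strength * exp(-d_A / attraction_scale)` where `d_A` is the
#' distance to the nearest A cell.
#'
#' @param n_cells Number of cells.
#' @param width,height Window extent in micrometres.
#' @param p_a,p_b Label probabilities.
#' @param regime One of `"independent"`, `"exclusive"`, `"attractive"`.
#' @param exclusion_radius Exclusion distance (exclusive regime), um.
#' @param attraction_scale Decay length of the attraction weight, um.
#' @param strength Attraction strength (attractive regime).
#' @param max_retries Relocation attempts per violating B cell before the
#'   window is declared too crowded.
#' @param seed Integer seed.
#' @return Tibble with columns `cell_id`, `x`, `y`, `label_a`, `label_b`
#'   (logical); simulation parameters are attached as attribute
#'   `"params"`.
#' @export
simulate_tissue_cells <- function(n_cells = 500,
                                  width = 1000,
                                  height = 1000,
                                  p_a = 0.15,
                                  p_b = 0.15,
                                  regime = c("independent", "exclusive",
                                             "attractive"),
                                  exclusion_radius = 60,
                                  attraction_scale = 60,
                                  strength = 5,
                                  max_retries = 50,
                                  seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(p_a > 0, p_a < 1, p_b > 0, p_b < 1, strength >= 0)
  withr::with_seed(seed, {
    x <- stats::runif(n_cells, 0, width)
    y <- stats::runif(n_cells, 0, height)
    label_a <- stats::runif(n_cells) < p_a
    label_b <- rep(FALSE, n_cells)
    if (regime == "independent") {
      label_b <- stats::runif(n_cells) < p_b
    } else if (regime == "exclusive") {
      cand <- which(!label_a & stats::runif(n_cells) < p_b)
      ax <- x[label_a]; ay <- y[label_a]
      clear <- function(px, py) {
        !length(ax) || min((ax - px)^2 + (ay - py)^2) >= exclusion_radius^2
      }
      for (i in cand) {
        ok <- clear(x[i], y[i])
        tries <- 0L
        while (!ok && tries < max_retries) {
          x[i] <- stats::runif(1, 0, width)
          y[i] <- stats::runif(1, 0, height)
          ok <- clear(x[i], y[i])
          tries <- tries + 1L
        }
        if (!ok) {
          stop("window too crowded to place exclusive B cells after ",
               max_retries, " retries", call. = FALSE)
        }
        label_b[i] <- TRUE
      }
    } else {
      ax <- x[label_a]; ay <- y[label_a]
      d_a <- if (length(ax)) {
        vapply(seq_len(n_cells), function(i) {
          sqrt(min((ax - x[i])^2 + (ay - y[i])^2))
        }, 0)
      } else rep(Inf, n_cells)
      w <- 1 + strength * exp(-d_a / attraction_scale)
      n_b <- stats::rbinom(1, n_cells, p_b)
      pick <- sample.int(n_cells, min(n_b, n_cells), prob = w)
      label_b[pick] <- TRUE
    }
    out <- tibble::tibble(
      cell_id = sprintf("t%05d", seq_len(n_cells)),
      x = x, y = y, label_a = label_a, label_b = label_b
    )
    attr(out, "params") <- list(
      n_cells = n_cells, width = width, height = height, p_a = p_a,
      p_b = p_b, regime = regime, exclusion_radius = exclusion_radius,
      attraction_scale = attraction_scale, strength = strength, seed = seed
    )
    out
  })
}

#' Write a simulation to disk with its ground truth and manifest
#'
#' Lineage simulations are written as a 10x triplet directory plus
#' `truth_cells.csv` / `truth_genes.csv`; spot simulations as positions
#' CSV + triplet directory plus `truth_spots.csv`; tissue tables as a
#' point CSV. A `manifest.json` records all parameters including the
#' seed.
#'
#' @param sim A `lineage_sim`, `spot_sim`, or the tibble returned by
#'   [simulate_tissue_cells()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(sim, "lineage_sim")) {
    write_counts_10x(sim$matrix, file.path(dir, "counts"))
    tc <- sim$truth_cells
    tc$age <- as.character(tc$age)
    readr::write_csv(tc, file.path(dir, "truth_cells.csv"))
    readr::write_csv(sim$truth_genes, file.path(dir, "truth_genes.csv"))
    params <- sim$params
  } else if (inherits(sim, "spot_sim")) {
    write_spot_grid(sim$grid, file.path(dir, "positions.csv"),
                    file.path(dir, "counts"))
    readr::write_csv(sim$truth, file.path(dir, "truth_spots.csv"))
    writeLines(sim$inflammatory_genes,
               file.path(dir, "inflammatory_genes.txt"))
    params <- sim$params
  } else if (is.data.frame(sim)) {
    readr::write_csv(sim, file.path(dir, "cells.csv"))
    params <- attr(sim, "params")
  } else {
    stop("unknown simulation object", call. = FALSE)
  }
  jsonlite::write_json(params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
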