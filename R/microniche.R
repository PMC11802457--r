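#' Tile circles along a reference polyline
#'
#' Places circles of radius `radius` along the arc of a polyline (the
#' manually drawn subgranular-zone line in the tissue workflow), with
#' consecutive centres spaced `2 * radius * (1 - overlap)` apart so that
#' `overlap = 0.5` gives half-diameter overlap (spacing = radius) and
#' `overlap = 0` gives tangent circles. Centres keep one radius of
#' clearance from both ends so circles stay on the line, with any
#' leftover arc split symmetrically between the ends (reversing the
#' polyline therefore reverses the same centre set); a polyline shorter
#' than one diameter yields a single circle at the midpoint, with a
#' warning.
#'
#' `overlap_mode = "area"` instead interprets `overlap` as the shared
#' lens-area fraction of neighbouring circles and solves for the
#' spacing (0.5 shared area gives spacing of about 0.8079 radius).
#'
#' @param polyline Two-column matrix or data frame of ordered `(x, y)`
#'   vertices, in micrometres.
#' @param radius Circle radius, micrometres.
#' @param overlap Fractional overlap of consecutive circles.
#' @param overlap_mode `"linear"` (along-line fraction of the diameter,
#'   default) or `"area"`.
#' @return Object of class `microniche_set`: tibble `circle_id`,
#'   `center_x`, `center_y`, `arc_pos`, with attributes `radius`,
#'   `spacing` and `mode = "tiling"`.
#' @export
tile_sgz_circles <- function(polyline, radius = 55, overlap = 0.5,
                             overlap_mode = c("linear", "area")) {
  overlap_mode <- match.arg(overlap_mode)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)",
                                        call. = FALSE)
  pl <- as.matrix(polyline)[, 1:2, drop = FALSE]
  if (nrow(pl) < 2) stop("polyline needs at least 2 vertices",
                         call. = FALSE)
  seg <- sqrt(rowSums(diff(pl)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  spacing <- if (overlap_mode == "linear") {
    2 * radius * (1 - overlap)
  } else {
    lens_spacing(radius, overlap)
  }
  if (total < 2 * radius) {
    warning("polyline shorter than one circle; placing a single circle ",
            "at the midpoint")
    pos <- total / 2
  } else {
    # symmetric placement: leftover arc beyond the last full spacing is
    # split between the two ends, so reversing the polyline reverses the
    # same centre set
    offset <- ((total - 2 * radius) %% spacing) / 2
    pos <- seq(radius + offset, total - radius + 1e-9, by = spacing)
  }
  centers <- cbind(
    stats::approx(arc, pl[, 1], xout = pos)$y,
    stats::approx(arc, pl[, 2], xout = pos)$y
  )
  out <- tibble::tibble(
    circle_id = sprintf("circle-%03d", seq_along(pos)),
    center_x = centers[, 1],
    center_y = centers[, 2],
    arc_pos = pos
  )
  structure(out, radius = radius, spacing = spacing, mode = "tiling",
            class = c("microniche_set", class(out)))
}

# spacing d solving: lens area of two radius-r circles d apart equals
# `frac` of the circle area
lens_spacing <- function(radius, frac) {
  lens <- function(d) {
    2 * radius^2 * acos(d / (2 * radius)) -
      (d / 2) * sqrt(4 * radius^2 - d^2)
  }
  stats::uniroot(function(d) lens(d) / (pi * radius^2) - frac,
                 c(1e-9, 2 * radius - 1e-9))$root
}

#' Count labelled cells inside each microniche circle
#'
#' A cell is counted in every circle whose centre lies within `radius`
#' of it (closed disc: a cell exactly on the rim counts).
#'
#' @param niches A [tile_sgz_circles()] result (or any `microniche_set`).
#' @param cells Point table with columns `x`, `y` and logical `label_a`,
#'   `label_b` (as from [simulate_tissue_cells()]).
#' @return The `microniche_set` with added columns `n_a`, `n_b`.
#' @export
assign_cells_to_circles <- function(niches, cells) {
  stopifnot(inherits(niches, "microniche_set"),
            all(c("x", "y", "label_a", "label_b") %in% names(cells)))
  r2 <- attr(niches, "radius")^2
  n_a <- integer(nrow(niches))
  n_b <- integer(nrow(niches))
  for (i in seq_len(nrow(niches))) {
    d2 <- (cells$x - niches$center_x[i])^2 +
      (cells$y - niches$center_y[i])^2
    inside <- d2 <= r2
    n_a[i] <- sum(inside & cells$label_a)
    n_b[i] <- sum(inside & cells$label_b)
  }
  out <- niches
  out$n_a <- n_a
  out$n_b <- n_b
  out
}

#' Permutation co-occurrence test over microniche circles
#'
#' Reduces each circle to presence indicators of the two labels and
#' compares the observed number of circles containing both against a
#' null built by permuting the B-presence indicator across circles
#' (conditioning on the circle geometry and both presence totals). The
#' two-sided p-value is `(1 + #{|null - E| >= |obs - E|}) / (1 +
#' n_perm)` with `E = nA * nB / n`. The odds ratio uses the
#' Haldane-corrected 2x2 presence table.
#'
#' @param niches An [assign_cells_to_circles()] result.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Object of class `cooccurrence_result` (a list): `n_circles`,
#'   `n_a`, `n_b`, `n_both`, `n_neither`, `expected_both`, `odds_ratio`,
#'   `p_value`, `n_perm`, `seed`, `degenerate`.
#' @export
cooccurrence_test <- function(niches, n_perm = 1000, seed = 1L) {
  stopifnot(all(c("n_a", "n_b") %in% names(niches)))
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  a <- niches$n_a >= 1
  b <- niches$n_b >= 1
  n <- length(a)
  n_a <- sum(a); n_b <- sum(b); n_both <- sum(a & b)
  n_neither <- sum(!a & !b)
  stopifnot(n_a + n_b - n_both + n_neither == n)
  expected <- n_a * n_b / n
  or <- ((n_both + 0.5) * (n_neither + 0.5)) /
    ((n_a - n_both + 0.5) * (n_b - n_both + 0.5))
  degenerate <- n_a == 0 || n_b == 0 || n_a == n || n_b == n
  if (n_a == 0 || n_b == 0) {
    p <- 1
  } else {
    null_both <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(k) sum(a & sample(b)), 0L)
    })
    p <- (1 + sum(abs(null_both - expected) >= abs(n_both - expected))) /
      (1 + n_perm)
  }
  structure(
    list(n_circles = n, n_a = n_a, n_b = n_b, n_both = n_both,
         n_neither = n_neither, expected_both = expected,
         odds_ratio = or, p_value = p, n_perm = n_perm, seed = seed,
         degenerate = degenerate),
    class = "cooccurrence_result"
  )
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat(sprintf(
    "<cooccurrence_result> %d circles: A in %d, B in %d, both in %d (expected %.1f)\n  odds ratio %.3f, p = %.4g (%d permutations)%s\n",
    x$n_circles, x$n_a, x$n_b, x$n_both, x$expected_both, x$odds_ratio,
    x$p_value, x$n_perm, if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @exportS3Method
glance.cooccurrence_result <- function(x, ...) {
  tibble::tibble(
    n_circles = x$n_circles, n_a = x$n_a, n_b = x$n_b,
    n_both = x$n_both, n_neither = x$n_neither,
    expected_both = x$expected_both, odds_ratio = x$odds_ratio,
    p_value = x$p_value, degenerate = x$degenerate
  )
}

#' Fraction of centre-labelled cells with a target cell nearby
#'
#' Each centre-labelled cell is the middle of a closed disc of the given
#' radius; the function reports the fraction of centres with at least
#' one target-labelled cell inside, a cell carrying both labels not
#' counting as its own target.
#'
#' @param cells Point table with `x`, `y` and logical label columns.
#' @param center_label,target_label Names of the logical label columns.
#' @param radius Disc radius (same units as the coordinates).
#' @return Object of class `proximity_result`: `fraction`, `radius`, and
#'   `centers` (tibble `cell_id`, `x`, `y`, `has_target`).
#' @export
proximity_fraction <- function(cells, center_label = "label_a",
                               target_label = "label_b", radius = 55) {
  stopifnot(all(c("x", "y", center_label, target_label) %in% names(cells)))
  centre_idx <- which(cells[[center_label]])
  if (!length(centre_idx)) stop("no centre-labelled cells", call. = FALSE)
  target_idx <- which(cells[[target_label]])
  r2 <- radius^2
  has_target <- vapply(centre_idx, function(i) {
    others <- setdiff(target_idx, i)
    if (!length(others)) return(FALSE)
    any((cells$x[others] - cells$x[i])^2 +
          (cells$y[others] - cells$y[i])^2 <= r2)
  }, TRUE)
  centers <- tibble::tibble(
    cell_id = if ("cell_id" %in% names(cells)) cells$cell_id[centre_idx] else
      as.character(centre_idx),
    x = cells$x[centre_idx], y = cells$y[centre_idx],
    has_target = has_target
  )
  structure(list(fraction = mean(has_target), radius = radius,
                 centers = centers),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "<proximity_result> %.3f of %d centres have a target within %g um\n",
    x$fraction, nrow(x$centers), x$radius
  ))
  invisible(x)
}

#' Serpentine reference polyline spanning a rectangular window
#'
#' Builds a boustrophedon path (alternating vertical sweeps joined by
#' horizontal steps) inside the window, a convenient stand-in for the
#' hand-drawn subgranular-zone line when tiling synthetic tissue: its
#' arc length grows with `passes`, so any circle count can be reached
#' inside a fixed window.
#'
#' @param width,height Window extent, micrometres.
#' @param margin Clearance kept from the window edge.
#' @param passes Number of vertical sweeps.
#' @return Matrix of ordered `(x, y)` vertices.
#' @export
serpentine_polyline <- function(width, height, margin = 100, passes = 10) {
  stopifnot(passes >= 2, margin < width / 2, margin < height / 2)
  xs <- seq(margin, width - margin, length.out = passes)
  pts <- matrix(NA_real_, 2 * passes, 2)
  for (i in seq_len(passes)) {
    ys <- if (i %% 2 == 1) c(margin, height - margin) else
      c(height - margin, margin)
    pts[2 * i - 1, ] <- c(xs[i], ys[1])
    pts[2 * i, ] <- c(xs[i], ys[2])
  }
  pts
}
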