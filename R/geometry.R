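#' Fit an ellipsoid to a 3D point set by second moments
#'
#' The centre is the arithmetic mean of the points and the axes come from the
#' eigen-decomposition of the second central moment tensor. Semi-axis lengths
#' are `sqrt(5 * eigenvalue)`, which is exact for points filling a solid
#' uniform ellipsoid. Eigenvalues are sorted descending and each axis vector
#' is flipped so that its largest-magnitude component is positive, giving a
#' deterministic sign convention.
#'
#' @param points Numeric matrix (n x 3) of coordinates in µm, n >= 4 and not
#'   coplanar.
#'
#' @return A `fitted_ellipsoid`: list with `center`, semi-axes `a >= b >= c`
#'   and orthonormal axis vectors `e_a`, `e_b`, `e_c` (columns of `axes`).
#' @examples
#' pts <- sample_ellipsoid_points(2000, c(20, 10, 5), seed = 1)
#' fit_ellipsoid(pts)
#' @export
fit_ellipsoid <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix", call. = FALSE)
  n <- nrow(points)
  if (n < 4) stop("need at least 4 points to fit an ellipsoid", call. = FALSE)
  center <- colMeans(points)
  centred <- sweep(points, 2, center)
  mom <- crossprod(centred) / n
  eg <- eigen(mom, symmetric = TRUE)
  if (eg$values[3] <= max(eg$values[1], .Machine$double.eps) * 1e-9) {
    stop("degenerate geometry: points are (nearly) coplanar", call. = FALSE)
  }
  axes <- eg$vectors
  for (k in 1:3) {
    v <- axes[, k]
    if (v[which.max(abs(v))] < 0) axes[, k] <- -v
  }
  semi <- sqrt(5 * eg$values)
  structure(
    list(center = center, a = semi[1], b = semi[2], c = semi[3],
         axes = axes),
    class = "fitted_ellipsoid"
  )
}

#' @export
print.fitted_ellipsoid <- function(x, ...) {
  cat(sprintf("<fitted_ellipsoid> semi-axes %.2f >= %.2f >= %.2f um\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Sample points uniformly inside an ellipsoid
#'
#' @param n Number of points.
#' @param semi Semi-axis lengths `c(a, b, c)` in µm.
#' @param center Centre (µm).
#' @param axes 3x3 rotation matrix whose columns are the axis directions.
#' @param seed Optional integer seed (local RNG scope).
#' @return An n x 3 matrix.
#' @export
sample_ellipsoid_points <- function(n, semi, center = c(0, 0, 0),
                                    axes = diag(3), seed = NULL) {
  draw <- function() {
    g <- matrix(stats::rnorm(3 * n), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    r <- stats::runif(n)^(1 / 3)
    u <- g * r
    sweep(u %*% diag(semi) %*% t(axes), 2, center, `+`)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Re-measure cell shapes by point sampling and ellipsoid fitting
#'
#' Runs the measurement route over synthetic (or stored) cells: each cell's
#' ellipsoid is filled with uniformly sampled points and re-fitted with
#' [fit_ellipsoid()], emulating segmentation-based shape measurement. Uses
#' the caller's RNG state.
#'
#' @param cells Data frame of cells.
#' @param points_per_cell Points sampled inside each ellipsoid.
#' @return The input as a tibble with fitted `fit_a_um`, `fit_b_um`,
#'   `fit_c_um` and `fit_ar` columns.
#' @export
refit_cell_shapes <- function(cells, points_per_cell = 400) {
  cells <- tibble::as_tibble(cells)
  fits <- vapply(seq_len(nrow(cells)), function(i) {
    e_a <- c(cells$dir_x[i], cells$dir_y[i], cells$dir_z[i])
    ref <- if (abs(e_a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e_b <- crossprod3(e_a, ref); e_b <- e_b / sqrt(sum(e_b^2))
    axes <- cbind(e_a, e_b, crossprod3(e_a, e_b))
    pts <- sample_ellipsoid_points(
      points_per_cell,
      c(cells$axis_a_um[i], cells$axis_b_um[i], cells$axis_c_um[i]),
      center = c(cells$x_um[i], cells$y_um[i], cells$z_um[i]), axes = axes)
    fit <- fit_ellipsoid(pts)
    c(fit$a, fit$b, fit$c)
  }, numeric(3))
  cells$fit_a_um <- fits[1, ]
  cells$fit_b_um <- fits[2, ]
  cells$fit_c_um <- fits[3, ]
  cells$fit_ar <- fits[1, ] / fits[3, ]
  cells
}

#' Long/short aspect ratio of a cell ellipsoid
#'
#' The "cellular coefficient": ratio of the longest to the shortest fitted
#' semi-axis, `a / c`, always >= 1. For a data frame of cells, the ratio is
#' computed row-wise from the `axis_a_um` and `axis_c_um` columns.
#'
#' @param x A `fitted_ellipsoid` or a data frame of cells.
#' @return Numeric vector of aspect ratios.
#' @export
aspect_ratio <- function(x) UseMethod("aspect_ratio")

#' @export
aspect_ratio.fitted_ellipsoid <- function(x) x$a / x$c

#' @export
aspect_ratio.data.frame <- function(x) x$axis_a_um / x$axis_c_um

#' Classify cell orientation against the embryo axes
#'
#' Cells whose aspect ratio is below `min_ar` have an unstable long axis and
#' are left `unclassified`; otherwise the class is the frame axis (AP, ML or
#' DV) with the largest absolute dot product with the cell's long axis.
#'
#' @param cells Data frame of cells (columns `dir_x/y/z`, `axis_a_um`,
#'   `axis_c_um`).
#' @param frame An [axis_frame()].
#' @param min_ar Minimum aspect ratio for a cell to be orientable
#'   (default 1.3).
#' @return The input as a tibble with an `orientation` factor column with
#'   levels `AP`, `ML`, `DV`, `unclassified`.
#' @seealso [orientation_fractions()]
#' @export
classify_orientation <- function(cells, frame = axis_frame(), min_ar = 1.3) {
  cells <- tibble::as_tibble(cells)
  dirs <- as.matrix(cells[, c("dir_x", "dir_y", "dir_z")])
  dots <- abs(dirs %*% cbind(frame$ap, frame$ml, frame$dv))
  cls <- c("AP", "ML", "DV")[max.col(dots, ties.method = "first")]
  cls[aspect_ratio(cells) < min_ar] <- "unclassified"
  cells$orientation <- factor(cls, levels = c("AP", "ML", "DV", "unclassified"))
  cells
}

#' Per-region orientation class fractions
#'
#' @inheritParams classify_orientation
#' @return Tibble with one row per region and orientation class; fractions
#'   sum to 1 within each region.
#' @export
orientation_fractions <- function(cells, frame = axis_frame(), min_ar = 1.3) {
  classify_orientation(cells, frame, min_ar) |>
    dplyr::count(.data$region, .data$orientation, .drop = FALSE) |>
    dplyr::group_by(.data$region) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$region %in% unique(cells$region))
}

#' Fraction of anteroposteriorly oriented mitotic spindles
#'
#' Each event's spindle vector is the normalised difference of its two
#' centriole points; the spindle counts as AP-oriented when its angle to the
#' AP axis, folded to `[0, 90]` degrees, is at most `cone_half_angle`.
#' Events with coincident centrioles are skipped with a warning and excluded
#' from the denominator. An empty event set yields `NA` (undefined fraction),
#' not 0.
#'
#' @param events Tibble of division events with centriole columns
#'   `c1x, c1y, c1z, c2x, c2y, c2z` (µm).
#' @param frame An [axis_frame()].
#' @param cone_half_angle Cone half-angle in degrees (default 30). Under
#'   uniformly random spindle directions the expected AP fraction is
#'   `1 - cos(cone_half_angle)`.
#' @return Fraction in `[0, 1]`, or `NA_real_` for an empty/fully-degenerate
#'   event set.
#' @export
spindle_ap_fraction <- function(events, frame = axis_frame(),
                                cone_half_angle = 30) {
  if (is.null(events) || nrow(events) == 0) return(NA_real_)
  d <- cbind(events$c2x - events$c1x,
             events$c2y - events$c1y,
             events$c2z - events$c1z)
  len <- sqrt(rowSums(d^2))
  degenerate <- len < 1e-12
  if (any(degenerate)) {
    warning(sprintf("skipping %d division event(s) with coincident centrioles",
                    sum(degenerate)), call. = FALSE)
    d <- d[!degenerate, , drop = FALSE]
    len <- len[!degenerate]
  }
  if (nrow(d) == 0) return(NA_real_)
  cosang <- abs((d / len) %*% frame$ap)
  mean(cosang >= cos(cone_half_angle * pi / 180))
}

#' Filopodia statistics for a region
#'
#' Pools all filopodia of the region's cells. Cells without filopodia
#' contribute to the fractions only; with no filopodia at all in the region
#' the mean and maximum are `NA`.
#'
#' @param cells Data frame of cells.
#' @param region Region label to summarise (default: all cells given).
#' @return One-row tibble: `n_cells`, `n_filopodia`, `frac_ge1` (fraction of
#'   cells with >= 1 filopodium), `frac_ge5` (>= 5), `mean_length_um`,
#'   `max_length_um`.
#' @export
filopodia_stats <- function(cells, region = NULL) {
  if (!is.null(region)) cells <- cells[cells$region %in% region, ]
  if (nrow(cells) == 0) stop("no cells in the requested region", call. = FALSE)
  fil <- parse_filopodia(cells$filopodia_lengths)
  counts <- lengths(fil)
  lens <- unlist(fil)
  tibble::tibble(
    n_cells = nrow(cells),
    n_filopodia = length(lens),
    frac_ge1 = mean(counts >= 1),
    frac_ge5 = mean(counts >= 5),
    mean_length_um = if (length(lens)) mean(lens) else NA_real_,
    max_length_um = if (length(lens)) max(lens) else NA_real_
  )
}
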