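#' Assign mesodermal cells to regions along the PSM arc
#'
#' Each cell centroid is projected to its nearest point on the arc (a spline
#' through the control points, resampled densely) and assigned by arc-length
#' lookup in the breakpoint partition. A cell exactly on a breakpoint goes to
#' the more posterior region (half-open intervals); projections outside the
#' spline domain are clamped to the nearest terminal region with a warning.
#'
#' @param cells Data frame of cells.
#' @param breakpoints Strictly increasing arc-length breakpoints (µm)
#'   delimiting, from anterior to posterior, the regions in `labels`.
#' @param labels Region labels, one more than `length(breakpoints)`... from
#'   anterior-most to posterior-most.
#' @param control Arc spline control points (matrix with columns x, z); by
#'   default a straight anteroposterior axis spanning the cells.
#' @return The input as a tibble with the `region` column replaced.
#' @export
assign_regions <- function(cells, breakpoints, labels, control = NULL) {
  stopifnot(length(labels) == length(breakpoints) + 1)
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  cells <- tibble::as_tibble(cells)
  if (is.null(control)) {
    control <- cbind(x = range(cells$x_um) + c(-1, 1), z = c(0, 0))
  }
  arc <- arc_polyline(control, n = 2048)
  s <- project_arc_length(cells, arc)
  if (any(s$outside)) {
    warning(sprintf("%d cell(s) project outside the spline domain; %s",
                    sum(s$outside),
                    "assigned to the nearest terminal region"),
            call. = FALSE)
  }
  # half-open [b_k, b_{k+1}): a cell exactly on a breakpoint joins the
  # more posterior (larger arc length) region
  bin <- findInterval(s$s, breakpoints, left.open = FALSE) + 1L
  cells$region <- labels[bin]
  cells
}

# nearest-point projection of centroids onto the dense arc polyline,
# returning arc lengths (projection onto segments, ties to smallest s)
project_arc_length <- function(cells, arc) {
  px <- arc$x; pz <- arc$z; cum <- arc$cum
  n <- length(px)
  x <- cells$x_um; z <- cells$z_um
  sx <- px[-n]; sz <- pz[-n]
  dx <- diff(px); dz <- diff(pz)
  len2 <- dx^2 + dz^2
  s_best <- numeric(length(x)); d_best <- rep(Inf, length(x))
  for (j in seq_len(n - 1)) {
    t <- ((x - sx[j]) * dx[j] + (z - sz[j]) * dz[j]) / len2[j]
    t <- pmin(pmax(t, 0), 1)
    d2 <- (x - (sx[j] + t * dx[j]))^2 + (z - (sz[j] + t * dz[j]))^2
    s_cand <- cum[j] + t * sqrt(len2[j])
    better <- d2 < d_best - 1e-12
    s_best[better] <- s_cand[better]
    d_best[better] <- d2[better]
  }
  ends <- (abs(s_best) < 1e-9 & (x < px[1])) |
    (abs(s_best - cum[n]) < 1e-9 & (x > px[n]))
  list(s = s_best, outside = ends)
}

#' Pairwise-distance cohesion of a labelled cell group
#'
#' Within each section, every unordered pair of labelled cells contributes
#' the 3D Euclidean distance between their ellipsoid centres; pairs spanning
#' sections are never formed. Distances are pooled across sections and
#' summarised by their exact sample median and the fraction of pairs closer
#' than 25 µm (the proximity criterion used for cohesive groups).
#'
#' @param cells Data frame of cells of one region, with a `section` column
#'   (see [assign_sections()]).
#' @param planar If `TRUE`, use 2D in-plane distances (the coordinates
#'   orthogonal to the section axis) instead of full 3D distances.
#' @param axis Section axis (used only when `planar = TRUE`).
#' @return A `cohesion_result`: list with `region`, `distances` (tibble of
#'   `section`, `distance_um`), `median_um`, `n_pairs`, `frac_lt25`.
#' @export
pairwise_cohesion <- function(cells, planar = FALSE, axis = "AP") {
  if (!"section" %in% names(cells)) {
    stop("cells must carry a 'section' column; see assign_sections()",
         call. = FALSE)
  }
  cols <- c("x_um", "y_um", "z_um")
  if (planar) cols <- setdiff(cols, switch(axis, AP = "x_um", ML = "y_um",
                                           DV = "z_um"))
  per <- lapply(split(seq_len(nrow(cells)), cells$section), function(idx) {
    if (length(idx) < 2) return(NULL)
    d <- as.numeric(stats::dist(as.matrix(cells[idx, cols])))
    tibble::tibble(section = cells$section[idx[1]], distance_um = d)
  })
  dists <- dplyr::bind_rows(per)
  if (nrow(dists) == 0) {
    stop("insufficient pairs: fewer than 2 cells in every section",
         call. = FALSE)
  }
  structure(
    list(region = unique(cells$region), distances = dists,
         median_um = stats::median(dists$distance_um),
         n_pairs = nrow(dists),
         frac_lt25 = mean(dists$distance_um < 25)),
    class = "cohesion_result"
  )
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat(sprintf("<cohesion_result> %s: median %.1f um over %d pairs (%.0f%% < 25 um)\n",
              paste(x$region, collapse = "/"), x$median_um, x$n_pairs,
              100 * x$frac_lt25))
  invisible(x)
}

#' @export
tidy.cohesion_result <- function(x, ...) x$distances

#' @export
glance.cohesion_result <- function(x, ...) {
  tibble::tibble(region = paste(x$region, collapse = "/"),
                 median_um = x$median_um, n_pairs = x$n_pairs,
                 frac_lt25 = x$frac_lt25)
}

#' Closest-neighbour distances as a density measure
#'
#' For every cell of a group, the minimum centre-to-centre distance to any
#' other cell of the same group; the group median summarises local packing.
#'
#' @param cells Data frame with `x_um`, `y_um`, `z_um` (one group).
#' @return A `density_result`: list with `region`, `nn_um` (per-cell
#'   distances) and `median_um`.
#' @export
nearest_neighbour_density <- function(cells) {
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 cells in the group", call. = FALSE)
  d <- as.matrix(stats::dist(as.matrix(cells[, c("x_um", "y_um", "z_um")])))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  region <- if ("region" %in% names(cells)) unique(cells$region) else NA_character_
  structure(
    list(region = region, nn_um = unname(nn),
         median_um = stats::median(nn)),
    class = "density_result"
  )
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result> %s: median NN %.1f um over %d cells\n",
              paste(x$region, collapse = "/"), x$median_um, length(x$nn_um)))
  invisible(x)
}

#' @export
glance.density_result <- function(x, ...) {
  tibble::tibble(region = paste(x$region, collapse = "/"),
                 median_um = x$median_um, n_cells = length(x$nn_um))
}

#' Per-region, per-side closest-neighbour medians of a snapshot
#'
#' Groups mesodermal cells by region and body side (sign of the ML
#' coordinate) and computes the closest-neighbour median within each group.
#'
#' @param snapshot A [psm_snapshot()] (or cell data frame).
#' @param min_cells Groups smaller than this are dropped.
#' @return Tibble: `region`, `side`, `median_um`, `n_cells`.
#' @export
density_by_region_side <- function(snapshot, min_cells = 5) {
  cells <- tibble::as_tibble(snapshot)
  cells <- cells[is_mesodermal(cells$region), ]
  cells$side <- ifelse(cells$y_um < 0, "left", "right")
  cells |>
    dplyr::group_by(.data$region, .data$side) |>
    dplyr::filter(dplyr::n() >= min_cells) |>
    dplyr::group_modify(function(g, key) {
      r <- nearest_neighbour_density(g)
      tibble::tibble(median_um = r$median_um, n_cells = nrow(g))
    }) |>
    dplyr::ungroup()
}

#' Compare closest-neighbour densities between two conditions
#'
#' Per region(-side) group present in both conditions: difference of medians
#' (treated minus control) and a two-sample Wilcoxon rank-sum p-value on the
#' per-cell closest-neighbour distances. Regions missing from one condition
#' are skipped with a warning.
#'
#' @param control,treated Data frames of cells (same region set), e.g.
#'   mesodermal cells of two snapshots.
#' @param by Grouping columns (default region and side).
#' @return Tibble: group columns, medians, `delta_um`, `p_value`,
#'   `direction`.
#' @export
compare_epidermis_conditions <- function(control, treated,
                                         by = c("region", "side")) {
  prep <- function(cells) {
    cells <- tibble::as_tibble(cells)
    cells <- cells[is_mesodermal(cells$region), ]
    if ("side" %in% by && !"side" %in% names(cells)) {
      cells$side <- ifelse(cells$y_um < 0, "left", "right")
    }
    cells
  }
  control <- prep(control); treated <- prep(treated)
  key <- function(cells) do.call(paste, c(cells[by], sep = "\r"))
  groups <- union(key(control), key(treated))
  shared <- intersect(unique(key(control)), unique(key(treated)))
  if (length(setdiff(groups, shared)) > 0) {
    warning(sprintf("skipping %d group(s) missing from one condition",
                    length(setdiff(groups, shared))), call. = FALSE)
  }
  rows <- lapply(shared, function(k) {
    g_ctl <- control[key(control) == k, ]
    g_trt <- treated[key(treated) == k, ]
    if (nrow(g_ctl) < 2 || nrow(g_trt) < 2) return(NULL)
    nn_ctl <- nearest_neighbour_density(g_ctl)$nn_um
    nn_trt <- nearest_neighbour_density(g_trt)$nn_um
    delta <- stats::median(nn_trt) - stats::median(nn_ctl)
    p <- stats::wilcox.test(nn_trt, nn_ctl, exact = FALSE)$p.value
    out <- stats::setNames(as.list(strsplit(k, "\r", fixed = TRUE)[[1]]), by)
    tibble::as_tibble(c(out, list(
      control_median_um = stats::median(nn_ctl),
      treated_median_um = stats::median(nn_trt),
      delta_um = delta, p_value = p,
      direction = ifelse(delta > 0, "increase",
                         ifelse(delta < 0, "decrease", "none"))
    )))
  })
  dplyr::bind_rows(rows)
}
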