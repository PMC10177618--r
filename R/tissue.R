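#' Extents of the labelled mesodermal tissue
#'
#' Anteroposterior length, dorsoventral height and mediolateral width of the
#' labelled (Sox2-negative mesodermal) cells: per axis the difference of the
#' extreme ellipsoid-surface projections, i.e. centroid projection plus or
#' minus the ellipsoid's support in that direction. Using surfaces rather
#' than centroids gives a single cell a nonzero extent.
#'
#' @param snapshot A [psm_snapshot()] (or cell data frame).
#' @param frame An [axis_frame()].
#' @return One-row tibble: `stage`, `length_um`, `height_um`, `width_um`.
#' @export
labelled_extents <- function(snapshot, frame = NULL) {
  frame <- frame %||% snapshot_frame(snapshot)
  cells <- tibble::as_tibble(snapshot)
  cells <- cells[is_mesodermal(cells$region) & !cells$sox2, ]
  if (nrow(cells) == 0) stop("no labelled mesodermal cells", call. = FALSE)
  coord <- frame_coords(cells, frame)
  axes <- list(frame$ap, frame$ml, frame$dv)
  ext <- vapply(1:3, function(k) {
    r <- ellipsoid_support(cells, axes[[k]])
    max(coord[, k] + r) - min(coord[, k] - r)
  }, numeric(1))
  tibble::tibble(
    stage = attr(snapshot, "stage") %||% NA_integer_,
    length_um = ext[1], width_um = ext[2], height_um = ext[3]
  )
}

# support radius of each cell's ellipsoid in a given direction:
# r(u) = sqrt(sum_k (semi_k * <u, e_k>)^2); only the long axis direction is
# stored, so the two transverse axes are completed around it
ellipsoid_support <- function(cells, axis) {
  e_a <- as.matrix(cells[, c("dir_x", "dir_y", "dir_z")])
  ca <- as.numeric(e_a %*% axis)
  # component of the axis orthogonal to e_a is shared by e_b/e_c; bound with
  # the larger transverse semi-axis b (exact for spheroids, upper bound else)
  ct2 <- pmax(0, 1 - ca^2)
  sqrt((cells$axis_a_um * ca)^2 + (cells$axis_b_um)^2 * ct2)
}

#' Labelled-tissue volume by ellipsoid rasterization
#'
#' Rasterizes every labelled cell's ellipsoid onto an isotropic voxel grid
#' and counts occupied voxels once (union semantics), so overlapping cells
#' are not double-counted.
#'
#' @param snapshot A [psm_snapshot()] or cell data frame.
#' @param voxel_um Isotropic voxel size in µm (default 2).
#' @return Volume in µm³.
#' @export
labelled_volume <- function(snapshot, voxel_um = 2) {
  cells <- tibble::as_tibble(snapshot)
  if (nrow(cells) == 0) stop("no labelled cells", call. = FALSE)
  lo <- c(min(cells$x_um - cells$axis_a_um),
          min(cells$y_um - cells$axis_a_um),
          min(cells$z_um - cells$axis_a_um)) - voxel_um
  hi <- c(max(cells$x_um + cells$axis_a_um),
          max(cells$y_um + cells$axis_a_um),
          max(cells$z_um + cells$axis_a_um)) + voxel_um
  dims <- pmax(ceiling((hi - lo) / voxel_um), 1)
  # union of per-cell voxel index sets: overlaps counted once
  all_idx <- lapply(seq_len(nrow(cells)), function(i) {
    ellipsoid_voxels(cells[i, ], lo, dims, voxel_um)
  })
  length(unique(unlist(all_idx))) * voxel_um^3
}

#' Classify growth phases from a volume series
#'
#' Labels each stage interval `isovolumetric` when the relative volume
#' change is within `tolerance`, `volumetric` when it exceeds it and
#' `shrinking` when it falls below `-tolerance`.
#'
#' @param volumes Positive volume series ordered by stage.
#' @param stages Optional stage ids (length of `volumes`).
#' @param tolerance Relative change treated as "no volume change"
#'   (default 0.15, separating constancy from doubling).
#' @return Tibble: `from`, `to`, `ratio`, `phase`.
#' @export
growth_phase <- function(volumes, stages = seq_along(volumes),
                         tolerance = 0.15) {
  if (length(volumes) < 2) stop("need volumes for >= 2 stages", call. = FALSE)
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  rel <- diff(volumes) / utils::head(volumes, -1)
  tibble::tibble(
    from = utils::head(stages, -1), to = utils::tail(stages, -1),
    ratio = utils::tail(volumes, -1) / utils::head(volumes, -1),
    phase = dplyr::case_when(
      rel > tolerance ~ "volumetric",
      rel < -tolerance ~ "shrinking",
      TRUE ~ "isovolumetric"
    )
  )
}

#' Fraction of labelled mesodermal cells across the midline
#'
#' A cell counts as crossed when its signed ML coordinate lies strictly on
#' the side opposite the graft side; cells exactly on the midline plane do
#' not count.
#'
#' @param snapshot A [psm_snapshot()].
#' @param frame An [axis_frame()] (defaults to the snapshot's).
#' @return Fraction in `[0, 1]`.
#' @export
midline_crossing_fraction <- function(snapshot, frame = NULL) {
  frame <- frame %||% snapshot_frame(snapshot)
  cells <- tibble::as_tibble(snapshot)
  cells <- cells[is_mesodermal(cells$region) & !cells$sox2, ]
  if (nrow(cells) == 0) return(0)
  ml <- frame_coords(cells, frame)[, 2]
  if (frame$graft_side == "left") mean(ml > 0) else mean(ml < 0)
}

#' Relative displacement of a labelled region along the body contour
#'
#' `d_rel = a / b`, where `b` is the total arc length of the ventral body
#' contour polyline and `a` is the arc length from the anterior end (vertex
#' 1) to the nearest-point projection of the label centroid onto the
#' polyline. Projection ties resolve to the smallest arc length. The measure
#' is invariant under rigid motion and uniform scaling of contour and
#' centroid together.
#'
#' @param outline Polyline matrix (>= 2 vertices, 2 or 3 columns, µm);
#'   vertex 1 is the anterior-most body point.
#' @param centroid Label centroid (length 2 or 3, µm).
#' @return One-row tibble: `a_um`, `b_um`, `d_rel`.
#' @export
relative_displacement <- function(outline, centroid) {
  outline <- as.matrix(outline)
  if (nrow(outline) < 2) stop("outline needs >= 2 vertices", call. = FALSE)
  d <- ncol(outline)
  centroid <- as.numeric(centroid)[seq_len(d)]
  seg <- diff(outline)
  len <- sqrt(rowSums(seg^2))
  b <- sum(len)
  if (b <= 0) stop("outline has zero length", call. = FALSE)
  cum <- c(0, cumsum(len))
  a_best <- 0; d_best <- Inf
  for (j in seq_len(nrow(seg))) {
    if (len[j] == 0) next
    t <- sum((centroid - outline[j, ]) * seg[j, ]) / len[j]^2
    t <- min(max(t, 0), 1)
    p <- outline[j, ] + t * seg[j, ]
    d2 <- sum((centroid - p)^2)
    if (d2 < d_best - 1e-12) {        # strict: ties keep the smallest a
      d_best <- d2
      a_best <- cum[j] + t * len[j]
    }
  }
  tibble::tibble(a_um = a_best, b_um = b, d_rel = a_best / b)
}
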