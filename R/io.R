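#' Read and write labelled-cell tables
#'
#' The cell-table dialect is a UTF-8, tab-separated file with exactly the
#' columns `id, stage, region, origin, sox2, x_um, y_um, z_um, axis_a_um,
#' axis_b_um, axis_c_um, dir_x, dir_y, dir_z, volume_um3, filopodia_lengths`
#' (the last is a semicolon-separated list of µm values, possibly empty).
#' A write/read round trip reproduces every field to at least 6 significant
#' digits.
#'
#' @param path File path.
#' @return `read_cell_table()` returns a validated tibble of cells;
#'   `write_cell_table()` returns `path` invisibly.
#' @export
read_cell_table <- function(path) {
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  missing <- setdiff(CELL_COLUMNS, hdr)
  if (length(missing) > 0) {
    stop(sprintf("cell table '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cells <- readr::read_tsv(
    path,
    col_types = readr::cols(
      id = readr::col_character(), stage = readr::col_integer(),
      region = readr::col_character(), origin = readr::col_character(),
      sox2 = readr::col_logical(),
      x_um = readr::col_double(), y_um = readr::col_double(),
      z_um = readr::col_double(),
      axis_a_um = readr::col_double(), axis_b_um = readr::col_double(),
      axis_c_um = readr::col_double(),
      dir_x = readr::col_double(), dir_y = readr::col_double(),
      dir_z = readr::col_double(),
      volume_um3 = readr::col_double(),
      filopodia_lengths = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE, na = "NA"
  )
  cells$filopodia_lengths[is.na(cells$filopodia_lengths)] <- ""
  validate_cells(cells, context = sprintf("cell table '%s'", path))
}

#' @param cells A data frame of cells (e.g. a [psm_snapshot()]).
#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  cells <- tibble::as_tibble(cells)[, CELL_COLUMNS]
  readr::write_tsv(cells, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Partition cells into sections along a body axis
#'
#' Sections are half-open arc intervals `[k*t, (k+1)*t)` of the chosen axis
#' coordinate; every cell belongs to exactly one section by its centroid, so
#' sectioned counting never double-counts regardless of thickness. This is a
#' deliberate simplification of physical sectioning, where a cell spanning a
#' cut can appear on both faces.
#'
#' @param cells Data frame of cells.
#' @param axis `"AP"`, `"ML"` or `"DV"`.
#' @param thickness Section thickness in µm (default 80, vibratome-like).
#' @param frame An [axis_frame()].
#' @return The input as a tibble with an integer `section` column.
#' @export
assign_sections <- function(cells, axis = c("AP", "ML", "DV"),
                            thickness = 80, frame = axis_frame()) {
  axis <- match.arg(axis)
  stopifnot(thickness > 0)
  cells <- tibble::as_tibble(cells)
  if (nrow(cells) == 0) {
    cells$section <- integer()
    return(cells)
  }
  coord <- frame_coords(cells, frame)[, c(AP = 1, ML = 2, DV = 3)[[axis]]]
  cells$section <- as.integer(floor(coord / thickness))
  cells
}

#' Count labelled mesodermal cells across sections
#'
#' @inheritParams assign_sections
#' @return One-row tibble with `n_sections` and `n_mesodermal` (the summed
#'   per-section counts of Sox2-negative mesodermal cells).
#' @export
count_sectioned_cells <- function(cells, axis = "AP", thickness = 80,
                                  frame = axis_frame()) {
  sec <- assign_sections(cells, axis, thickness, frame)
  meso <- sec[is_mesodermal(sec$region) & !sec$sox2, ]
  per <- dplyr::count(meso, .data$section)
  tibble::tibble(n_sections = nrow(per), n_mesodermal = sum(per$n))
}

#' Extract cell records from a 3D label image
#'
#' One record per distinct positive label: the centroid is the voxel-centre
#' mean scaled by the voxel size, the volume is the voxel count times the
#' voxel volume and the ellipsoid comes from [fit_ellipsoid()] on the voxel
#' centre coordinates. Labels with degenerate geometry (fewer than 4 voxels
#' or coplanar) get `NA` shape entries with a warning.
#'
#' @param stack 3D integer array (z, y, x or any consistent order), 0 =
#'   background.
#' @param voxel_um Isotropic voxel edge length in µm (scalar; anisotropic
#'   voxels are not supported).
#' @return Tibble with `label`, centroid, semi-axes, direction and volume
#'   columns.
#' @export
cells_from_label_stack <- function(stack, voxel_um = 2) {
  if (length(voxel_um) != 1) {
    stop("anisotropic voxel sizes are not supported", call. = FALSE)
  }
  stopifnot(voxel_um > 0)
  idx <- which(stack > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(
      label = integer(), x_um = numeric(), y_um = numeric(), z_um = numeric(),
      axis_a_um = numeric(), axis_b_um = numeric(), axis_c_um = numeric(),
      dir_x = numeric(), dir_y = numeric(), dir_z = numeric(),
      volume_um3 = numeric()
    ))
  }
  coords <- arrayInd(idx, dim(stack))
  labels <- stack[idx]
  n_degenerate <- 0L
  rows <- lapply(split(seq_along(idx), labels), function(ii) {
    # voxel centres in µm, array dims taken as (x, y, z) index order
    pts <- (coords[ii, , drop = FALSE] - 0.5) * voxel_um
    vol <- length(ii) * voxel_um^3
    fit <- tryCatch(fit_ellipsoid(pts), error = function(e) NULL)
    if (is.null(fit)) {
      n_degenerate <<- n_degenerate + 1L
      ctr <- colMeans(pts)
      return(tibble::tibble(
        x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
        axis_a_um = NA_real_, axis_b_um = NA_real_, axis_c_um = NA_real_,
        dir_x = NA_real_, dir_y = NA_real_, dir_z = NA_real_,
        volume_um3 = vol
      ))
    }
    tibble::tibble(
      x_um = fit$center[1], y_um = fit$center[2], z_um = fit$center[3],
      axis_a_um = fit$a, axis_b_um = fit$b, axis_c_um = fit$c,
      dir_x = fit$axes[1, 1], dir_y = fit$axes[2, 1], dir_z = fit$axes[3, 1],
      volume_um3 = vol
    )
  })
  if (n_degenerate > 0) {
    warning(sprintf("%d label(s) with degenerate geometry: shape set to NA",
                    n_degenerate), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(
    tibble::tibble(label = as.integer(names(split(seq_along(idx), labels)))),
    out
  )
  out[order(out$label), ]
}

#' Rasterize cells into a 3D label stack
#'
#' Paints each cell's ellipsoid into a 16-bit-style integer array (one label
#' per cell, 0 = background) at an isotropic voxel size. Where ellipsoids
#' overlap, the later cell wins.
#'
#' @param cells Data frame of cells.
#' @param voxel_um Isotropic voxel size in µm (default 2).
#' @param pad_um Padding added around the bounding box.
#' @return Integer 3D array with attribute `voxel_um`.
#' @export
rasterize_cells <- function(cells, voxel_um = 2, pad_um = 10) {
  stopifnot(nrow(cells) > 0)
  lo <- c(min(cells$x_um - cells$axis_a_um), min(cells$y_um - cells$axis_a_um),
          min(cells$z_um - cells$axis_a_um)) - pad_um
  hi <- c(max(cells$x_um + cells$axis_a_um), max(cells$y_um + cells$axis_a_um),
          max(cells$z_um + cells$axis_a_um)) + pad_um
  dims <- pmax(ceiling((hi - lo) / voxel_um), 1)
  stack <- array(0L, dims)
  for (i in seq_len(nrow(cells))) {
    vox <- ellipsoid_voxels(cells[i, ], lo, dims, voxel_um)
    if (length(vox)) stack[vox] <- i
  }
  attr(stack, "voxel_um") <- voxel_um
  attr(stack, "origin_um") <- lo
  stack
}

# linear indices of voxels whose centres fall inside a cell's ellipsoid
ellipsoid_voxels <- function(cell, lo, dims, voxel_um) {
  ctr <- c(cell$x_um, cell$y_um, cell$z_um)
  a <- cell$axis_a_um
  rng <- lapply(1:3, function(k) {
    i0 <- max(1, floor((ctr[k] - a - lo[k]) / voxel_um))
    i1 <- min(dims[k], ceiling((ctr[k] + a - lo[k]) / voxel_um))
    if (i0 > i1) integer(0) else i0:i1
  })
  if (any(lengths(rng) == 0)) return(integer(0))
  grid <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  pts <- sweep((grid - 0.5) * voxel_um, 2, -lo)   # voxel centres, µm
  rel <- sweep(pts, 2, ctr)
  e_a <- c(cell$dir_x, cell$dir_y, cell$dir_z)
  # complete an orthonormal triad around the long axis
  ref <- if (abs(e_a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e_b <- crossprod3(e_a, ref); e_b <- e_b / sqrt(sum(e_b^2))
  e_c <- crossprod3(e_a, e_b)
  q <- (rel %*% e_a / a)^2 + (rel %*% e_b / cell$axis_b_um)^2 +
    (rel %*% e_c / cell$axis_c_um)^2
  inside <- q <= 1
  if (!any(inside)) return(integer(0))
  g <- grid[inside, , drop = FALSE]
  (g[, 3] - 1) * dims[1] * dims[2] + (g[, 2] - 1) * dims[1] + g[, 1]
}

#' Write or read a 16-bit multi-page label TIFF
#'
#' Thin wrappers over the `tiff` package (one page per z-plane, labels
#' scaled through the 16-bit range).
#' @param stack Integer 3D array.
#' @param path File path.
#' @return `read_label_tiff()` returns an integer 3D array.
#' @export
write_label_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF output", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    stack[, , k] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF input", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(round(pages[[k]] * 65535))
  arr
}

#' Write and reread the per-stage summary table
#'
#' One row per parameter, one column per stage; missing entries are `NA`.
#'
#' @param summary Tibble with a `parameter` column and one column per stage.
#' @param path File path.
#' @return `read_summary_table()` returns the tibble back.
#' @export
write_summary_table <- function(summary, path) {
  readr::write_tsv(summary, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    parameter = readr::col_character(), .default = readr::col_character()
  ), na = "NA", progress = FALSE, show_col_types = FALSE)
}
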