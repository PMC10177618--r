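#' Stage snapshots of labelled cell ensembles
#'
#' A `psm_snapshot` is a tibble with one row per labelled cell and the
#' column set of the cell-table dialect (see [read_cell_table()]), plus
#' attributes carrying the embryo [axis_frame()], the axolotl stage, any
#' mitotic [division events][spindle_ap_fraction()] and an optional embryo
#' outline polyline. All lengths are in µm, volumes in µm³.
#'
#' Region labels are one of `PZ`, `posterior_PSM`, `medial_PSM`,
#' `anterior_PSM`, `somite_<k>`, `NT`, `epidermis`, `LPM`, `endoderm`.
#' Mesodermal regions (everything from `PZ` through somites) are the ones
#' entering the morphometric statistics.
#'
#' @param cells Tibble of cells in the dialect column set.
#' @param stage Integer axolotl stage.
#' @param frame An [axis_frame()].
#' @param divisions Optional tibble of mitotic events with columns
#'   `id`, `c1x`, `c1y`, `c1z`, `c2x`, `c2y`, `c2z` (centriole positions, µm).
#' @param outline Optional 2- or 3-column matrix, embryo outline polyline (µm).
#'
#' @return A `psm_snapshot` tibble.
#' @export
psm_snapshot <- function(cells, stage, frame = axis_frame(),
                         divisions = NULL, outline = NULL) {
  cells <- validate_cells(tibble::as_tibble(cells))
  structure(
    cells,
    stage = as.integer(stage),
    frame = frame,
    divisions = divisions,
    outline = outline,
    class = c("psm_snapshot", class(tibble::tibble()))
  )
}

CELL_COLUMNS <- c("id", "stage", "region", "origin", "sox2",
                  "x_um", "y_um", "z_um",
                  "axis_a_um", "axis_b_um", "axis_c_um",
                  "dir_x", "dir_y", "dir_z",
                  "volume_um3", "filopodia_lengths")

MESODERM_REGIONS <- c("PZ", "posterior_PSM", "medial_PSM", "anterior_PSM")

KNOWN_REGIONS <- c(MESODERM_REGIONS, "NT", "epidermis", "LPM", "endoderm")

is_mesodermal <- function(region) {
  region %in% MESODERM_REGIONS | grepl("^somite_[0-9]+$", region)
}

validate_cells <- function(cells, context = "cell table") {
  missing <- setdiff(CELL_COLUMNS, names(cells))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cells <- cells[, CELL_COLUMNS]
  if (nrow(cells) == 0) return(cells)
  coords <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  bad <- which(!apply(is.finite(coords), 1, all))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-finite coordinates in row(s) %s", context,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  with(cells, {
    if (any(axis_a_um < axis_b_um - 1e-9 | axis_b_um < axis_c_um - 1e-9)) {
      stop(sprintf("%s: semi-axes must satisfy a >= b >= c", context),
           call. = FALSE)
    }
    if (any(axis_c_um <= 0)) {
      stop(sprintf("%s: semi-axes must be positive", context), call. = FALSE)
    }
    if (any(volume_um3 <= 0)) {
      stop(sprintf("%s: volumes must be positive", context), call. = FALSE)
    }
  })
  nrm <- sqrt(cells$dir_x^2 + cells$dir_y^2 + cells$dir_z^2)
  if (any(abs(nrm - 1) > 1e-6)) {
    stop(sprintf("%s: long-axis direction vectors must have unit norm", context),
         call. = FALSE)
  }
  unknown <- setdiff(unique(cells$region),
                     c(KNOWN_REGIONS,
                       grep("^somite_[0-9]+$", unique(cells$region),
                            value = TRUE)))
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown region label(s): %s", context,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  fil <- parse_filopodia(cells$filopodia_lengths)
  lens <- unlist(fil)
  if (length(lens) > 0 && (any(lens <= 0) || any(lens > 40))) {
    stop(sprintf("%s: filopodia lengths must lie in (0, 40] um", context),
         call. = FALSE)
  }
  cells
}

#' @export
print.psm_snapshot <- function(x, ...) {
  cat(sprintf("<psm_snapshot> stage %d, %d cells (%d mesodermal), graft side %s\n",
              attr(x, "stage"), nrow(x), sum(is_mesodermal(x$region)),
              attr(x, "frame")$graft_side))
  NextMethod()
}

snapshot_stage <- function(snapshot) attr(snapshot, "stage")
snapshot_frame <- function(snapshot) attr(snapshot, "frame") %||% axis_frame()
snapshot_divisions <- function(snapshot) attr(snapshot, "divisions")

parse_filopodia <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

format_filopodia <- function(lengths) {
  vapply(lengths, function(v) paste(format(v, digits = 7, trim = TRUE),
                                    collapse = ";"), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
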