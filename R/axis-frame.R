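#' Embryo coordinate frame
#'
#' An `axis_frame` fixes the embryo coordinate system used throughout the
#' package: `ap` points posteriorly along the anteroposterior axis, `ml`
#' points to the embryo's right along the mediolateral axis and `dv` points
#' dorsally. The origin sits at the anterior-most point of the embryo and the
#' midline is the plane `ml == 0`. The three axes must form a right-handed
#' orthonormal triad.
#'
#' @param origin Numeric length-3, anterior-most point (µm).
#' @param ap,ml,dv Numeric length-3 unit vectors.
#' @param graft_side `"left"` or `"right"`; side carrying the graft.
#'
#' @return An object of class `axis_frame`.
#' @examples
#' axis_frame()
#' @export
axis_frame <- function(origin = c(0, 0, 0),
                       ap = c(1, 0, 0),
                       ml = c(0, 1, 0),
                       dv = c(0, 0, 1),
                       graft_side = "left") {
  origin <- as.numeric(origin)
  ap <- as.numeric(ap); ml <- as.numeric(ml); dv <- as.numeric(dv)
  stopifnot(length(origin) == 3, length(ap) == 3, length(ml) == 3,
            length(dv) == 3)
  graft_side <- match.arg(graft_side, c("left", "right"))
  for (v in list(ap, ml, dv)) {
    if (abs(sqrt(sum(v^2)) - 1) > 1e-9) {
      stop("axis vectors must have unit norm", call. = FALSE)
    }
  }
  dots <- c(abs(sum(ap * ml)), abs(sum(ap * dv)), abs(sum(ml * dv)))
  if (any(dots >= 1e-9)) {
    stop("axis vectors must be mutually orthogonal", call. = FALSE)
  }
  if (sum(crossprod3(ap, ml) * dv) <= 0) {
    stop("axis frame must be right-handed (ap x ml = dv)", call. = FALSE)
  }
  structure(
    list(origin = origin, ap = ap, ml = ml, dv = dv, graft_side = graft_side),
    class = "axis_frame"
  )
}

#' @export
print.axis_frame <- function(x, ...) {
  cat("<axis_frame>\n")
  cat("  origin:", format(x$origin), "\n")
  cat("  AP:", format(x$ap), " ML:", format(x$ml), " DV:", format(x$dv), "\n")
  cat("  graft side:", x$graft_side, "\n")
  invisible(x)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# project cell centroids onto frame axes, returning a 3-column matrix of
# AP/ML/DV coordinates relative to the frame origin
frame_coords <- function(cells, frame) {
  xyz <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  xyz <- sweep(xyz, 2, frame$origin)
  cbind(ap = xyz %*% frame$ap, ml = xyz %*% frame$ml, dv = xyz %*% frame$dv)
}
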