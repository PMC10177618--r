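#' Generate one synthetic stage snapshot
#'
#' Draws the configured number of labelled cells per region for one stage,
#' with per-region ellipsoid shapes, orientations, volumes and filopodia, and
#' a set of mitotic division events with the configured anteroposterior
#' spindle fraction. Identical `(config, stage, seed)` give bit-identical
#' snapshots.
#'
#' @param config A [generator_config()].
#' @param stage Stage id present in `config$counts`.
#' @param seed Integer seed.
#' @return A [psm_snapshot()].
#' @examples
#' snap <- generate_stage_snapshot(lifeact_config(), 22, seed = 1)
#' dplyr::count(snap, region)
#' @export
generate_stage_snapshot <- function(config, stage, seed = 1) {
  st <- as.character(stage)
  if (!st %in% names(config$counts)) {
    stop(sprintf("unknown stage '%s': no counts configured", st),
         call. = FALSE)
  }
  withr::with_seed(seed, build_snapshot(config, st))
}

build_snapshot <- function(config, st, origin_label = "host",
                           span_override = NULL, leader = FALSE,
                           counts = NULL) {
  geom <- config$stages[[st]]
  arc <- arc_polyline(geom$control)
  counts <- counts %||% config$counts[[st]]
  frame <- axis_frame(graft_side = "left")
  cells <- list()
  for (key in names(counts)) {
    n <- counts[[key]]
    if (n == 0) next
    if (!key %in% names(config$regions)) {
      stop(sprintf("no region parameters configured for '%s'", key),
           call. = FALSE)
    }
    span <- geom$spans[[key]] %||% c(0, 1)
    if (!is.null(span_override)) {
      span <- c(max(span[1], span_override[1]), min(span[2], span_override[2]))
      if (span[1] >= span[2]) next
    }
    cells[[key]] <- build_region_cells(config, geom, arc, key, n, span,
                                       st, origin_label, leader)
  }
  cells <- if (length(cells)) dplyr::bind_rows(cells) else empty_cells()
  if (nrow(cells) > 0) cells$id <- sprintf("c%04d", seq_len(nrow(cells)))
  div <- build_divisions(config, st, cells)
  psm_snapshot(cells, stage = as.integer(st), frame = frame, divisions = div)
}

build_region_cells <- function(config, geom, arc, key, n, span, st,
                               origin_label, leader = FALSE) {
  reg <- config$regions[[key]]
  L <- arc$length
  s <- stats::runif(n, span[1], span[2]) * L
  if (leader) s[1] <- span[1] * L   # deterministic substream leader
  if (config$placement == "tube" || key == "NT") {
    base <- arc_point(arc, s)
    disc <- runif_disc(n)
    y <- -geom$ml_offset_um + disc[, 1] * geom$half_width_um
    z <- base[, 2] + disc[, 2] * geom$half_height_um
    x <- base[, 1]
    if (key == "NT") { y <- stats::rnorm(n, 0, 10); z <- base[, 2] + geom$half_height_um + 30 }
  } else {
    mid <- mean(span) * L
    anchor_s <- (floor(mid / config$section_um) + 0.5) * config$section_um
    anchor <- arc_point(arc, min(max(anchor_s, 0), L))
    off <- standardized_gauss(n, reg$sigma_um)
    x <- anchor[, 1] + off[, 1]
    y <- -geom$ml_offset_um + off[, 2]
    z <- anchor[, 2] + off[, 3]
  }
  # contralateral crossing: mirrored in ML across the midline plane
  if (origin_label %in% c("median", "entire") && config$contra_frac > 0) {
    cross <- stats::runif(n) < config$contra_frac
    y[cross] <- -y[cross]
  }
  shp <- draw_shapes(config, reg, n, st)
  label <- rep(key, n)
  if (key == "somite") {
    k <- max(geom$n_somites, 1L)
    idx <- pmin(floor((s / L - span[1]) / diff(span) * k) + 1L, k)
    label <- paste0("somite_", k - idx + 1L)  # somite_1 is posterior-most
  }
  filo <- draw_filopodia(reg, n)
  tibble::tibble(
    id = NA_character_, stage = as.integer(st), region = label,
    origin = origin_label, sox2 = key == "NT",
    x_um = x, y_um = y, z_um = z,
    axis_a_um = shp$a, axis_b_um = shp$b, axis_c_um = shp$c,
    dir_x = shp$dir[, 1], dir_y = shp$dir[, 2], dir_z = shp$dir[, 3],
    volume_um3 = shp$vol, filopodia_lengths = filo
  )
}

# couple the orientation class with the aspect-ratio threshold: unclassified
# cells draw AR below min_ar, classified cells above it with the long axis
# inside the arg-max region of the drawn class, so the classifier recovers
# the configured class fractions exactly and the marginal AR distribution
# stays the configured truncated log-normal
draw_shapes <- function(config, reg, n, st) {
  probs <- reg$orientation
  cls <- sample(names(probs), n, replace = TRUE, prob = probs)
  ar <- numeric(n)
  uncl <- cls == "unclassified"
  ar[uncl] <- rlnorm_trunc(sum(uncl), reg$ar_mean, reg$ar_sd,
                           lo = 1, hi = config$min_ar)
  ar[!uncl] <- rlnorm_trunc(sum(!uncl), reg$ar_mean, reg$ar_sd,
                            lo = config$min_ar, hi = Inf)
  dir <- matrix(0, n, 3)
  dir[uncl, ] <- runif_sphere(sum(uncl))
  for (ax in c("AP", "ML", "DV")) {
    k <- which(cls == ax)
    if (length(k)) dir[k, ] <- runif_axis_class(length(k), ax)
  }
  v_mean <- config$mean_cell_volume_um3[[st]] %||% 4000
  vol <- rlnorm_trunc(n, v_mean, v_mean * config$cell_volume_cv, lo = 0)
  u <- stats::runif(n, 1, ar)              # mid axis b/c uniform in [1, a/c]
  cc <- (3 * vol / (4 * pi * ar * u))^(1 / 3)
  list(a = ar * cc, b = u * cc, c = cc, dir = dir, vol = vol)
}

draw_filopodia <- function(reg, n) {
  counts <- stats::rpois(n, reg$filo_count_mean)
  format_filopodia(lapply(counts, function(k) {
    if (k == 0) return(numeric(0))
    rlnorm_trunc(k, reg$filo_len_mean, reg$filo_len_sd, lo = 0, hi = 40)
  }))
}

build_divisions <- function(config, st, cells) {
  n <- config$n_divisions[[st]] %||% 0
  meso <- cells[is_mesodermal(cells$region), , drop = FALSE]
  if (n == 0 || nrow(meso) == 0) return(NULL)
  idx <- sample(nrow(meso), n, replace = n > nrow(meso))
  dirs <- draw_spindle_dirs(n, config$spindle_ap[[st]] %||% 0,
                            config$cone_deg)
  half <- 5  # centriole half-separation, um
  tibble::tibble(
    id = meso$id[idx],
    c1x = meso$x_um[idx] - half * dirs[, 1],
    c1y = meso$y_um[idx] - half * dirs[, 2],
    c1z = meso$z_um[idx] - half * dirs[, 3],
    c2x = meso$x_um[idx] + half * dirs[, 1],
    c2y = meso$y_um[idx] + half * dirs[, 2],
    c2z = meso$z_um[idx] + half * dirs[, 3]
  )
}

#' Generate standalone mitotic division events
#'
#' Spindle directions are drawn inside the AP cone with probability
#' `ap_fraction` (folded angle to the AP axis at most `cone_deg`) and
#' uniformly outside it otherwise, so [spindle_ap_fraction()] with the same
#' cone angle recovers the configured fraction.
#'
#' @param n Number of events.
#' @param ap_fraction Target AP-oriented fraction.
#' @param cone_deg Cone half-angle (degrees).
#' @param seed Integer seed.
#' @param centers Optional n x 3 matrix of cell centres (default origin).
#' @return Tibble of division events.
#' @export
generate_division_events <- function(n, ap_fraction, cone_deg = 30, seed = 1,
                                     centers = NULL) {
  withr::with_seed(seed, {
    dirs <- draw_spindle_dirs(n, ap_fraction, cone_deg)
    if (is.null(centers)) centers <- matrix(0, n, 3)
    half <- 5
    tibble::tibble(
      id = sprintf("d%05d", seq_len(n)),
      c1x = centers[, 1] - half * dirs[, 1],
      c1y = centers[, 2] - half * dirs[, 2],
      c1z = centers[, 3] - half * dirs[, 3],
      c2x = centers[, 1] + half * dirs[, 1],
      c2y = centers[, 2] + half * dirs[, 2],
      c2z = centers[, 3] + half * dirs[, 3]
    )
  })
}

draw_spindle_dirs <- function(n, ap_fraction, cone_deg) {
  ct <- cos(cone_deg * pi / 180)
  inside <- stats::runif(n) < ap_fraction
  cosang <- ifelse(inside, stats::runif(n, ct, 1), stats::runif(n, 0, ct))
  phi <- stats::runif(n, 0, 2 * pi)
  sinang <- sqrt(pmax(0, 1 - cosang^2))
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  cbind(sgn * cosang, sinang * cos(phi), sinang * sin(phi))
}

#' Generate a graft series from one posterior neural plate origin
#'
#' Labelled cells carry the origin label and occupy origin-specific arc
#' spans: at equal stages, median-origin cells reach the furthest anterior
#' (smallest minimum AP coordinate), lateral-origin cells the least, with the
#' paramedian origin in between; the ordering is guaranteed for every seed by
#' a deterministic substream leader cell pinned at the span's anterior
#' boundary. Only `median` and `entire` origins place cells across the
#' midline.
#'
#' @param config A [generator_config()].
#' @param origin One of `median`, `paramedian`, `lateral`, `left_half`,
#'   `entire`.
#' @param stages Stage ids (default 28 and 30).
#' @param seed Integer seed.
#' @return Named list of [psm_snapshot()]s, one per stage.
#' @export
generate_graft_series <- function(config, origin, stages = c(28, 30),
                                  seed = 1) {
  origin <- match.arg(origin,
                      c("median", "paramedian", "lateral", "left_half",
                        "entire"))
  spans <- list(
    `28` = list(median = c(0.05, 0.55), paramedian = c(0.15, 0.95),
                lateral = c(0.55, 1), left_half = c(0, 1), entire = c(0, 1)),
    `30` = list(median = c(0.00, 0.45), paramedian = c(0.10, 0.85),
                lateral = c(0.20, 1), left_half = c(0, 1), entire = c(0, 1))
  )
  out <- lapply(seq_along(stages), function(i) {
    st <- as.character(stages[i])
    if (!st %in% names(config$stages)) {
      stop(sprintf("unknown stage '%s'", st), call. = FALSE)
    }
    span <- (spans[[st]] %||% spans[["30"]])[[origin]]
    counts <- graft_counts(config, st, span)
    withr::with_seed(seed + i,
      build_snapshot(config, st, origin_label = origin,
                     span_override = span, leader = TRUE, counts = counts))
  })
  stats::setNames(out, as.character(stages))
}

# distribute the labelled graft cells over the regions whose stage spans
# overlap the origin's reach, proportionally to the overlap
graft_counts <- function(config, st, span) {
  geom <- config$stages[[st]]
  overlap <- vapply(geom$spans, function(sp) {
    max(0, min(sp[2], span[2]) - max(sp[1], span[1]))
  }, numeric(1))
  overlap <- overlap[overlap > 0]
  n <- config$graft_cells
  cnt <- round(n * overlap / sum(overlap))
  cnt[1] <- cnt[1] + n - sum(cnt)
  as.list(cnt)
}

#' Spread cells mediolaterally as after epidermis removal
#'
#' Multiplies the mediolateral dispersion (about each affected group's ML
#' centre) of posterior-zone and posterior-PSM cells on the deprived side(s)
#' by `spread_factor`; anterior PSM and all other regions are untouched and
#' the cell count is conserved. With `spread_factor = 1` the snapshot is
#' returned unchanged. The transform is a deterministic affine scaling;
#' `seed` is accepted for interface compatibility.
#'
#' @param snapshot A [psm_snapshot()].
#' @param side `"left"`, `"right"` or `"bilateral"`.
#' @param spread_factor Multiplier >= 1 for the ML dispersion.
#' @param seed Unused.
#' @return The modified snapshot.
#' @export
apply_epidermis_removal <- function(snapshot, side = c("left", "right",
                                                       "bilateral"),
                                    spread_factor = 1, seed = NULL) {
  side <- match.arg(side)
  stopifnot(spread_factor >= 1)
  if (spread_factor == 1 || nrow(snapshot) == 0) return(snapshot)
  affected_region <- snapshot$region %in% c("PZ", "posterior_PSM")
  for (sd in if (side == "bilateral") c("left", "right") else side) {
    sel0 <- affected_region &
      (if (sd == "left") snapshot$y_um < 0 else snapshot$y_um > 0)
    for (reg in unique(snapshot$region[sel0])) {
      sel <- sel0 & snapshot$region == reg
      ctr <- mean(snapshot$y_um[sel])
      snapshot$y_um[sel] <- ctr + spread_factor * (snapshot$y_um[sel] - ctr)
    }
  }
  snapshot
}

#' Whole-embryo displacement timecourse for one labelled tissue
#'
#' Returns, per stage, the ventral body-contour polyline (whose total length
#' follows the embryo length schedule) and the displaced label centroid.
#' Epidermal labels keep their absolute arc-length position; paraxial
#' mesoderm and lateral plate labels shift anteriorly (non-increasing arc
#' length) from the first stage on; endodermal labels only start shifting
#' after stage 30.
#'
#' @param config A [generator_config()] (unused fields are ignored).
#' @param tissue One of `paraxial`, `epidermis`, `LPM`, `endoderm`.
#' @param label_site Initial axial position as a fraction of the first
#'   stage's contour length, in `[0, 1]`.
#' @param stages Increasing stage ids.
#' @param seed Integer seed (small anterior-drift jitter for displaced
#'   tissues).
#' @param drift Per-stage-unit anterior drift rate of displaced tissues.
#' @return Tibble: `stage`, `a_um`, `b_um`, `d_rel`, list-columns `outline`
#'   (polyline matrix) and `centroid`.
#' @export
generate_embryo_timecourse <- function(config = generator_config(),
                                       tissue = c("paraxial", "epidermis",
                                                  "LPM", "endoderm"),
                                       label_site = 0.5,
                                       stages = c(22, 28, 30, 35, 40),
                                       seed = 1, drift = 0.04) {
  tissue <- match.arg(tissue)
  if (label_site < 0 || label_site > 1) {
    stop("label_site must lie in [0, 1]", call. = FALSE)
  }
  stages <- sort(stages)
  withr::with_seed(seed, {
    b <- body_length_um(stages)
    a0 <- label_site * b[1]
    onset <- switch(tissue, epidermis = Inf, endoderm = 30, stages[1])
    rate <- if (is.finite(onset)) drift * stats::runif(1, 0.8, 1.2) else 0
    a <- vapply(stages, function(s) {
      dt <- max(0, s - max(onset, stages[1]))
      a0 * exp(-rate * dt)
    }, numeric(1))
    a <- cummin(a)
    tibble::tibble(
      stage = stages, a_um = a, b_um = b, d_rel = ifelse(b > 0, a / b, 0),
      outline = lapply(b, straight_outline),
      centroid = lapply(seq_along(a), function(i) c(a[i], 0))
    )
  })
}

# embryo length schedule: ~2.1 mm up to stage 14, 9.3 mm at stage 40,
# linear in between (the printed schedule gives only the end points)
body_length_um <- function(stage) {
  pmax(2100, 2100 + (9300 - 2100) * (stage - 14) / (40 - 14))
}

straight_outline <- function(length_um, n = 51) {
  cbind(x = seq(0, length_um, length.out = n), y = rep(0, n))
}

#' Generate sphere-grouped cell sets at configured closest-neighbour scales
#'
#' Emulates the density analysis grouping: for each region, `n` cells are
#' placed uniformly in a sphere whose radius is chosen from the Poisson
#' nearest-neighbour closed form so the expected NN median equals the
#' region's configured scale.
#'
#' @param config A [generator_config()].
#' @param regions Region keys (default: all mesodermal keys).
#' @param n Cells per group.
#' @param seed Integer seed.
#' @return Tibble with `region`, `x_um`, `y_um`, `z_um`.
#' @export
generate_density_groups <- function(config = generator_config(),
                                    regions = c("PZ", "posterior_PSM",
                                                "medial_PSM", "anterior_PSM",
                                                "somite"),
                                    n = 120, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(regions, function(key) {
      r_m <- config$regions[[key]]$nn_um
      R <- r_m * (n / log(2))^(1 / 3)
      u <- runif_ball(n) * R
      tibble::tibble(region = if (key == "somite") "somite_1" else key,
                     x_um = u[, 1], y_um = u[, 2], z_um = u[, 3])
    }))
  })
}

# --- low-level samplers and arc helpers ------------------------------------

# isotropic Gaussian displacements with the clone's empirical dispersion
# standardized to sigma exactly (variance-controlled placement: the clone's
# realized spread, not only its expectation, matches the calibrated scale)
standardized_gauss <- function(n, sigma) {
  if (n == 1) return(matrix(0, 1, 3))
  g <- matrix(stats::rnorm(3 * n), ncol = 3)
  g <- sweep(g, 2, colMeans(g))
  g * sigma / sqrt(sum(g^2) / (3 * (n - 1)))
}

runif_sphere <- function(n) {
  g <- matrix(stats::rnorm(3 * n), ncol = 3)
  g / sqrt(rowSums(g^2))
}

runif_ball <- function(n) {
  runif_sphere(n) * stats::runif(n)^(1 / 3)
}

runif_disc <- function(n) {
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# uniform directions within the arg-max spherical region of one frame axis
runif_axis_class <- function(n, axis) {
  col <- c(AP = 1, ML = 2, DV = 3)[[axis]]
  out <- matrix(NA_real_, n, 3)
  need <- n
  while (need > 0) {
    cand <- runif_sphere(max(2 * need, 16))
    ok <- max.col(abs(cand), ties.method = "first") == col
    take <- min(sum(ok), need)
    if (take > 0) {
      out[(n - need + 1):(n - need + take), ] <-
        cand[which(ok)[seq_len(take)], , drop = FALSE]
      need <- need - take
    }
  }
  out
}

# dense polyline along the configured PSM arc (spline through control points
# in the AP-DV plane), with cumulative arc length
arc_polyline <- function(control, n = 512) {
  x <- control[, 1]; z <- control[, 2]
  xs <- seq(min(x), max(x), length.out = n)
  zs <- if (all(z == z[1])) rep(z[1], n) else stats::spline(x, z, xout = xs)$y
  seg <- sqrt(diff(xs)^2 + diff(zs)^2)
  list(x = xs, z = zs, cum = c(0, cumsum(seg)), length = sum(seg))
}

# point(s) on the arc at arc length s (matrix with columns x, z)
arc_point <- function(arc, s) {
  s <- pmin(pmax(s, 0), arc$length)
  x <- stats::approx(arc$cum, arc$x, xout = s)$y
  z <- stats::approx(arc$cum, arc$z, xout = s)$y
  cbind(x, z)
}

empty_cells <- function() {
  tibble::tibble(
    id = character(), stage = integer(), region = character(),
    origin = character(), sox2 = logical(),
    x_um = numeric(), y_um = numeric(), z_um = numeric(),
    axis_a_um = numeric(), axis_b_um = numeric(), axis_c_um = numeric(),
    dir_x = numeric(), dir_y = numeric(), dir_z = numeric(),
    volume_um3 = numeric(), filopodia_lengths = character()
  )
}
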