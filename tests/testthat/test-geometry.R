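test_that("fit_ellipsoid recovers known shapes from sampled points", {
  # solid sphere, radius 10: voxel centres on a grid
  g <- seq(-9.5, 9.5, by = 1)
  vox <- as.matrix(expand.grid(g, g, g))
  vox <- vox[rowSums(vox^2) <= 100, ]
  fs <- fit_ellipsoid(vox)
  expect_true(all(abs(c(fs$a, fs$b, fs$c) - 10) / 10 < 0.03))

  # uniform samples inside a (20, 10, 5) ellipsoid
  pts <- sample_ellipsoid_points(50000, c(20, 10, 5), seed = 7)
  fe <- fit_ellipsoid(pts)
  expect_lt(abs(fe$a - 20) / 20, 0.03)
  expect_lt(abs(fe$b - 10) / 10, 0.03)
  expect_lt(abs(fe$c - 5) / 5, 0.03)
  # deterministic sign convention
  expect_true(all(apply(fe$axes, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("fit_ellipsoid rejects degenerate input", {
  expect_error(fit_ellipsoid(matrix(rnorm(9), 3, 3)), "at least 4")
  coplanar <- cbind(runif(20), runif(20), 0)
  expect_error(fit_ellipsoid(coplanar), "coplanar")
})

test_that("fit_ellipsoid is rotation-equivariant", {
  pts <- sample_ellipsoid_points(20000, c(15, 8, 4), seed = 11)
  f0 <- fit_ellipsoid(pts)
  R <- rotation_xyz(0.4, -0.9, 1.7)
  f1 <- fit_ellipsoid(pts %*% t(R))
  expect_equal(c(f1$a, f1$b, f1$c), c(f0$a, f0$b, f0$c), tolerance = 1e-6)
  for (k in 1:3) {
    v <- R %*% f0$axes[, k]
    # same line, possibly opposite sign before the convention flip
    expect_equal(abs(sum(v * f1$axes[, k])), 1, tolerance = 1e-6)
  }
})

test_that("aspect ratio is correct and scale-invariant", {
  pts <- sample_ellipsoid_points(30000, c(7, 3, 3), seed = 3)
  ar1 <- aspect_ratio(fit_ellipsoid(pts))
  ar2 <- aspect_ratio(fit_ellipsoid(pts * 12.5))
  expect_equal(ar1, 7 / 3, tolerance = 0.03)
  expect_equal(ar1, ar2, tolerance = 1e-12)
  cells <- make_cells(0, a = 7, b = 3, c = 3)
  expect_equal(aspect_ratio(cells), 7 / 3)
})

test_that("orientation classification follows the arg-max and threshold rules", {
  cells <- make_cells(c(0, 0, 0), a = 12, c = 4)
  dirs <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  cells$dir_x <- dirs[, 1]; cells$dir_y <- dirs[, 2]; cells$dir_z <- dirs[, 3]
  out <- classify_orientation(cells)
  expect_equal(as.character(out$orientation), c("ML", "DV", "AP"))

  round_cell <- make_cells(0, a = 4.4, b = 4.2, c = 4) # AR 1.1 < 1.3
  expect_equal(as.character(classify_orientation(round_cell)$orientation),
               "unclassified")

  # symmetry: uniform random long axes split evenly across the three classes
  n <- 100000
  d <- withr::with_seed(5, {
    g <- matrix(rnorm(3 * n), ncol = 3); g / sqrt(rowSums(g^2))
  })
  cells <- make_cells(rep(0, n), a = 8, c = 4)
  cells$dir_x <- d[, 1]; cells$dir_y <- d[, 2]; cells$dir_z <- d[, 3]
  fr <- table(classify_orientation(cells)$orientation) / n
  expect_true(all(abs(fr[c("AP", "ML", "DV")] - 1 / 3) < 0.01))
})

test_that("orientation fractions sum to one per region", {
  snap <- generate_stage_snapshot(TUBE_CFG, 28, seed = 4)
  fr <- orientation_fractions(snap[is_mesodermal(snap$region), ])
  sums <- tapply(fr$fraction, fr$region, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("spindle AP fraction matches the analytic solid-angle baseline", {
  n <- 100000
  d <- withr::with_seed(9, {
    g <- matrix(rnorm(3 * n), ncol = 3); g / sqrt(rowSums(g^2))
  })
  ev <- tibble::tibble(id = as.character(seq_len(n)),
                       c1x = -d[, 1], c1y = -d[, 2], c1z = -d[, 3],
                       c2x = d[, 1], c2y = d[, 2], c2z = d[, 3])
  frac <- spindle_ap_fraction(ev, cone_half_angle = 30)
  expect_lt(abs(frac - (1 - cos(30 * pi / 180))), 0.005)

  # all spindles exactly along AP
  ap <- tibble::tibble(id = "1", c1x = 0, c1y = 0, c1z = 0,
                       c2x = 10, c2y = 0, c2z = 0)
  expect_equal(spindle_ap_fraction(ap), 1)
})

test_that("spindle fraction is monotone in the cone angle and handles edge cases", {
  ev <- generate_division_events(2000, 0.3, seed = 2)
  angles <- c(10, 20, 30, 45, 60, 90)
  fr <- vapply(angles, function(a) spindle_ap_fraction(ev, cone_half_angle = a),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[length(fr)], 1) # 90 degrees covers the folded hemisphere

  expect_true(is.na(spindle_ap_fraction(NULL)))
  degen <- tibble::tibble(id = c("a", "b"),
                          c1x = c(0, 0), c1y = c(0, 0), c1z = c(0, 0),
                          c2x = c(0, 10), c2y = 0, c2z = 0)
  expect_warning(frac <- spindle_ap_fraction(degen), "coincident")
  expect_equal(frac, 1) # degenerate event excluded from the denominator
})

test_that("filopodia statistics pool lengths and count fractions correctly", {
  cells <- make_cells(c(0, 1, 2), filo = c("2;4;6", "", "1;2;3;4;5"))
  fs <- filopodia_stats(cells)
  expect_equal(fs$frac_ge1, 2 / 3)
  expect_equal(fs$frac_ge5, 1 / 3)
  expect_equal(fs$mean_length_um, mean(c(2, 4, 6, 1, 2, 3, 4, 5)))
  expect_equal(fs$max_length_um, 6)

  none <- make_cells(c(0, 1), filo = "")
  fs0 <- filopodia_stats(none)
  expect_equal(fs0$frac_ge1, 0)
  expect_true(is.na(fs0$mean_length_um) && is.na(fs0$max_length_um))
  expect_error(filopodia_stats(cells, region = "NT"), "no cells")
})

test_that("refit_cell_shapes reproduces stored shapes", {
  cells <- withr::with_seed(21, {
    snap <- generate_stage_snapshot(TUBE_CFG, 22, seed = 3)
    refit_cell_shapes(snap[1:50, ], points_per_cell = 2000)
  })
  expect_equal(cells$fit_a_um, cells$axis_a_um, tolerance = 0.08)
  expect_equal(cells$fit_c_um, cells$axis_c_um, tolerance = 0.08)
})
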