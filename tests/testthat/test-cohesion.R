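test_that("pairwise cohesion equals brute-force enumeration", {
  # two cells 10 um apart in one section
  two <- assign_sections(make_cells(c(5, 11), y = c(0, 8)), "AP", 80)
  res <- pairwise_cohesion(two)
  expect_equal(res$distances$distance_um, 10)
  expect_equal(res$median_um, 10)
  expect_equal(res$frac_lt25, 1)

  for (seed in 1:3) {
    cells <- withr::with_seed(seed, make_cells(
      runif(50, 0, 400), y = runif(50, -60, 0), z = runif(50, -40, 40)))
    cells$y_um <- withr::with_seed(seed + 10, runif(50, -60, 0))
    cells$z_um <- withr::with_seed(seed + 20, runif(50, -40, 40))
    sec <- assign_sections(cells, "AP", 80)
    res <- pairwise_cohesion(sec)
    oracle <- brute_pairs(sec)
    expect_equal(sort(res$distances$distance_um), sort(oracle))
    expect_equal(res$n_pairs, length(oracle))
    # per-section pair count identity: sum n_s (n_s - 1) / 2
    ns <- table(sec$section)
    expect_equal(res$n_pairs, sum(ns * (ns - 1) / 2))
  }
})

test_that("cohesion refuses groups without any co-sectioned pair", {
  lonely <- assign_sections(make_cells(c(10, 100, 250)), "AP", 80)
  expect_error(pairwise_cohesion(lonely), "insufficient pairs")
  expect_error(pairwise_cohesion(make_cells(1)), "section")
})

test_that("cohesion median is invariant under rigid motion", {
  cells <- withr::with_seed(4, make_cells(runif(40, 0, 300)))
  cells$y_um <- withr::with_seed(5, runif(40, -50, 0))
  cells$z_um <- withr::with_seed(6, runif(40, -30, 30))
  sec0 <- assign_sections(cells, "AP", 80)
  m0 <- pairwise_cohesion(sec0)$median_um

  R <- rotation_xyz(0.3, 1.1, -0.7)
  shift <- c(120, -40, 60)
  rot <- cells
  xyz <- as.matrix(cells[, c("x_um", "y_um", "z_um")]) %*% t(R)
  rot$x_um <- xyz[, 1] + shift[1]
  rot$y_um <- xyz[, 2] + shift[2]
  rot$z_um <- xyz[, 3] + shift[3]
  frame2 <- axis_frame(origin = shift, ap = R[, 1], ml = R[, 2], dv = R[, 3])
  sec1 <- assign_sections(rot, "AP", 80, frame2)
  m1 <- pairwise_cohesion(sec1)$median_um
  expect_equal(m1, m0, tolerance = 1e-9)
})

test_that("planar cohesion drops the section-axis component", {
  cells <- make_cells(c(10, 40), y = c(0, 0), z = c(0, 0))
  cells$y_um <- c(0, 30)
  sec <- assign_sections(cells, "AP", 80)
  expect_equal(pairwise_cohesion(sec)$median_um, sqrt(30^2 + 30^2))
  expect_equal(pairwise_cohesion(sec, planar = TRUE)$median_um, 30)
})

test_that("nearest-neighbour density matches brute force and the 3-cell example", {
  tri <- make_cells(c(0, 10, 25))
  expect_equal(nearest_neighbour_density(tri)$nn_um, c(10, 10, 15))

  cells <- withr::with_seed(8, make_cells(runif(200, 0, 200)))
  cells$y_um <- withr::with_seed(9, runif(200, 0, 200))
  cells$z_um <- withr::with_seed(10, runif(200, 0, 200))
  res <- nearest_neighbour_density(cells)
  expect_equal(res$nn_um, brute_nn(cells))
  # NN distance never exceeds any pairwise distance involving the cell
  sec <- assign_sections(cells, "AP", 1e6)
  pc <- pairwise_cohesion(sec)
  expect_lte(max(res$nn_um), max(pc$distances$distance_um))
  expect_lte(min(res$nn_um), min(pc$distances$distance_um))
  expect_error(nearest_neighbour_density(make_cells(1)), "at least 2")
})

test_that("region assignment matches analytic binning on a straight arc", {
  cells <- make_cells(withr::with_seed(2, runif(300, 0, 300)))
  bp <- c(100, 200)
  labs <- c("anterior_PSM", "medial_PSM", "posterior_PSM")
  out <- assign_regions(cells, bp, labs,
                        control = cbind(x = c(0, 100, 200, 300), z = 0))
  oracle <- labs[findInterval(cells$x_um, bp) + 1]
  expect_equal(out$region, oracle)

  # a cell exactly on a breakpoint joins the more posterior region
  tie <- assign_regions(make_cells(100), bp, labs,
                        control = cbind(x = c(0, 300), z = 0))
  expect_equal(tie$region, "medial_PSM")

  far <- make_cells(c(-50, 350))
  expect_warning(out2 <- assign_regions(far, bp, labs,
                                        control = cbind(x = c(0, 300), z = 0)),
                 "terminal")
  expect_equal(out2$region, c("anterior_PSM", "posterior_PSM"))
})

test_that("every mesodermal cell of a generated snapshot gets a region", {
  snap <- generate_stage_snapshot(TUBE_CFG, 28, seed = 11)
  meso <- snap[is_mesodermal(snap$region), ]
  L <- TUBE_CFG$stages[["28"]]$arc_length_um
  out <- assign_regions(meso, c(0.3, 0.55, 0.8) * L,
                        c("anterior_PSM", "medial_PSM", "posterior_PSM", "PZ"),
                        control = TUBE_CFG$stages[["28"]]$control)
  expect_true(all(out$region %in% c("anterior_PSM", "medial_PSM",
                                    "posterior_PSM", "PZ")))
  # regions along the straight default arc agree with the generating labels
  expect_gt(mean(out$region == meso$region), 0.95)
})

test_that("epidermis-condition comparison flags only the deprived side", {
  snap <- generate_stage_snapshot(TUBE_CFG, 28, seed = 13)
  treated <- apply_epidermis_removal(snap, "left", 1.5)
  # spreading can push a few cells across the midline, creating new
  # treated-only side groups that are skipped with a warning
  cmp <- suppressWarnings(compare_epidermis_conditions(snap, treated))
  trt <- cmp[cmp$side == "left" & cmp$region %in% c("PZ", "posterior_PSM"), ]
  expect_true(all(trt$direction == "increase"))
  rest <- cmp[cmp$region == "anterior_PSM" | cmp$side == "right", ]
  expect_true(all(rest$delta_um == 0))

  same <- compare_epidermis_conditions(snap, snap)
  expect_true(all(same$delta_um == 0))

  missing <- snap[snap$region != "PZ", ]
  expect_warning(compare_epidermis_conditions(snap, missing), "skipping")
})
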