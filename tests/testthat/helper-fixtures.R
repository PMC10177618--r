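# Shared fixtures: configs are built once per run (cluster-mode construction
# solves the cohesion scales numerically, which takes a few seconds).
TUBE_CFG <- generator_config()
LIFEACT_CFG <- lifeact_config()

# small hand-built cell table used by io and metric tests
make_cells <- function(x, y = 0, z = 0, a = 10, b = 8, c = 6,
                       region = "PZ", dir = c(1, 0, 0), filo = "",
                       sox2 = FALSE) {
  n <- length(x)
  tibble::tibble(
    id = sprintf("t%03d", seq_len(n)), stage = 22L,
    region = rep_len(region, n), origin = "host",
    sox2 = rep_len(sox2, n),
    x_um = x, y_um = rep_len(y, n), z_um = rep_len(z, n),
    axis_a_um = rep_len(a, n), axis_b_um = rep_len(b, n),
    axis_c_um = rep_len(c, n),
    dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
    volume_um3 = 4 / 3 * pi * rep_len(a, n) * rep_len(b, n) * rep_len(c, n),
    filopodia_lengths = rep_len(filo, n)
  )
}

# brute-force in-section pair distances (independent of pairwise_cohesion)
brute_pairs <- function(cells) {
  out <- numeric(0)
  for (sec in unique(cells$section)) {
    idx <- which(cells$section == sec)
    if (length(idx) < 2) next
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in (i + 1):length(idx)) {
        a <- idx[i]; b <- idx[j]
        out <- c(out, sqrt((cells$x_um[a] - cells$x_um[b])^2 +
                           (cells$y_um[a] - cells$y_um[b])^2 +
                           (cells$z_um[a] - cells$z_um[b])^2))
      }
    }
  }
  out
}

# brute-force nearest-neighbour distances
brute_nn <- function(cells) {
  n <- nrow(cells)
  vapply(seq_len(n), function(i) {
    min(vapply(setdiff(seq_len(n), i), function(j) {
      sqrt((cells$x_um[i] - cells$x_um[j])^2 +
           (cells$y_um[i] - cells$y_um[j])^2 +
           (cells$z_um[i] - cells$z_um[j])^2)
    }, numeric(1)))
  }, numeric(1))
}

rotation_xyz <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
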