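#' Generator configuration for synthetic tail-bud ensembles
#'
#' Builds the full parameter set driving the synthetic generator. Defaults
#' are calibrated to the measured statistics of axolotl posterior neural
#' plate grafting experiments: per-stage labelled mesodermal and neural cell
#' counts, per-region aspect-ratio moments, orientation-class probabilities,
#' in-section cohesion medians, closest-neighbour scales, filopodia count and
#' length distributions, per-stage anteroposterior mitotic-spindle fractions,
#' the tissue-dimension schedule (arc length, tube height/width), the
#' labelled-tissue volume schedule and the mean-cell-volume schedule.
#'
#' Two placement modes exist. `"tube"` spreads each region's cells uniformly
#' through that region's segment of the PSM tube and models dense half-plate
#' grafts (the large counted ensembles). `"cluster"` drops a small
#' labelled clone as an isotropic Gaussian cloud about a jittered anchor in
#' the region; its standard deviation is solved numerically so the expected
#' in-section median pairwise distance equals the configured cohesion scale
#' (see [calibrate_cohesion_sigma()]). [lifeact_config()] is the cluster-mode
#' preset emulating small actin-reporter grafts.
#'
#' @param counts Named list: for each stage (character key), a named integer
#'   vector of mesodermal cells per region plus optionally `NT`.
#' @param placement `"tube"` or `"cluster"`.
#' @param regions Named list of per-region parameter lists; see
#'   [region_defaults()].
#' @param stages Named list of per-stage geometry; see [stage_defaults()].
#' @param spindle_ap Named numeric, per-stage fraction of AP-oriented
#'   divisions.
#' @param n_divisions Named integer, per-stage number of mitotic events.
#' @param tissue_volume_um3 Named numeric, labelled-tissue volume schedule.
#' @param mean_cell_volume_um3 Named numeric, per-stage mean cell volume.
#' @param cell_volume_cv Coefficient of variation of the log-normal cell
#'   volume distribution.
#' @param section_um Section thickness used for cohesion calibration (µm).
#' @param min_ar Orientation classifier threshold the generator agrees with.
#' @param cone_deg Spindle cone half-angle the generator agrees with.
#' @param contra_frac Fraction of cells mirrored to the contralateral side
#'   for median-origin and entire grafts.
#' @param graft_cells Labelled-cell count per snapshot in
#'   [generate_graft_series()].
#' @param epidermis Logical, is the epidermis intact.
#'
#' @return A `generator_config` list.
#' @examples
#' cfg <- generator_config()
#' names(cfg$counts)
#' @export
generator_config <- function(counts = default_counts(),
                             placement = c("tube", "cluster"),
                             regions = region_defaults(),
                             stages = stage_defaults(),
                             spindle_ap = c(`19` = 0.059, `22` = 0.014,
                                            `28` = 0.121, `30` = 0.044),
                             n_divisions = c(`19` = 40, `22` = 60,
                                             `28` = 80, `30` = 90),
                             tissue_volume_um3 = c(`22` = 4e6, `28` = 4e6,
                                                   `30` = 8e6),
                             mean_cell_volume_um3 = c(`19` = 8000, `22` = 8000,
                                                      `28` = 4000, `30` = 4000),
                             cell_volume_cv = 0.25,
                             section_um = 80,
                             min_ar = 1.3,
                             cone_deg = 30,
                             contra_frac = 0.08,
                             graft_cells = 60,
                             epidermis = TRUE) {
  placement <- match.arg(placement)
  for (st in names(counts)) {
    cnt <- counts[[st]]
    if (any(cnt < 0)) stop("cell counts must be >= 0", call. = FALSE)
    if (!st %in% names(stages)) {
      stop(sprintf("counts given for stage %s but no stage geometry", st),
           call. = FALSE)
    }
  }
  for (rn in names(regions)) {
    r <- regions[[rn]]
    if (r$ar_sd < 0) stop("aspect-ratio SD must be >= 0", call. = FALSE)
    if (r$cohesion_um <= 0 || r$nn_um <= 0) {
      stop("cohesion and nearest-neighbour scales must be > 0", call. = FALSE)
    }
    p <- r$orientation
    if (is.null(p)) {
      regions[[rn]]$orientation <- p <-
        default_orientation_probs(rn, r$ar_mean, r$ar_sd, min_ar,
                                  named = r$named_orientation)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("orientation-class probabilities for %s must sum to 1", rn),
           call. = FALSE)
    }
  }
  cfg <- structure(
    list(counts = counts, placement = placement, regions = regions,
         stages = stages, spindle_ap = spindle_ap, n_divisions = n_divisions,
         tissue_volume_um3 = tissue_volume_um3,
         mean_cell_volume_um3 = mean_cell_volume_um3,
         cell_volume_cv = cell_volume_cv, section_um = section_um,
         min_ar = min_ar, cone_deg = cone_deg, contra_frac = contra_frac,
         graft_cells = graft_cells, epidermis = epidermis),
    class = "generator_config"
  )
  if (placement == "cluster") {
    used <- intersect(names(cfg$regions),
                      unique(unlist(lapply(counts, names))))
    for (rn in used) {
      n_grp <- max(unlist(lapply(counts, function(cnt) {
        cnt[intersect(names(cnt), rn)]
      })), 3)
      cfg$regions[[rn]]$sigma_um <- calibrate_cohesion_sigma(
        cfg$regions[[rn]]$cohesion_um, thickness = section_um,
        n_cells = n_grp)
    }
  }
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> placement %s, stages: %s\n", x$placement,
              paste(names(x$counts), collapse = ", ")))
  invisible(x)
}

#' Default per-stage labelled-cell counts
#'
#' Totals per stage follow the measured labelled mesodermal (527, 1095, 1232,
#' 1989) and neural (0, 27, 78, 1) counts of whole/half posterior-plate
#' grafts; the split of each total across regions follows the qualitative
#' staging (stage 22: posterior-zone bulge plus nascent posterior stream;
#' stage 30: stream from posterior zone through somites).
#' @return Named list of named integer vectors.
#' @export
default_counts <- function() {
  list(
    `19` = c(PZ = 527L),
    `22` = c(PZ = 800L, posterior_PSM = 295L, NT = 27L),
    `28` = c(PZ = 232L, posterior_PSM = 400L, medial_PSM = 350L,
             anterior_PSM = 250L, NT = 78L),
    `30` = c(PZ = 250L, posterior_PSM = 389L, medial_PSM = 350L,
             anterior_PSM = 400L, somite = 600L, NT = 1L)
  )
}

#' Per-region generating parameters (defaults)
#'
#' Aspect-ratio means and SDs, cohesion medians and filopodia parameters are
#' the measured per-region values (aspect ratio 2.33/2.78/2.26/2.37/3.03,
#' cohesion medians 14.9/14.3/57.9/10.6/10.2 µm, filopodium mean lengths
#' ~6 µm posteriorly and ~4 µm in the anterior PSM and somites);
#' `cohesion_n` are the small-clone group sizes chosen so that three pooled
#' clones yield the measured pairwise-distance counts (246/92/437/150/446).
#' @return Named list of per-region parameter lists.
#' @export
region_defaults <- function() {
  list(
    PZ = list(ar_mean = 2.33, ar_sd = 0.70,
              named_orientation = c(ML = 0.48),
              cohesion_um = 14.9, cohesion_n = 14L, nn_um = 30,
              filo_count_mean = 0.6, filo_len_mean = 6, filo_len_sd = 3),
    posterior_PSM = list(ar_mean = 2.78, ar_sd = 0.67,
                         named_orientation = c(ML = 0.36, AP = 0.36),
                         cohesion_um = 14.3, cohesion_n = 9L, nn_um = 30,
                         filo_count_mean = 1.6, filo_len_mean = 6,
                         filo_len_sd = 3),
    medial_PSM = list(ar_mean = 2.26, ar_sd = 0.68,
                      named_orientation = c(AP = 0.44),
                      cohesion_um = 57.9, cohesion_n = 21L, nn_um = 30,
                      filo_count_mean = 1.6, filo_len_mean = 6,
                      filo_len_sd = 3),
    anterior_PSM = list(ar_mean = 2.37, ar_sd = 0.71,
                        named_orientation = c(ML = 0.32, AP = 0.30),
                        cohesion_um = 10.6, cohesion_n = 11L, nn_um = 30,
                        filo_count_mean = 3.0, filo_len_mean = 4,
                        filo_len_sd = 2),
    somite = list(ar_mean = 3.03, ar_sd = 1.31,
                  named_orientation = c(DV = 0.46, AP = 0.33),
                  cohesion_um = 10.2, cohesion_n = 18L, nn_um = 25,
                  filo_count_mean = 0.6, filo_len_mean = 4, filo_len_sd = 2),
    NT = list(ar_mean = 1.6, ar_sd = 0.4,
              named_orientation = c(AP = 0.4),
              cohesion_um = 15, cohesion_n = 5L, nn_um = 25,
              filo_count_mean = 0.3, filo_len_mean = 4, filo_len_sd = 2)
  ) |>
    lapply(function(r) { r$orientation <- NULL; r })
}

#' Per-stage tube geometry (defaults)
#'
#' Arc length of the labelled mesodermal strand grows from ~300 µm (stage 19)
#' through 500 µm (stage 22) to 1200 µm (stage 30); the stage-30 tube height
#' is set so the labelled strand has a near-constant dorsoventral extent of
#' about 140 µm. `spans` are fractional arc intervals (anterior = 0) for the
#' regions present at each stage; `control` are spline control points of the
#' PSM arc (straight along AP by default, configurable to curved silhouettes).
#' @return Named list of per-stage geometry lists.
#' @export
stage_defaults <- function() {
  geom <- function(L, hh, hw, spans, n_somites = 0L) {
    list(arc_length_um = L, half_height_um = hh, half_width_um = hw,
         ml_offset_um = hw + 12, spans = spans, n_somites = n_somites,
         control = cbind(x = seq(0, L, length.out = 4), z = rep(0, 4)))
  }
  list(
    `19` = geom(300, 90, 70, list(PZ = c(0, 1))),
    `22` = geom(500, 100, 80,
                list(posterior_PSM = c(0, 0.6), PZ = c(0.6, 1))),
    `28` = geom(950, 80, 55,
                list(anterior_PSM = c(0, 0.3), medial_PSM = c(0.3, 0.55),
                     posterior_PSM = c(0.55, 0.8), PZ = c(0.8, 1))),
    `30` = geom(1200, 50, 45,
                list(somite = c(0, 0.25), anterior_PSM = c(0.25, 0.45),
                     medial_PSM = c(0.45, 0.65), posterior_PSM = c(0.65, 0.85),
                     PZ = c(0.85, 1)), n_somites = 6L)
  )
}

#' Small-clone (actin reporter) preset
#'
#' Cluster-mode configuration emulating ~20-cell grafts whose descendants
#' form one tight labelled clone per region. Group sizes are the
#' `cohesion_n` region defaults; each region is generated at the stage where
#' it was measured (posterior zone at 22, posterior/medial PSM at 28,
#' anterior PSM and somites at 30).
#' @param ... Passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
lifeact_config <- function(...) {
  reg <- region_defaults()
  counts <- list(
    `22` = c(PZ = reg$PZ$cohesion_n),
    `28` = c(posterior_PSM = reg$posterior_PSM$cohesion_n,
             medial_PSM = reg$medial_PSM$cohesion_n),
    `30` = c(anterior_PSM = reg$anterior_PSM$cohesion_n,
             somite = reg$somite$cohesion_n)
  )
  generator_config(counts = counts, placement = "cluster", ...)
}

#' Orientation-class probabilities consistent with a shape distribution
#'
#' Completes a partially specified orientation-class vector: the
#' `unclassified` probability is the below-threshold mass of the region's
#' truncated log-normal aspect-ratio distribution (so the marginal shape
#' distribution is undistorted), and the leftover mass is split equally
#' among the axes without a stated fraction.
#'
#' @param region Region name (looked up in [region_defaults()] for stated
#'   fractions when `named` is missing).
#' @param ar_mean,ar_sd Aspect-ratio mean and SD.
#' @param min_ar Classifier threshold.
#' @param named Named numeric of stated axis fractions (subset of
#'   `AP`, `ML`, `DV`).
#' @return Named numeric `c(AP=, ML=, DV=, unclassified=)` summing to 1.
#' @export
default_orientation_probs <- function(region, ar_mean, ar_sd, min_ar = 1.3,
                                      named = NULL) {
  if (is.null(named)) {
    named <- region_defaults()[[region]]$named_orientation %||% numeric(0)
  }
  par <- lnorm_pars(ar_mean, ar_sd)
  f1 <- stats::plnorm(1, par$mu, par$sig)
  p_uncl <- (stats::plnorm(min_ar, par$mu, par$sig) - f1) / (1 - f1)
  p <- c(AP = 0, ML = 0, DV = 0, unclassified = p_uncl)
  p[names(named)] <- named
  rest <- setdiff(c("AP", "ML", "DV"), names(named))
  p[rest] <- (1 - sum(named) - p_uncl) / length(rest)
  if (any(p < -1e-9)) {
    stop("stated orientation fractions exceed available probability mass",
         call. = FALSE)
  }
  pmax(p, 0)
}

# log-normal parameters from mean/SD on the natural scale
lnorm_pars <- function(m, s) {
  sig2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sig2 / 2, sig = sqrt(sig2))
}

# truncated log-normal sampler on [lo, hi], parameterised by natural mean/SD
rlnorm_trunc <- function(n, m, s, lo = 1, hi = Inf) {
  if (s <= 0) return(rep(max(m, lo), n))
  par <- lnorm_pars(m, s)
  flo <- stats::plnorm(lo, par$mu, par$sig)
  fhi <- stats::plnorm(hi, par$mu, par$sig)
  stats::qlnorm(stats::runif(n, flo, fhi), par$mu, par$sig)
}

#' Solve the Gaussian clone scale for a target in-section cohesion median
#'
#' For cluster placement the generator drops each labelled clone as an
#' isotropic Gaussian about an anchor whose position relative to the section
#' grid is random. Sectioning discards pairs spanning a cut, which biases
#' the observed median below the unconditional Gaussian pairwise median, so
#' the Gaussian scale is found by root-solving a Monte-Carlo estimate of the
#' in-section median (run under a fixed internal RNG scope, so the result is
#' deterministic).
#'
#' @param target_median_um Target pooled in-section median pairwise distance.
#' @param thickness Section thickness (µm, default 80).
#' @param n_cells Clone size used in the simulation.
#' @param clusters Number of simulated clones per evaluation.
#' @return Gaussian standard deviation in µm.
#' @export
calibrate_cohesion_sigma <- function(target_median_um, thickness = 80,
                                     n_cells = 15, clusters = 600) {
  stopifnot(target_median_um > 0, thickness > 0, n_cells >= 3)
  med_at <- function(sigma) {
    withr::with_seed(48103, {
      d <- lapply(seq_len(clusters), function(i) {
        off <- standardized_gauss(n_cells, sigma)   # the generator's placement
        x <- thickness / 2 + off[, 1]
        sec <- floor(x / thickness)
        unlist(lapply(split(seq_len(n_cells), sec), function(idx) {
          if (length(idx) < 2) return(numeric(0))
          as.numeric(stats::dist(cbind(x[idx], off[idx, 2:3, drop = FALSE])))
        }))
      })
      stats::median(unlist(d))
    })
  }
  stats::uniroot(function(s) med_at(s) - target_median_um,
                 lower = target_median_um / 6,
                 upper = target_median_um * 1.5,
                 tol = target_median_um * 1e-3)$root
}

# region config key for a cell label ("somite_3" -> "somite")
region_key <- function(label) {
  ifelse(grepl("^somite_", label), "somite", label)
}

# cell labels a region config key can produce
region_labels_for <- function(key) {
  if (key == "somite") paste0("somite_", 1:8) else key
}
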