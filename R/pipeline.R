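#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' One-way ANOVA comparison of a parameter across groups
#'
#' F and p come from the standard between/within sums of squares; pairwise
#' group comparisons are two-sample t tests with Holm adjustment. With
#' identical groups (zero between-group variation) the comparison reports
#' `F = 0`, `p = 1`.
#'
#' @param data Data frame with a value and a group column.
#' @param value,group Column names (strings) of the measured value and the
#'   grouping factor.
#' @return A `psm_anova` object; see [tidy()] and [glance()] methods.
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' glance(compare_groups(d, "v", "g"))
#' @export
compare_groups <- function(data, value = "value", group = "group") {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2)) stop("every group needs >= 2 values", call. = FALSE)
  grand <- mean(v)
  means <- tapply(v, g, mean)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((v - means[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(v) - nlevels(g)
  if (ss_between <= .Machine$double.eps * max(1, sum(v^2))) {
    f <- 0; p <- 1
  } else if (ss_within == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  pw <- if (stats::var(v) > 0) {
    pt <- stats::pairwise.t.test(v, g, p.adjust.method = "none",
                                 pool.sd = TRUE)
    raw <- as.data.frame(as.table(pt$p.value))
    raw <- raw[!is.na(raw$Freq), ]
    tibble::tibble(group1 = as.character(raw$Var1),
                   group2 = as.character(raw$Var2),
                   p_raw = raw$Freq,
                   p_adj = stats::p.adjust(raw$Freq, method = "holm"))
  } else {
    tibble::tibble(group1 = character(), group2 = character(),
                   p_raw = numeric(), p_adj = numeric())
  }
  structure(
    list(parameter = value, groups = levels(g), statistic = f, p_value = p,
         df = c(df1, df2), pairwise = pw, method = "oneway_anova_holm"),
    class = "psm_anova"
  )
}

#' @export
print.psm_anova <- function(x, ...) {
  cat(sprintf("<psm_anova> %s across %d groups: F(%d, %d) = %.3g, p = %.3g\n",
              x$parameter, length(x$groups), x$df[1], x$df[2], x$statistic,
              x$p_value))
  invisible(x)
}

#' @export
tidy.psm_anova <- function(x, ...) x$pairwise

#' @export
glance.psm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 df_between = x$df[1], df_within = x$df[2],
                 n_groups = length(x$groups), method = x$method)
}

#' Run the full morphometry pipeline on synthetic defaults
#'
#' Orchestrates the generator and every analysis stage for a set of stages:
#' ensemble snapshots (tube placement) for counting, orientation, spindle
#' and tissue measures; small-clone snapshots (cluster placement) for
#' per-region cohesion; density groups for closest-neighbour medians; plus
#' aspect-ratio, filopodia and growth-phase summaries and the relative
#' displacement series. Deterministic given `(config, seed)`.
#'
#' @param config A tube-mode [generator_config()].
#' @param lifeact A cluster-mode config for the cohesion stage
#'   (default [lifeact_config()]).
#' @param stages Stages to analyse (default the configured ones).
#' @param seed Integer seed.
#' @param section_um Section thickness for counting and cohesion.
#' @return A `psm_morphometry` object: list with `summary` (parameter-by-
#'   stage tibble), `details` (per-statistic tibbles) and `seed`.
#' @export
run_morphometry <- function(config = generator_config(),
                            lifeact = lifeact_config(),
                            stages = names(config$counts),
                            seed = 1, section_um = config$section_um) {
  stages <- as.character(stages)
  snaps <- lapply(seq_along(stages), function(i) {
    generate_stage_snapshot(config, stages[i], seed = seed + i)
  })
  names(snaps) <- stages
  lif <- lapply(seq_along(names(lifeact$counts)), function(i) {
    st <- names(lifeact$counts)[i]
    generate_stage_snapshot(lifeact, st, seed = seed + 100 + i)
  })
  names(lif) <- names(lifeact$counts)

  counts <- purrr::map_dfr(snaps, function(s) {
    tibble::tibble(stage = snapshot_stage(s),
                   n_mesodermal = count_sectioned_cells(
                     s, thickness = section_um)$n_mesodermal,
                   n_neural = sum(s$sox2))
  })
  spindle <- purrr::map_dfr(snaps, function(s) {
    tibble::tibble(stage = snapshot_stage(s),
                   ap_fraction = spindle_ap_fraction(
                     snapshot_divisions(s), snapshot_frame(s),
                     config$cone_deg))
  })
  orientation <- purrr::map_dfr(snaps, function(s) {
    meso <- s[is_mesodermal(s$region), ]
    if (nrow(meso) == 0) return(NULL)
    out <- orientation_fractions(meso, snapshot_frame(s), config$min_ar)
    out$stage <- snapshot_stage(s)
    out
  })
  shape <- purrr::map_dfr(snaps, function(s) {
    meso <- s[is_mesodermal(s$region), ]
    if (nrow(meso) == 0) return(NULL)
    meso$ar <- aspect_ratio(meso)
    meso |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(mean_ar = mean(.data$ar), sd_ar = stats::sd(.data$ar),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(stage = snapshot_stage(s))
  })
  cohesion <- purrr::map_dfr(names(lif), function(st) {
    s <- lif[[st]]
    sec <- assign_sections(s, "AP", section_um, snapshot_frame(s))
    purrr::map_dfr(unique(region_key(sec$region)), function(key) {
      grp <- sec[region_key(sec$region) == key, ]
      res <- tryCatch(pairwise_cohesion(grp), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      dplyr::mutate(glance(res), region = key, stage = as.integer(st))
    })
  })
  dens_cells <- generate_density_groups(config, seed = seed + 500)
  density <- purrr::map_dfr(unique(dens_cells$region), function(r) {
    g <- glance(nearest_neighbour_density(dens_cells[dens_cells$region == r, ]))
    dplyr::mutate(g, stage = 30L)
  })
  filopodia <- purrr::map_dfr(snaps, function(s) {
    meso <- s[is_mesodermal(s$region), ]
    if (nrow(meso) == 0) return(NULL)
    purrr::map_dfr(unique(region_key(meso$region)), function(key) {
      fs <- filopodia_stats(meso[region_key(meso$region) == key, ])
      dplyr::mutate(fs, region = key, stage = snapshot_stage(s))
    })
  })
  dims <- purrr::map_dfr(snaps, labelled_extents)
  vols <- config$tissue_volume_um3
  phases <- growth_phase(unname(vols), as.integer(names(vols)))
  disp <- purrr::map_dfr(c("paraxial", "epidermis"), function(tis) {
    tc <- generate_embryo_timecourse(config, tis, label_site = 0.5,
                                     stages = as.integer(stages),
                                     seed = seed + 900)
    dplyr::mutate(tc[, c("stage", "d_rel")], tissue = tis)
  })

  details <- list(counts = counts, spindle = spindle,
                  orientation = orientation, shape = shape,
                  cohesion = cohesion, density = density,
                  filopodia = filopodia, dimensions = dims,
                  growth_phase = phases, displacement = disp)
  structure(
    list(summary = build_summary_table(details, stages),
         details = details, seed = seed),
    class = "psm_morphometry"
  )
}

# Parameter-by-stage overview in the style of a collective-behaviour table
build_summary_table <- function(d, stages) {
  stage_cols <- paste0("stage_", stages)
  fmt <- function(x, digits = 3) {
    ifelse(is.na(x), NA_character_,
           trimws(formatC(x, digits = digits, format = "fg")))
  }
  row_of <- function(parameter, values) {
    out <- as.list(rep(NA_character_, length(stage_cols)))
    names(out) <- stage_cols
    for (st in names(values)) {
      col <- paste0("stage_", st)
      if (col %in% stage_cols) out[[col]] <- values[[st]]
    }
    tibble::as_tibble(c(list(parameter = parameter), out))
  }
  by_stage <- function(df, value_fn) {
    vals <- lapply(split(df, df$stage), value_fn)
    stats::setNames(vals, names(vals))
  }
  rows <- list(
    row_of("labelled mesodermal cells",
           by_stage(d$counts, function(g) fmt(g$n_mesodermal, 6))),
    row_of("AP-oriented divisions [%]",
           by_stage(d$spindle, function(g) fmt(100 * g$ap_fraction))),
    row_of("orientation (per region)",
           by_stage(d$orientation, function(g) {
             g <- g[g$orientation != "unclassified", ]
             top <- g[order(-g$fraction), ][seq_len(min(3, nrow(g))), ]
             paste(sprintf("%s %s %.0f%%", top$region, top$orientation,
                           100 * top$fraction), collapse = "; ")
           })),
    row_of("cohesion median [um]",
           by_stage(d$cohesion, function(g) {
             paste(sprintf("%s %.1f", g$region, g$median_um), collapse = "; ")
           })),
    row_of("closest-neighbour median [um]",
           by_stage(d$density, function(g) {
             paste(sprintf("%s %.0f", g$region, g$median_um), collapse = "; ")
           })),
    row_of("aspect ratio (mean, SD)",
           by_stage(d$shape, function(g) {
             paste(sprintf("%s %.2f (%.2f)", g$region, g$mean_ar, g$sd_ar),
                   collapse = "; ")
           })),
    row_of("filopodium mean length [um]",
           by_stage(d$filopodia, function(g) {
             paste(sprintf("%s %.1f", g$region, g$mean_length_um),
                   collapse = "; ")
           })),
    row_of("tissue length [um]",
           by_stage(d$dimensions, function(g) fmt(g$length_um, 4))),
    row_of("tissue height [um]",
           by_stage(d$dimensions, function(g) fmt(g$height_um, 4))),
    row_of("growth phase (interval to stage)",
           stats::setNames(as.list(d$growth_phase$phase),
                           d$growth_phase$to)),
    row_of("d_rel (paraxial)",
           by_stage(d$displacement[d$displacement$tissue == "paraxial", ],
                    function(g) fmt(g$d_rel)))
  )
  dplyr::bind_rows(rows)
}

#' @export
print.psm_morphometry <- function(x, ...) {
  cat(sprintf("<psm_morphometry> seed %d; summary:\n", x$seed))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
glance.psm_morphometry <- function(x, ...) {
  tibble::tibble(n_parameters = nrow(x$summary),
                 n_stages = ncol(x$summary) - 1, seed = x$seed)
}
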