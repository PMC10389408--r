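# --- synthetic cohort generator ---------------------------------------------
# Emulates the statistical structure the analysis assumes: two slide-mean
# area components (medians ~150 vs ~217 um^2), per-cell lognormal areas
# around the patient mean rendered as noisy polygons, proportional-hazards
# DFS with a large hazard ratio for the large-area class and independent
# uniform censoring, Table-2-style binary covariates, and clustered
# (Thomas) vs dispersed (Poisson) L-TAM point patterns in the peritumoral
# band. The truth sidecar is written for recovery tests only; analysis
# stages never read it.

p_event_uniform_censoring <- function(hazard, censor_max) {
  # P(T <= C), T ~ Exp(hazard), C ~ U(0, censor_max)
  1 - (1 - exp(-hazard * censor_max)) / (hazard * censor_max)
}

#' Generator configuration
#'
#' All tunables of the synthetic cohort with their defaults. The two area
#' components have medians 150.4 and 217.0 um^2 with log-scale spreads
#' 0.22 / 0.25; per-cell areas are lognormal around the patient mean with
#' log-sd 0.20. DFS times are exponential with baseline hazard 0.02/month
#' and hazard ratio 5 for the large class, censored by an independent
#' U(0, 60 months) time. The prevalence of the large class is derived
#' analytically so the expected recurrence fraction matches
#' `fraction_recurrence` under those survival settings (the class is
#' defined by the true slide-mean area being at or above `area_cutoff`).
#'
#' @param seed integer master seed.
#' @param n_patients cohort size.
#' @param fraction_recurrence target expected fraction of patients with an
#'   observed recurrence.
#' @param median_area_small,median_area_large component medians, um^2.
#' @param sdlog_small,sdlog_large log-scale spread of the slide-mean
#'   components.
#' @param cell_sdlog log-scale spread of per-cell areas within a patient.
#' @param cell_irregularity outline irregularity passed to
#'   [render_cell_outline()].
#' @param n_zones annotated zones per slide.
#' @param cells_per_zone_available traced cells available per zone (must be
#'   at least the protocol's cells per zone).
#' @param area_cutoff true class boundary, um^2 (defaults to the reference
#'   cutoff).
#' @param baseline_hazard DFS hazard of the small class, events/month.
#' @param hazard_ratio hazard ratio of the large class vs the small class.
#' @param censor_max upper bound of the uniform censoring time, months.
#' @param post_recurrence_hazard hazard of death after recurrence (used to
#'   extend DFS to OS), events/month.
#' @param prob_large_component mixture weight of the large area component;
#'   `NULL` (default) derives it from `fraction_recurrence`.
#' @param tumor_radius,tumor_irregularity,contour_vertices synthetic tumor
#'   contour shape (micrometres / fraction / count).
#' @param band_width peritumoral band width, micrometres.
#' @param thomas_parents,thomas_offspring,thomas_sigma Thomas cluster
#'   process: mean parent count per slide, mean offspring per parent,
#'   Gaussian scatter (um) — the clustered L-TAM pattern of
#'   early-recurrence slides.
#' @param stam_expected expected S-TAM count per slide band.
#' @param early_recurrence_months recurrence within this many months marks
#'   a slide as early-recurrence (clustered L-TAMs).
#' @param no_recurrence_months descriptive follow-up threshold for the
#'   favorable arm.
#' @param covariate_prevalence named vector of baseline (small-class)
#'   prevalences of the binary clinical covariates.
#' @param covariate_class_assoc named vector of log-odds shifts applied to
#'   a covariate's prevalence for large-class patients.
#' @return Object of class `generator_config` (a validated list, with the
#'   derived `prob_large_class` and `prob_large_component` filled in).
#' @export
generator_config <- function(seed = 1L,
                             n_patients = 84L,
                             fraction_recurrence = 66 / 84,
                             median_area_small = 150.4,
                             median_area_large = 217.0,
                             sdlog_small = 0.22,
                             sdlog_large = 0.25,
                             cell_sdlog = 0.20,
                             cell_irregularity = 0.2,
                             n_zones = 3L,
                             cells_per_zone_available = 10L,
                             area_cutoff = TAM_REFERENCE_CUTOFF,
                             baseline_hazard = 0.02,
                             hazard_ratio = 5,
                             censor_max = 60,
                             post_recurrence_hazard = 0.04,
                             prob_large_component = NULL,
                             tumor_radius = 800,
                             tumor_irregularity = 0.12,
                             contour_vertices = 72L,
                             band_width = 500,
                             thomas_parents = 3,
                             thomas_offspring = 150,
                             thomas_sigma = 50,
                             stam_expected = 400,
                             early_recurrence_months = 3,
                             no_recurrence_months = 48,
                             covariate_prevalence = c(
                               sex_male = 0.72, neoadjuvant = 0.60,
                               cea_elevated = 0.60, ca199_elevated = 0.15,
                               t34 = 0.75, n_positive = 0.45,
                               synchronous = 0.45, g34 = 0.15,
                               ras_mutated = 0.30, bilobar = 0.40,
                               rectum_primary = 0.32),
                             covariate_class_assoc = c(
                               neoadjuvant = 0.9, n_positive = 1.1,
                               synchronous = 0.8)) {
  stopifnot(n_patients >= 2, fraction_recurrence > 0, fraction_recurrence < 1,
            median_area_small > 0, median_area_large > median_area_small,
            sdlog_small > 0, sdlog_large > 0, cell_sdlog > 0,
            baseline_hazard > 0, hazard_ratio > 0, censor_max > 0,
            post_recurrence_hazard > 0, area_cutoff > 0,
            tumor_radius > 0, band_width > 0, thomas_parents > 0,
            thomas_offspring > 0, thomas_sigma > 0, stam_expected >= 0,
            cells_per_zone_available >= 1, n_zones >= 1)
  p_ev_s <- p_event_uniform_censoring(baseline_hazard, censor_max)
  p_ev_l <- p_event_uniform_censoring(baseline_hazard * hazard_ratio,
                                      censor_max)
  p_class_l <- if (abs(p_ev_l - p_ev_s) < 1e-10) 0.5 else
    (fraction_recurrence - p_ev_s) / (p_ev_l - p_ev_s)
  if (p_class_l < 0.02 || p_class_l > 0.98) {
    warning("derived large-class prevalence ", round(p_class_l, 3),
            " clamped to [0.02, 0.98]")
    p_class_l <- min(max(p_class_l, 0.02), 0.98)
  }
  # P(true slide mean >= cutoff | component)
  q_s <- stats::pnorm((log(median_area_small) - log(area_cutoff)) / sdlog_small)
  q_l <- stats::pnorm((log(median_area_large) - log(area_cutoff)) / sdlog_large)
  if (is.null(prob_large_component)) {
    prob_large_component <- (p_class_l - q_s) / (q_l - q_s)
    if (prob_large_component < 0.02 || prob_large_component > 0.98) {
      warning("derived large-component weight ",
              round(prob_large_component, 3), " clamped to [0.02, 0.98]")
      prob_large_component <- min(max(prob_large_component, 0.02), 0.98)
    }
  }
  cfg <- as.list(environment())
  cfg$prob_large_class <- p_class_l
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config: n=%d, seed=%d, components %g/%g um^2",
                     " (weight %.2f large), HR=%g, h0=%g/mo, censor U(0,%g)>\n"),
              x$n_patients, x$seed, x$median_area_small, x$median_area_large,
              x$prob_large_component, x$hazard_ratio, x$baseline_hazard,
              x$censor_max))
  invisible(x)
}

#' Render a synthetic tumor contour
#'
#' Star-shaped polygon with low-frequency radial modulation: radius
#' `R(theta) = R0 (1 + sum a_k cos(k theta + phi_k))`, k = 2..5, which is
#' simple by construction.
#'
#' @param config a [generator_config()].
#' @param centre contour centre in slide coordinates.
#' @return n x 2 vertex matrix.
#' @export
render_tumor_contour <- function(config, centre = c(0, 0)) {
  n <- config$contour_vertices
  irr <- config$tumor_irregularity
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- rep(1, n)
  for (k in 2:5)
    r <- r + stats::runif(1, -irr, irr) / k * cos(k * th + stats::runif(1, 0, 2 * pi))
  r <- pmax(r, 0.3) * config$tumor_radius
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

uniform_in_band <- function(n, geometry) {
  v <- geometry$contour
  w <- geometry$band_width
  lo <- c(min(v[, 1]) - w, min(v[, 2]) - w)
  hi <- c(max(v[, 1]) + w, max(v[, 2]) + w)
  out <- matrix(numeric(0), 0, 2)
  guard <- 0L
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    x <- stats::runif(m, lo[1], hi[1])
    y <- stats::runif(m, lo[2], hi[2])
    keep <- in_band(geometry, x, y)
    out <- rbind(out, cbind(x[keep], y[keep]))
    guard <- guard + 1L
    if (guard > 1000L)
      stop("infeasible geometry: cannot place points in the band ",
           "(band area too small?)")
  }
  out[seq_len(n), , drop = FALSE]
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower = -Inf, upper = Inf) {
  # draw lognormal areas restricted to (lower, upper) via inverse CDF
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Simulate one slide's L-TAM / S-TAM point pattern
#'
#' L-TAM centroids follow a Thomas cluster process (Poisson parents
#' uniform in the band, Poisson(offspring) progeny scattered with Gaussian
#' sd `thomas_sigma`, clipped to the band) on `pattern = "clustered"`
#' slides and a homogeneous Poisson process at matched expected count on
#' `pattern = "poisson"` slides. S-TAM centroids are always homogeneous
#' Poisson. Per-cell areas are drawn from the large (resp. small)
#' component's per-cell law truncated at the cohort cutoff, so the
#' designated population matches the per-cell area rule used by the
#' spatial analysis.
#'
#' Uses the current RNG stream; seed at the caller.
#'
#' @param geometry a [tumor_geometry()].
#' @param pattern `"clustered"` or `"poisson"` — the L-TAM pattern.
#' @param config a [generator_config()].
#' @return data.frame with x, y, area_um2, population ("L"/"S").
#' @export
simulate_slide_points <- function(geometry, pattern = c("clustered", "poisson"),
                                  config = generator_config()) {
  pattern <- match.arg(pattern)
  cut <- config$area_cutoff
  if (pattern == "clustered") {
    n_par <- stats::rpois(1, config$thomas_parents)
    pts <- matrix(numeric(0), 0, 2)
    if (n_par > 0) {
      parents <- uniform_in_band(n_par, geometry)
      for (i in seq_len(n_par)) {
        m <- stats::rpois(1, config$thomas_offspring)
        if (m == 0) next
        off <- cbind(parents[i, 1] + stats::rnorm(m, 0, config$thomas_sigma),
                     parents[i, 2] + stats::rnorm(m, 0, config$thomas_sigma))
        off <- off[in_band(geometry, off[, 1], off[, 2]), , drop = FALSE]
        pts <- rbind(pts, off)
      }
    }
  } else {
    n_l <- stats::rpois(1, config$thomas_parents * config$thomas_offspring)
    pts <- if (n_l > 0) uniform_in_band(n_l, geometry) else
      matrix(numeric(0), 0, 2)
  }
  n_l <- nrow(pts)
  l_areas <- rlnorm_trunc(n_l, log(config$median_area_large),
                          config$cell_sdlog, lower = cut)
  n_s <- stats::rpois(1, config$stam_expected)
  spts <- if (n_s > 0) uniform_in_band(n_s, geometry) else
    matrix(numeric(0), 0, 2)
  s_areas <- rlnorm_trunc(n_s, log(config$median_area_small),
                          config$cell_sdlog, upper = cut)
  data.frame(x = c(pts[, 1], spts[, 1]), y = c(pts[, 2], spts[, 2]),
             area_um2 = c(l_areas, s_areas),
             population = rep(c("L", "S"), c(n_l, n_s)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws the patient-level truth (area component, true slide-mean area,
#' class, covariates, DFS/OS), then per-slide traced-cell areas (always)
#' and rendered outlines plus a tumor contour (when `render_slides =
#' TRUE`). Cell areas are drawn from each slide's child RNG stream before
#' any outline-shape draws, so measured means are identical whether or not
#' outlines are rendered. Fully reproducible from `config$seed`; the truth
#' component is intended for recovery tests only.
#'
#' @param config a [generator_config()].
#' @param render_slides render polygon outlines and tumor contours (set
#'   `FALSE` for the patient-level fast path used in large simulation
#'   studies).
#' @param out_dir optional directory: writes `cohort.csv`, `truth.json`,
#'   `config.json` and (when rendered) `slides/<slide>.geojson`.
#' @return list with `cohort` (data.frame), `cells` (per-cell area table),
#'   `slides` (named list of `outlines` + `tumor`, when rendered), `truth`
#'   (data.frame + attributes), `config`.
#' @export
generate_cohort <- function(config = generator_config(), render_slides = TRUE,
                            out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n))
  sid <- sprintf("S%03d", seq_len(n))
  truth_env <- withr::with_seed(as.integer(config$seed), {
    component <- ifelse(stats::runif(n) < config$prob_large_component,
                        "large", "small")
    true_mean <- ifelse(component == "large",
                        stats::rlnorm(n, log(config$median_area_large),
                                      config$sdlog_large),
                        stats::rlnorm(n, log(config$median_area_small),
                                      config$sdlog_small))
    true_class <- ifelse(true_mean >= config$area_cutoff, "L-TAM", "S-TAM")
    large <- true_class == "L-TAM"
    # covariates
    age <- round(pmin(pmax(stats::rnorm(n, 61, 10), 30), 85))
    tumor_number <- 1L + stats::rpois(n, 1.5)
    max_size_mm <- round(stats::rlnorm(n, log(20), 0.5))
    cov <- list()
    for (nm in names(config$covariate_prevalence)) {
      shift <- if (nm %in% names(config$covariate_class_assoc))
        config$covariate_class_assoc[[nm]] else 0
      p <- stats::plogis(stats::qlogis(config$covariate_prevalence[[nm]]) +
                           shift * large)
      cov[[nm]] <- as.integer(stats::runif(n) < p)
    }
    # survival: exponential PH on the true class, independent uniform
    # censoring; OS extends DFS by a post-recurrence death time
    hz <- config$baseline_hazard * config$hazard_ratio^large
    t_rec <- stats::rexp(n, hz)
    cens <- stats::runif(n, 0, config$censor_max)
    dfs_event <- as.integer(t_rec <= cens)
    dfs_time <- pmin(t_rec, cens)
    t_death <- t_rec + stats::rexp(n, config$post_recurrence_hazard)
    os_event <- as.integer(dfs_event == 1L & t_death <= cens)
    os_time <- ifelse(dfs_event == 1L, pmin(t_death, cens), cens)
    list(component = component, true_mean = true_mean,
         true_class = true_class, age = age, tumor_number = tumor_number,
         max_size_mm = max_size_mm, cov = cov, dfs_time = dfs_time,
         dfs_event = dfs_event, os_time = os_time, os_event = os_event)
  })
  e <- truth_env
  pattern <- ifelse(e$dfs_event == 1L &
                      e$dfs_time <= config$early_recurrence_months,
                    "clustered", "poisson")
  cohort <- data.frame(patient_id = pid, slide_id = sid, age = e$age,
                       tumor_number = e$tumor_number,
                       max_size_mm = e$max_size_mm,
                       stringsAsFactors = FALSE)
  for (nm in names(e$cov)) cohort[[nm]] <- e$cov[[nm]]
  cohort$dfs_time <- round(e$dfs_time, 2)
  cohort$dfs_event <- e$dfs_event
  cohort$os_time <- round(e$os_time, 2)
  cohort$os_event <- e$os_event
  truth <- data.frame(patient_id = pid, slide_id = sid,
                      component = e$component,
                      true_mean_area = e$true_mean,
                      true_class = e$true_class,
                      spatial_pattern = pattern,
                      stringsAsFactors = FALSE)
  # per-slide traced cells: areas first (shared with the fast path), then
  # outline shapes, all inside the slide's child stream
  n_cells <- config$n_zones * config$cells_per_zone_available
  zone_ids <- rep(sprintf("Z%d", seq_len(config$n_zones)),
                  each = config$cells_per_zone_available)
  cells <- list()
  slides <- if (render_slides) vector("list", n) else NULL
  for (i in seq_len(n)) {
    res <- withr::with_seed(child_seed(config$seed, paste0("slide_", sid[i])), {
      mlog <- log(e$true_mean[i]) - config$cell_sdlog^2 / 2
      areas <- stats::rlnorm(n_cells, mlog, config$cell_sdlog)
      slide <- NULL
      if (render_slides) {
        contour <- render_tumor_contour(config)
        geom <- tumor_geometry(contour, config$band_width, sid[i])
        zang <- stats::runif(1, 0, 2 * pi) +
          2 * pi * (seq_len(config$n_zones) - 1) / config$n_zones
        outlines <- vector("list", n_cells)
        for (j in seq_len(n_cells)) {
          z <- (j - 1L) %/% config$cells_per_zone_available + 1L
          rad <- config$tumor_radius + config$band_width / 2
          ctr <- c(cos(zang[z]), sin(zang[z])) * rad +
            stats::runif(2, -config$band_width / 3, config$band_width / 3)
          outlines[[j]] <- render_cell_outline(
            areas[j], irregularity = config$cell_irregularity, centre = ctr,
            cell_id = sprintf("%s_%s_C%02d", sid[i], zone_ids[j],
                              (j - 1L) %% config$cells_per_zone_available + 1L),
            slide_id = sid[i], zone_id = zone_ids[j])
        }
        slide <- list(outlines = outlines, tumor = contour)
      }
      list(areas = areas, slide = slide)
    })
    cells[[i]] <- data.frame(
      slide_id = sid[i], zone_id = zone_ids,
      cell_id = sprintf("%s_%s_C%02d", sid[i], zone_ids,
                        (seq_len(n_cells) - 1L) %%
                          config$cells_per_zone_available + 1L),
      area_um2 = res$areas, stringsAsFactors = FALSE)
    if (render_slides) slides[[i]] <- res$slide
  }
  cells <- do.call(rbind, cells)
  if (render_slides) names(slides) <- sid
  out <- list(cohort = cohort, cells = cells, slides = slides,
              truth = truth, config = config)
  if (!is.null(out_dir)) write_cohort_files(out, out_dir)
  out
}

write_cohort_files <- function(generated, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(generated$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  cfg <- generated$config
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, TRUE)],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(true_hazard_ratio = cfg$hazard_ratio,
         area_cutoff = cfg$area_cutoff,
         patients = generated$truth),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  if (!is.null(generated$slides)) {
    sdir <- file.path(out_dir, "slides")
    dir.create(sdir, showWarnings = FALSE)
    for (sid in names(generated$slides)) {
      s <- generated$slides[[sid]]
      write_slide_geojson(s$outlines, s$tumor,
                          file.path(sdir, paste0(sid, ".geojson")),
                          slide_id = sid)
    }
  }
  invisible(out_dir)
}

#' Select the prognostic-extreme slide subset
#'
#' The 6-vs-6 design: the `n_per_arm` patients with the earliest observed
#' recurrences versus the `n_per_arm` event-free patients with the longest
#' follow-up.
#'
#' @param cohort cohort data.frame with `dfs_time` / `dfs_event`.
#' @param n_per_arm slides per arm (default 6).
#' @return list with `early` and `favorable` row subsets of `cohort`.
#' @export
select_prognostic_extremes <- function(cohort, n_per_arm = 6L) {
  ev <- cohort[cohort$dfs_event == 1L, , drop = FALSE]
  nev <- cohort[cohort$dfs_event == 0L, , drop = FALSE]
  if (nrow(ev) < n_per_arm || nrow(nev) < n_per_arm)
    stop("cohort has too few events (", nrow(ev), ") or non-events (",
         nrow(nev), ") for ", n_per_arm, " slides per arm")
  list(early = ev[order(ev$dfs_time), , drop = FALSE][seq_len(n_per_arm), ],
       favorable = nev[order(-nev$dfs_time), , drop = FALSE][seq_len(n_per_arm), ])
}

#' Clustered-vs-dispersed foci contrast on a 6-vs-6 slide set
#'
#' Simulates `n_per_arm` slides with Thomas-clustered L-TAMs ("early
#' recurrence" arm) and `n_per_arm` with dispersed Poisson L-TAMs at
#' matched expected count, runs foci detection on each (per-cell L-TAM
#' status = area at or above the cohort cutoff) and compares total foci
#' areas with the exact Mann-Whitney test.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param n_per_arm slides per arm.
#' @param pixel_size raster pitch for foci detection, micrometres.
#' @return list with `p_value`, `U`, `clustered_areas`, `poisson_areas`.
#' @export
simulate_foci_contrast <- function(config = generator_config(), seed = 1L,
                                   n_per_arm = 6L, pixel_size = 20) {
  withr::with_seed(as.integer(seed), {
    run_arm <- function(pattern) {
      vapply(seq_len(n_per_arm), function(i) {
        geom <- tumor_geometry(render_tumor_contour(config),
                               config$band_width)
        pts <- simulate_slide_points(geom, pattern, config)
        ltam <- pts[pts$area_um2 >= config$area_cutoff, c("x", "y")]
        detect_foci(ltam, geom, pixel_size = pixel_size)$total_area_um2
      }, numeric(1))
    }
    clustered <- run_arm("clustered")
    dispersed <- run_arm("poisson")
    mw <- compare_foci(clustered, dispersed)
    list(p_value = mw$p_value, U = mw$U, clustered_areas = clustered,
         poisson_areas = dispersed)
  })
}
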