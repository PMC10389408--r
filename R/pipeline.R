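# --- pipeline configuration and driver --------------------------------------

#' Pipeline configuration
#'
#' All analysis tunables with their defaults: the 3-zones-of-7 sampling
#' protocol, the cutoff mode (derive by ROC/Youden or use the fixed
#' reference cutoff), and the spatial parameters (500-um band, 500-um
#' density radius, 100-L-TAMs-in-200-um foci rule, 20-um raster).
#'
#' @param zones_per_slide,cells_per_zone sampling protocol.
#' @param cutoff_mode `"derive"` (ROC + Youden) or `"fixed"`.
#' @param fixed_cutoff cutoff used when `cutoff_mode = "fixed"`, um^2.
#' @param band_width,count_radius,foci_radius,foci_threshold,pixel_size
#'   spatial parameters (micrometres / count).
#' @param alpha significance level for the univariate screen feeding the
#'   multivariate Cox model.
#' @param n_bootstrap Cox bootstrap resamples.
#' @param seed integer seed driving sampling and bootstrap.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(zones_per_slide = 3L, cells_per_zone = 7L,
                            cutoff_mode = c("derive", "fixed"),
                            fixed_cutoff = TAM_REFERENCE_CUTOFF,
                            band_width = 500, count_radius = 500,
                            foci_radius = 200, foci_threshold = 100,
                            pixel_size = 20, alpha = 0.05,
                            n_bootstrap = 1000L, seed = 1L) {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(zones_per_slide >= 1, cells_per_zone >= 1, fixed_cutoff > 0,
            band_width > 0, count_radius > pixel_size,
            foci_radius > pixel_size, foci_threshold > 0, pixel_size > 0,
            alpha > 0, alpha < 1, n_bootstrap >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> measure -> classify -> survival -> spatial ->
#' report. Stages:
#' \enumerate{
#'   \item morphometry: sample cells by the protocol, measure, aggregate
#'     zone means into slide means;
#'   \item cutoff: ROC of slide-mean area vs recurrence and the Youden
#'     optimal cutoff (or the fixed reference cutoff, skipping ROC
#'     derivation), then S-TAM/L-TAM classification;
#'   \item univariate screen (Table-2-shaped) and Kaplan-Meier / log-rank /
#'     3-year DFS by class, for DFS and OS;
#'   \item multivariate Cox (covariates significant at `alpha` in the
#'     screen, plus the TAM class) with bootstrap validation;
#'   \item spatial: foci contrast on the 6-vs-6 prognostic-extreme slides.
#' }
#' Deterministic given the seeds; any stage failure aborts with the stage
#' name, after earlier stages' outputs have been written.
#'
#' @param pipe a [pipeline_config()].
#' @param gen a [generator_config()] used when simulating (its seed drives
#'   the data; the pipeline seed drives sampling/bootstrap).
#' @param input_dir optional directory of `cohort.csv` + `slides/*.geojson`
#'   (as written by [generate_cohort()]); default: simulate.
#' @param out_dir optional output directory for the report bundle.
#' @param measure `"slides"` traces the rendered polygons;
#'   `"analytic"` uses the generator's cell-area table directly (fast
#'   path, identical sampled areas; only available when simulating).
#' @param spatial run the density-map/foci stage.
#' @return list of stage results (class `tam_pipeline`).
#' @export
run_pipeline <- function(pipe = pipeline_config(),
                         gen = generator_config(seed = pipe$seed),
                         input_dir = NULL, out_dir = NULL,
                         measure = c("slides", "analytic"),
                         spatial = TRUE) {
  measure <- match.arg(measure)
  stopifnot(inherits(pipe, "pipeline_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(name, obj) {
    if (!is.null(out_dir))
      utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    invisible(obj)
  }

  # -- data ------------------------------------------------------------------
  generated <- NULL
  if (is.null(input_dir)) {
    generated <- stage("simulate",
                       generate_cohort(gen, render_slides = (measure == "slides")))
    cohort <- generated$cohort
  } else {
    if (measure == "analytic")
      stop("pipeline stage 'data' failed: analytic measurement is only ",
           "available for simulated cohorts", call. = FALSE)
    cohort <- stage("data", utils::read.csv(file.path(input_dir, "cohort.csv"),
                                            stringsAsFactors = FALSE))
  }

  # -- morphometry -----------------------------------------------------------
  measurements <- stage("morphometry", {
    if (measure == "slides") {
      outlines <- if (is.null(input_dir)) {
        unlist(lapply(generated$slides, `[[`, "outlines"), recursive = FALSE)
      } else {
        files <- list.files(file.path(input_dir, "slides"),
                            pattern = "\\.geojson$", full.names = TRUE)
        if (!length(files)) stop("no slide annotation files found")
        unlist(lapply(files, function(f)
          read_slide_annotations(f)$outlines), recursive = FALSE)
      }
      sampled <- sample_cells(outlines, pipe$zones_per_slide,
                              pipe$cells_per_zone, seed = pipe$seed)
      measure_cells(sampled)
    } else {
      cells <- generated$cells
      idx <- sample_protocol_indices(cells$slide_id, cells$zone_id,
                                     pipe$zones_per_slide,
                                     pipe$cells_per_zone, seed = pipe$seed)
      m <- cells[idx, , drop = FALSE]
      # fast path: perimeter from the area with a near-circular shape
      # factor; perimeter feeds only the descriptive summary
      m$perimeter_um <- 2 * sqrt(pi * m$area_um2) * 1.06
      m[, c("slide_id", "zone_id", "cell_id", "area_um2", "perimeter_um")]
    }
  })
  emit("morphometry_cells", measurements)
  slide_summary <- stage("morphometry", summarize_slides(measurements))
  emit("morphometry_slides", slide_summary)
  dispersion <- cohort_morphometry_summary(measurements)
  emit("morphometry_summary", dispersion)
  cohort$mean_tam_area <-
    slide_summary$mean_area_um2[match(cohort$slide_id,
                                      slide_summary$slide_id)]

  # -- cutoff + classification ----------------------------------------------
  roc <- NULL
  cutoff <- if (pipe$cutoff_mode == "fixed") {
    pipe$fixed_cutoff
  } else {
    roc <- stage("cutoff", build_roc(cohort$mean_tam_area, cohort$dfs_event))
    if (!is.null(out_dir)) emit("roc_curve", roc$curve)
    roc$optimal_cutoff
  }
  cohort <- stage("classify", classify_patients(cohort, cutoff))
  emit("cohort_classified", cohort)

  # survival-stage precondition: fails here (after morphometry outputs are
  # written) if the cohort carries no survival contrast at all
  stage("survival",
        if (sum(cohort$dfs_event) == 0 || all(cohort$dfs_event == 1))
          stop("degenerate labels: all patients ",
               if (all(cohort$dfs_event == 1)) "relapsed" else "event-free"))

  # -- univariate screen -----------------------------------------------------
  uni <- stage("univariate", univariate_table(cohort))
  emit("univariate", uni)

  # -- survival --------------------------------------------------------------
  surv <- stage("survival", {
    by_class <- split(cohort, cohort$tam_class)
    km <- lapply(by_class, function(d) km_estimate(d$dfs_time, d$dfs_event))
    lr <- logrank_test(cohort$dfs_time, cohort$dfs_event, cohort$tam_class)
    lr_os <- logrank_test(cohort$os_time, cohort$os_event, cohort$tam_class)
    dfs36 <- vapply(km, km_survival_at, numeric(1), t = 36)
    list(km = km, logrank_dfs = lr, logrank_os = lr_os,
         dfs_3yr = dfs36)
  })
  if (!is.null(out_dir)) {
    kmtab <- do.call(rbind, lapply(names(surv$km), function(cl) {
      t <- surv$km[[cl]]$table; t$tam_class <- cl; t
    }))
    emit("km_dfs", kmtab)
  }

  # -- multivariate Cox ------------------------------------------------------
  cox <- stage("cox", {
    flags <- tam_covariate_roster()
    flags <- flags$variable[flags$type == "categorical"]
    sig <- uni$variable[uni$p_value < pipe$alpha & uni$variable %in% flags]
    cohort$ltam <- as.integer(cohort$tam_class == "L-TAM")
    cox_fit(cohort, covariates = c("ltam", sig), n_bootstrap = pipe$n_bootstrap,
            seed = pipe$seed)
  })
  emit("cox_multivariate", cox$table)

  # -- spatial ---------------------------------------------------------------
  spatial_res <- NULL
  if (spatial) {
    spatial_res <- stage("spatial", {
      extremes <- select_prognostic_extremes(cohort)
      sp_seed <- child_seed(pipe$seed, "spatial")
      cfg <- if (is.null(generated)) generator_config(seed = sp_seed) else {
        g <- generated$config
        g$band_width <- pipe$band_width
        g
      }
      res <- simulate_foci_contrast(cfg, seed = sp_seed,
                                    pixel_size = pipe$pixel_size)
      res$early_patients <- extremes$early$patient_id
      res$favorable_patients <- extremes$favorable$patient_id
      res
    })
    if (!is.null(out_dir))
      emit("foci_totals", data.frame(
        arm = rep(c("early_recurrence", "no_recurrence"),
                  each = length(spatial_res$clustered_areas)),
        total_foci_area_um2 = c(spatial_res$clustered_areas,
                                spatial_res$poisson_areas)))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("tamorph")),
                   r_version = R.version.string,
                   pipeline = unclass(pipe),
                   generator = if (!is.null(generated))
                     unclass(generated$config)[
                       !vapply(generated$config, is.null, TRUE)] else NULL,
                   input_dir = input_dir, measure = measure,
                   cutoff_um2 = cutoff)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(cohort = cohort, measurements = measurements,
                 slide_summary = slide_summary, dispersion = dispersion,
                 roc = roc, cutoff = cutoff, univariate = uni,
                 survival = surv, cox = cox, spatial = spatial_res,
                 manifest = manifest),
            class = "tam_pipeline")
}

#' @export
print.tam_pipeline <- function(x, ...) {
  cat(sprintf("<tam_pipeline: %d patients, cutoff %.2f um^2 (%s)>\n",
              nrow(x$cohort), x$cutoff,
              if (is.null(x$roc)) "fixed" else "ROC-derived"))
  if (!is.null(x$roc))
    cat(sprintf("  ROC AUC %.3f (%.3f-%.3f), sens %.0f%% / spec %.0f%%\n",
                x$roc$auc, x$roc$auc_ci[1], x$roc$auc_ci[2],
                100 * x$roc$sens_at_cutoff, 100 * x$roc$spec_at_cutoff))
  cat(sprintf("  3-year DFS: S-TAM %.1f%%, L-TAM %.1f%% (log-rank p = %.2g)\n",
              100 * x$survival$dfs_3yr[["S-TAM"]],
              100 * x$survival$dfs_3yr[["L-TAM"]],
              x$survival$logrank_dfs$p_value))
  i <- match("ltam", x$cox$table$term)
  cat(sprintf("  Cox (multivariate) L-TAM HR %.2f (%.2f-%.2f), p = %.2g\n",
              x$cox$table$hr[i], x$cox$table$ci_lower[i],
              x$cox$table$ci_upper[i], x$cox$table$p_value[i]))
  if (!is.null(x$spatial))
    cat(sprintf("  Foci contrast (6 vs 6): Mann-Whitney p = %.4f\n",
                x$spatial$p_value))
  invisible(x)
}

# --- density map / foci writers --------------------------------------------

#' Write a density map as a plain-text raster plus JSON sidecar
#'
#' The counts matrix goes to `<path>.tsv` (rows = y, columns = x, `NA`
#' outside the band) and the grid metadata (origin, pixel size, radius) to
#' `<path>.json`.
#'
#' @param dm a [density_map()].
#' @param path output path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_density_map <- function(dm, path) {
  stopifnot(inherits(dm, "density_map"))
  utils::write.table(t(dm$counts), paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(slide_id = dm$slide_id, origin = dm$origin,
         pixel_size = dm$pixel_size, count_radius = dm$count_radius,
         nx = nrow(dm$counts), ny = ncol(dm$counts)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a density map written by [write_density_map()]
#'
#' @param path path stem used at write time.
#' @return A `density_map` object (mask = in-band pixels, i.e. non-`NA`).
#' @export
read_density_map <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  m <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  counts <- t(m)
  dimnames(counts) <- NULL
  structure(list(counts = counts, mask = !is.na(counts),
                 origin = as.numeric(meta$origin),
                 pixel_size = meta$pixel_size,
                 count_radius = meta$count_radius,
                 slide_id = meta$slide_id),
            class = "density_map")
}

#' Export foci as GeoJSON
#'
#' Each focus becomes a MultiPolygon of its raster pixels (squares in slide
#' coordinates) with properties focus_id and area_um2.
#'
#' @param fs a [detect_foci()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_foci_geojson <- function(fs, path) {
  stopifnot(inherits(fs, "foci_set"))
  h <- fs$pixel_size
  org <- fs$density$origin
  feats <- lapply(seq_len(nrow(fs$foci)), function(k) {
    px <- which(fs$labels == k, arr.ind = TRUE)
    polys <- lapply(seq_len(nrow(px)), function(j) {
      x0 <- org[1] + (px[j, 1] - 1) * h
      y0 <- org[2] + (px[j, 2] - 1) * h
      list(list(c(x0, y0), c(x0 + h, y0), c(x0 + h, y0 + h),
                c(x0, y0 + h), c(x0, y0)))
    })
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = polys),
         properties = list(focus_id = k,
                           area_um2 = fs$foci$area_um2[k]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
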