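# --- per-cell morphometry and the zone-averaged sampling protocol ----------

#' Measure traced outlines
#'
#' Computes shoelace area and edge-sum perimeter for each outline. Every
#' record satisfies the isoperimetric inequality perimeter^2 >= 4*pi*area.
#'
#' @param outlines list of [cell_outline()] objects.
#' @return data.frame with columns slide_id, zone_id, cell_id, area_um2,
#'   perimeter_um.
#' @export
measure_cells <- function(outlines) {
  stopifnot(length(outlines) > 0)
  rows <- lapply(outlines, function(o) {
    stopifnot(inherits(o, "cell_outline"))
    data.frame(slide_id = o$slide_id, zone_id = o$zone_id,
               cell_id = o$cell_id,
               area_um2 = polygon_area(o$vertices),
               perimeter_um = polygon_perimeter(o$vertices),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Deterministic per-slide child seed: adding or reordering slides must not
# perturb an earlier slide's draw, so each slide's RNG stream depends only
# on the global seed and its own id.
child_seed <- function(seed, slide_id) {
  h <- 0
  for (k in utf8ToInt(as.character(slide_id))) h <- (h * 31 + k) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

#' Sample cells following the three-zones-of-seven protocol
#'
#' Emulates the reading protocol: within each slide, `zones_per_slide`
#' annotated invasive-margin zones are selected, and in each selected zone
#' `cells_per_zone` macrophages are drawn uniformly without replacement
#' (defaults 3 x 7 = 21 cells per slide). Deterministic given `seed`; each
#' slide uses a child seed derived from the global seed and its id.
#'
#' @param outlines list of [cell_outline()] objects (one or more slides).
#' @param zones_per_slide,cells_per_zone sampling protocol sizes.
#' @param seed integer global seed.
#' @return list of sampled [cell_outline()] objects.
#' @export
sample_cells <- function(outlines, zones_per_slide = 3L, cells_per_zone = 7L,
                         seed = 1L) {
  stopifnot(length(outlines) > 0)
  slide_ids <- vapply(outlines, `[[`, "", "slide_id")
  zone_ids <- vapply(outlines, `[[`, "", "zone_id")
  idx <- sample_protocol_indices(slide_ids, zone_ids, zones_per_slide,
                                 cells_per_zone, seed)
  outlines[idx]
}

# Shared core of the sampling protocol, operating on parallel id vectors and
# returning the selected element indices. Used both on outline lists and on
# the generator's cell tables so the two measurement paths draw identically.
sample_protocol_indices <- function(slide_ids, zone_ids,
                                    zones_per_slide = 3L, cells_per_zone = 7L,
                                    seed = 1L) {
  stopifnot(length(slide_ids) == length(zone_ids),
            zones_per_slide >= 1, cells_per_zone >= 1)
  out <- integer(0)
  for (sid in unique(slide_ids)) {
    in_slide <- which(slide_ids == sid)
    zones <- split(in_slide, zone_ids[in_slide])
    if (length(zones) < zones_per_slide)
      stop("slide '", sid, "' has ", length(zones),
           " zones; protocol needs ", zones_per_slide)
    sel <- withr::with_seed(child_seed(seed, sid), {
      zsel <- sample(names(zones), zones_per_slide)
      picked <- integer(0)
      for (z in sort(zsel)) {
        cells <- zones[[z]]
        if (length(cells) < cells_per_zone)
          stop("under-sampled zone: zone '", z, "' of slide '", sid,
               "' has ", length(cells), " cells but ", cells_per_zone,
               " are required")
        picked <- c(picked, cells[sample(length(cells), cells_per_zone)])
      }
      picked
    })
    out <- c(out, sel)
  }
  out
}

#' Zone-level morphometry summary
#'
#' Arithmetic mean area and perimeter of the measured cells in each
#' (slide, zone).
#'
#' @param measurements data.frame from [measure_cells()].
#' @return data.frame with slide_id, zone_id, n_cells, mean_area_um2,
#'   mean_perimeter_um.
#' @export
summarize_zones <- function(measurements) {
  stopifnot(is.data.frame(measurements), nrow(measurements) > 0)
  key <- interaction(measurements$slide_id, measurements$zone_id, drop = TRUE)
  parts <- split(measurements, key)
  out <- do.call(rbind, lapply(parts, function(d)
    data.frame(slide_id = d$slide_id[1], zone_id = d$zone_id[1],
               n_cells = nrow(d),
               mean_area_um2 = mean(d$area_um2),
               mean_perimeter_um = mean(d$perimeter_um),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$slide_id, out$zone_id), , drop = FALSE]
}

#' Slide-level morphometry summary (mean of zone means)
#'
#' The per-slide value is the unweighted mean of the zone means — the
#' "average of three zones per patient" rule — not the pooled mean over all
#' cells; the two differ whenever zones contribute unequal cell counts.
#'
#' @param measurements data.frame from [measure_cells()].
#' @return data.frame with one row per slide: slide_id, n_zones, n_cells,
#'   mean_area_um2, mean_perimeter_um (zone-averaged), pooled_mean_area_um2,
#'   pooled_mean_perimeter_um.
#' @export
summarize_slides <- function(measurements) {
  z <- summarize_zones(measurements)
  parts <- split(z, z$slide_id)
  pooled <- split(measurements, measurements$slide_id)
  out <- do.call(rbind, lapply(names(parts), function(sid) {
    d <- parts[[sid]]; p <- pooled[[sid]]
    data.frame(slide_id = sid, n_zones = nrow(d), n_cells = sum(d$n_cells),
               mean_area_um2 = mean(d$mean_area_um2),
               mean_perimeter_um = mean(d$mean_perimeter_um),
               pooled_mean_area_um2 = mean(p$area_um2),
               pooled_mean_perimeter_um = mean(p$perimeter_um),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$slide_id), , drop = FALSE]
}

#' Cohort-level morphometry dispersion summary
#'
#' Reports mean +/- SD of area and perimeter both pooled over all measured
#' cells and over the zone-averaged slide means. The two dispersions answer
#' different questions (cell-to-cell vs patient-to-patient variability) and
#' are labelled explicitly.
#'
#' @param measurements data.frame from [measure_cells()].
#' @return data.frame with columns level ("cell" / "slide"), n, mean and sd
#'   of area and perimeter.
#' @export
cohort_morphometry_summary <- function(measurements) {
  s <- summarize_slides(measurements)
  data.frame(
    level = c("cell", "slide"),
    n = c(nrow(measurements), nrow(s)),
    mean_area_um2 = c(mean(measurements$area_um2), mean(s$mean_area_um2)),
    sd_area_um2 = c(stats::sd(measurements$area_um2), stats::sd(s$mean_area_um2)),
    mean_perimeter_um = c(mean(measurements$perimeter_um), mean(s$mean_perimeter_um)),
    sd_perimeter_um = c(stats::sd(measurements$perimeter_um), stats::sd(s$mean_perimeter_um)),
    stringsAsFactors = FALSE)
}
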