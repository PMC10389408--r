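# --- peritumoral band, density maps, foci -----------------------------------

#' Peritumoral band geometry
#'
#' The band is the outward offset of the tumor contour by `band_width`
#' minus the tumor interior — equivalently the set of points outside the
#' tumor whose distance to the contour is at most `band_width` (the
#' Minkowski sum of the contour with a disk, clipped to the exterior).
#'
#' @param tumor_contour simple polygon, n x 2 matrix in micrometres.
#' @param band_width band width in micrometres (default 500).
#' @param slide_id slide identifier.
#' @return Object of class `tumor_geometry`.
#' @export
tumor_geometry <- function(tumor_contour, band_width = 500,
                           slide_id = "slide") {
  stopifnot(is.numeric(band_width), band_width >= 0)
  v <- validate_polygon(tumor_contour, "tumor contour")
  structure(list(contour = v, band_width = band_width,
                 slide_id = as.character(slide_id)),
            class = "tumor_geometry")
}

#' @export
print.tumor_geometry <- function(x, ...) {
  cat(sprintf("<tumor_geometry %s: %d-vertex contour, band width %g um>\n",
              x$slide_id, nrow(x$contour), x$band_width))
  invisible(x)
}

#' Band membership test
#'
#' @param geometry a [tumor_geometry()].
#' @param x,y point coordinates (micrometres).
#' @return logical vector: inside the peritumoral band?
#' @export
in_band <- function(geometry, x, y) {
  stopifnot(inherits(geometry, "tumor_geometry"))
  p <- cbind(as.numeric(x), as.numeric(y))
  inside <- points_in_polygon(p, geometry$contour)
  d <- dist_to_polygon(p, geometry$contour)
  !inside & d <= geometry$band_width
}

# signed distance to the band region (negative inside the band):
# inside tumor -> +d; outside, beyond the offset -> d - w; in band ->
# -min(d, w - d)
band_signed_distance <- function(geometry, p) {
  w <- geometry$band_width
  d <- dist_to_polygon(p, geometry$contour)
  inside <- points_in_polygon(p, geometry$contour)
  ifelse(inside, d, pmax(d - w, -pmin(d, w - d)))
}

#' Peritumoral band area
#'
#' Area of the band region, computed by two-pass adaptive rasterization of
#' the band's signed distance field: a coarse grid classifies cells as
#' fully inside, fully outside, or straddling a band boundary; straddling
#' cells are refined and each fine sample contributes an anti-aliased
#' coverage fraction clamped from its signed distance. The estimate
#' converges much faster than binary pixel counting (closed-form annulus
#' tests agree to well under 0.5%) and memory stays bounded regardless of
#' the band-width/contour-size ratio.
#'
#' @param geometry a [tumor_geometry()].
#' @param resolution fine sampling pitch in micrometres; default
#'   band_width/50, never finer than 1/32 of the coarse cell.
#' @return Band area in square micrometres.
#' @export
band_area <- function(geometry, resolution = NULL) {
  stopifnot(inherits(geometry, "tumor_geometry"))
  w <- geometry$band_width
  if (w == 0) return(0)
  v <- geometry$contour
  ext <- max(diff(range(v[, 1])), diff(range(v[, 2]))) + 2 * w
  H <- ext / 128
  h <- if (is.null(resolution)) w / 50 else resolution
  stopifnot(h > 0)
  h <- max(h, H / 32)
  m <- max(1L, ceiling(H / h))
  hf <- H / m
  xs <- seq(min(v[, 1]) - w - H, max(v[, 1]) + w + H, by = H)
  ys <- seq(min(v[, 2]) - w - H, max(v[, 2]) + w + H, by = H)
  ctr <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  g <- band_signed_distance(geometry, ctr)
  half_diag <- H * sqrt(2) / 2
  full <- g <= -half_diag
  border <- which(!full & g < half_diag)
  area <- sum(full) * H * H
  if (length(border)) {
    off <- (seq_len(m) - (m + 1) / 2) * hf
    sub <- as.matrix(expand.grid(dx = off, dy = off))
    # refine straddling cells in blocks to bound memory
    for (chunk in split(border, ceiling(seq_along(border) / 256))) {
      p <- cbind(rep(ctr[chunk, 1], each = nrow(sub)) + sub[, 1],
                 rep(ctr[chunk, 2], each = nrow(sub)) + sub[, 2])
      gf <- band_signed_distance(geometry, p)
      cov <- pmin(pmax(0.5 - gf / hf, 0), 1)
      area <- area + sum(cov) * hf * hf
    }
  }
  area
}

band_grid <- function(geometry, pixel_size) {
  v <- geometry$contour
  w <- geometry$band_width
  x0 <- floor((min(v[, 1]) - w - pixel_size) / pixel_size) * pixel_size
  y0 <- floor((min(v[, 2]) - w - pixel_size) / pixel_size) * pixel_size
  nx <- ceiling((max(v[, 1]) + w + pixel_size - x0) / pixel_size)
  ny <- ceiling((max(v[, 2]) + w + pixel_size - y0) / pixel_size)
  list(origin = c(x0, y0), nx = as.integer(nx), ny = as.integer(ny),
       cx = x0 + (seq_len(nx) - 0.5) * pixel_size,
       cy = y0 + (seq_len(ny) - 0.5) * pixel_size)
}

#' L-TAM density map over the peritumoral band
#'
#' Regular raster whose in-band pixels hold the exact number of centroids
#' within `count_radius` (closed ball, Euclidean distance) of the pixel
#' centre. No approximation is used in the counts; only the band mask is a
#' polygon-raster discretization. Pixels outside the band are `NA`.
#'
#' @param centroids m x 2 matrix (or data.frame with x, y) of L-TAM
#'   centroid coordinates in micrometres.
#' @param geometry a [tumor_geometry()].
#' @param count_radius counting radius, micrometres (default 500).
#' @param pixel_size raster pitch, micrometres (default 20; must be smaller
#'   than `count_radius`).
#' @return Object of class `density_map`: `counts` (nx x ny integer matrix,
#'   `NA` outside the band), `mask`, `origin`, `pixel_size`,
#'   `count_radius`, `slide_id`.
#' @export
density_map <- function(centroids, geometry, count_radius = 500,
                        pixel_size = 20) {
  stopifnot(inherits(geometry, "tumor_geometry"),
            pixel_size > 0, count_radius > 0, pixel_size < count_radius)
  pts <- as.matrix(as.data.frame(centroids)[, 1:2, drop = FALSE])
  g <- band_grid(geometry, pixel_size)
  centres <- cbind(rep(g$cx, times = g$ny), rep(g$cy, each = g$nx))
  mask <- matrix(in_band(geometry, centres[, 1], centres[, 2]),
                 nrow = g$nx, ncol = g$ny)
  if (!any(mask)) stop("empty band: no raster pixel falls in the ",
                       "peritumoral band")
  counts <- matrix(0L, g$nx, g$ny)
  if (nrow(pts) > 0) {
    r2 <- count_radius^2
    for (i in seq_len(nrow(pts))) {
      ix <- which(abs(g$cx - pts[i, 1]) <= count_radius)
      iy <- which(abs(g$cy - pts[i, 2]) <= count_radius)
      if (!length(ix) || !length(iy)) next
      dx2 <- (g$cx[ix] - pts[i, 1])^2
      dy2 <- (g$cy[iy] - pts[i, 2])^2
      hit <- outer(dx2, dy2, `+`) <= r2
      counts[ix, iy] <- counts[ix, iy] + hit
    }
  }
  counts[!mask] <- NA_integer_
  structure(list(counts = counts, mask = mask, origin = g$origin,
                 pixel_size = pixel_size, count_radius = count_radius,
                 slide_id = geometry$slide_id),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(paste0("<density_map %s: %d x %d px @ %g um, radius %g um, ",
                     "max in-band count %d>\n"),
              x$slide_id, nrow(x$counts), ncol(x$counts), x$pixel_size,
              x$count_radius, suppressWarnings(max(x$counts, na.rm = TRUE))))
  invisible(x)
}

# 8-connectivity connected-component labeling of a logical matrix
# (union-find over the four forward neighbour offsets).
label_components <- function(bin) {
  stopifnot(is.matrix(bin))
  bin[is.na(bin)] <- FALSE
  lab <- matrix(0L, nrow(bin), ncol(bin))
  idx <- which(bin)
  if (!length(idx)) return(lab)
  id <- matrix(0L, nrow(bin), ncol(bin))
  id[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  nr <- nrow(bin); nc <- ncol(bin)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + off[1L]; c2 <- cols + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- id[cbind(r2[ok], c2[ok])]
    me <- id[idx[ok]]
    pair <- which(nb > 0L)
    for (k in pair) {
      ra <- find(me[k]); rb <- find(nb[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Detect high-density L-TAM foci
#'
#' Recomputes the count field at `foci_radius` (counts at different radii
#' are not proportional, so the 500-um map is not rescaled), thresholds it
#' at `threshold` or more L-TAMs, and labels connected components of
#' supra-threshold in-band pixels with 8-connectivity. Per-focus area is
#' pixel count x pixel_size^2.
#'
#' @inheritParams density_map
#' @param foci_radius counting radius for foci detection, micrometres
#'   (default 200).
#' @param threshold minimum L-TAM count within `foci_radius` (default 100).
#' @return Object of class `foci_set`: `foci` (data.frame focus_id,
#'   n_pixels, area_um2), `total_area_um2`, `labels` matrix, the underlying
#'   `density_map`, and the parameters.
#' @export
detect_foci <- function(centroids, geometry, foci_radius = 200,
                        threshold = 100, pixel_size = 20) {
  stopifnot(threshold > 0)
  dm <- density_map(centroids, geometry, count_radius = foci_radius,
                    pixel_size = pixel_size)
  bin <- !is.na(dm$counts) & dm$counts >= threshold
  lab <- label_components(bin)
  nfoci <- max(lab)
  foci <- if (nfoci > 0) {
    np <- tabulate(lab[lab > 0L], nbins = nfoci)
    data.frame(focus_id = seq_len(nfoci), n_pixels = np,
               area_um2 = np * pixel_size^2)
  } else {
    data.frame(focus_id = integer(0), n_pixels = integer(0),
               area_um2 = numeric(0))
  }
  structure(list(foci = foci, total_area_um2 = sum(foci$area_um2),
                 labels = lab, density = dm, foci_radius = foci_radius,
                 threshold = threshold, pixel_size = pixel_size,
                 slide_id = geometry$slide_id),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set %s: %d foci, total area %.0f um^2 (>=%d L-TAMs in %g um)>\n",
              x$slide_id, nrow(x$foci), x$total_area_um2, x$threshold,
              x$foci_radius))
  invisible(x)
}

#' Compare total foci areas between two groups of slides
#'
#' Two-sided Mann-Whitney U test on per-slide total foci areas: exact by
#' full enumeration when both groups have at most 8 slides (the 6-vs-6
#' design), normal approximation above.
#'
#' @param group_a,group_b numeric vectors of per-slide total foci areas.
#' @return list with `U`, `p_value`, `method`, group sizes and medians.
#' @export
compare_foci <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  mw <- mann_whitney(group_a, group_b, exact_limit = 8L)
  c(mw, list(n_a = length(group_a), n_b = length(group_b),
             median_a = stats::median(group_a),
             median_b = stats::median(group_b)))
}
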