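# --- GeoJSON slide annotation I/O -------------------------------------------
# One FeatureCollection per slide: each cell outline a Polygon Feature with
# properties {cell_id, zone_id, marker}; the tumor contour a Polygon Feature
# with property {role: "tumor"}. Coordinates are (x, y) in micrometres after
# the microns-per-pixel scale factor is applied on read (image convention:
# x right, y down).

#' Write slide annotations to GeoJSON
#'
#' @param outlines list of [cell_outline()] objects for one slide.
#' @param tumor_contour n x 2 matrix, the tumor contour polygon
#'   (micrometres), or `NULL` to omit.
#' @param path output file path.
#' @param slide_id slide identifier stored at the collection level.
#' @return `path`, invisibly.
#' @export
write_slide_geojson <- function(outlines, tumor_contour, path,
                                slide_id = NULL) {
  close_ring <- function(v) rbind(v, v[1L, , drop = FALSE])
  feats <- lapply(outlines, function(o) {
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(close_ring(o$vertices))),
         properties = list(cell_id = o$cell_id, zone_id = o$zone_id,
                           marker = o$marker))
  })
  if (!is.null(tumor_contour)) {
    v <- validate_polygon(tumor_contour, "tumor contour")
    feats <- c(feats, list(list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(close_ring(v))),
      properties = list(role = "tumor"))))
  }
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(slide_id)) fc$slide_id <- as.character(slide_id)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

ring_to_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p)[1:2])))
  # GeoJSON rings repeat the first point as the last; drop the duplicate
  if (nrow(m) > 1 && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Read slide annotations from GeoJSON
#'
#' Parses a FeatureCollection of traced macrophage outlines plus the tumor
#' contour. Every outline is validated on load; malformed features (too few
#' vertices, self-intersections, missing properties) are rejected
#' individually with a warning naming the feature, while valid features are
#' kept. A missing tumor contour, an empty collection, or a CRS declaration
#' (slide annotations are in the slide frame, not a geographic CRS) are
#' errors.
#'
#' @param path GeoJSON file path.
#' @param microns_per_pixel scale factor applied to all coordinates on load
#'   (default 1: coordinates already in micrometres).
#' @param slide_id slide identifier to assign; default: the collection's
#'   `slide_id` member, else the file name without extension.
#' @return list with `outlines` (list of [cell_outline()]), `tumor` (matrix)
#'   and `slide_id`.
#' @export
read_slide_annotations <- function(path, microns_per_pixel = 1,
                                   slide_id = NULL) {
  stopifnot(is.numeric(microns_per_pixel), microns_per_pixel > 0)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("'", path, "' is not a GeoJSON FeatureCollection")
  if (!is.null(fc$crs))
    stop("'", path, "' declares a CRS; slide annotations must be in the ",
         "slide coordinate frame (micrometres or pixels + scale factor)")
  if (length(fc$features) == 0)
    stop("empty FeatureCollection: '", path, "'")
  if (is.null(slide_id))
    slide_id <- if (!is.null(fc$slide_id)) fc$slide_id else
      sub("\\.[^.]*$", "", basename(path))
  outlines <- list()
  tumor <- NULL
  for (i in seq_along(fc$features)) {
    ft <- fc$features[[i]]
    props <- ft$properties
    geom <- ft$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      warning("feature ", i, " in '", basename(path),
              "' is not a Polygon; skipped")
      next
    }
    v <- ring_to_matrix(geom$coordinates[[1L]]) * microns_per_pixel
    if (identical(props$role, "tumor")) {
      tumor <- validate_polygon(v, "tumor contour")
      next
    }
    cid <- if (!is.null(props$cell_id)) props$cell_id else paste0("feature_", i)
    res <- tryCatch(
      cell_outline(cell_id = cid,
                   slide_id = slide_id,
                   zone_id = if (!is.null(props$zone_id)) props$zone_id else "unzoned",
                   vertices = v,
                   marker = if (!is.null(props$marker)) props$marker else "CD163+"),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("rejected outline '", cid, "' in '", basename(path), "': ",
              conditionMessage(res))
    } else {
      outlines[[length(outlines) + 1L]] <- res
    }
  }
  if (is.null(tumor))
    stop("no tumor contour (feature with property role='tumor') in '",
         path, "'")
  list(outlines = outlines, tumor = tumor, slide_id = slide_id)
}
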