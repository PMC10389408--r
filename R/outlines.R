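# --- cell outlines ----------------------------------------------------------

#' Construct a validated cell outline
#'
#' A cell outline is one manually traced CD163+ macrophage: a closed simple
#' polygon in slide coordinates (micrometres, x right / y down), tagged with
#' the slide and invasive-margin zone it was traced in.
#'
#' @param cell_id,slide_id,zone_id identifiers (coerced to character).
#' @param vertices n x 2 numeric matrix, micrometres, implicitly closed
#'   (first vertex not repeated).
#' @param marker immunohistochemical marker label.
#' @return An object of class `cell_outline`.
#' @export
cell_outline <- function(cell_id, slide_id, zone_id, vertices,
                         marker = "CD163+") {
  v <- validate_polygon(vertices, what = paste0("outline '", cell_id, "'"))
  structure(
    list(cell_id = as.character(cell_id),
         slide_id = as.character(slide_id),
         zone_id = as.character(zone_id),
         vertices = v,
         marker = as.character(marker)),
    class = "cell_outline")
}

#' @export
print.cell_outline <- function(x, ...) {
  cat(sprintf("<cell_outline %s | slide %s zone %s | %d vertices | %s>\n",
              x$cell_id, x$slide_id, x$zone_id, nrow(x$vertices), x$marker))
  invisible(x)
}

#' Render a synthetic cell outline of prescribed area
#'
#' Draws a star-shaped polygon (12-40 vertices) around the origin with
#' radial and angular jitter controlled by `irregularity`, then rescales it
#' so the shoelace area matches `target_area` exactly. `irregularity = 0`
#' yields a regular polygon. Star-shaped construction guarantees the
#' outline is simple.
#'
#' @param target_area desired polygon area, square micrometres (> 0).
#' @param irregularity fraction in `[0, 0.5)`; 0 = regular polygon.
#' @param n_vertices vertex count; default: drawn uniformly from 12-40.
#' @param centre length-2 numeric, outline centre in slide coordinates.
#' @param seed optional integer; when given, rendering is deterministic and
#'   leaves the global RNG untouched.
#' @param cell_id,slide_id,zone_id,marker passed to [cell_outline()].
#' @return A [cell_outline()].
#' @export
render_cell_outline <- function(target_area, irregularity = 0.15,
                                n_vertices = NULL, centre = c(0, 0),
                                seed = NULL, cell_id = "cell",
                                slide_id = "slide", zone_id = "zone",
                                marker = "CD163+") {
  stopifnot(is.numeric(target_area), length(target_area) == 1L,
            target_area > 0, irregularity >= 0, irregularity < 0.5)
  draw <- function() {
    n <- if (is.null(n_vertices)) sample(12:40, 1L) else as.integer(n_vertices)
    step <- 2 * pi / n
    ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    if (irregularity > 0) {
      # |jitter| < 0.45*step even at irregularity -> 0.5, so angles stay
      # strictly increasing and the polygon star-shaped
      ang <- ang + stats::runif(n, -irregularity, irregularity) / 0.5 * 0.45 * step
      r <- 1 + stats::runif(n, -irregularity, irregularity)
    } else {
      r <- rep(1, n)
    }
    cbind(r * cos(ang), r * sin(ang))
  }
  xy <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  xy <- xy * sqrt(target_area / abs(shoelace_signed(xy)))
  xy[, 1] <- xy[, 1] + centre[1]
  xy[, 2] <- xy[, 2] + centre[2]
  cell_outline(cell_id, slide_id, zone_id, xy, marker)
}
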