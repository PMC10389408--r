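# --- low-level polygon geometry ---------------------------------------------
# Vertices are an n x 2 numeric matrix in micrometres, implicitly closed
# (the first vertex is not repeated as the last row).

as_vertex_matrix <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stop("invalid geometry: vertices must be an n x 2 numeric matrix")
  storage.mode(v) <- "double"
  unname(v)
}

#' Validate a polygon vertex sequence
#'
#' Checks the invariants required of a traced cell outline or tumor contour:
#' at least three vertices, all coordinates finite, no repeated consecutive
#' vertices, simple (non-self-intersecting), and non-zero signed area.
#' Self-intersecting outlines are rejected, never repaired: a silently
#' "fixed" trace would corrupt the morphometry.
#'
#' @param vertices n x 2 numeric matrix of (x, y) coordinates in micrometres,
#'   implicitly closed.
#' @param what label used in error messages.
#' @return The validated vertex matrix, invisibly usable downstream.
#' @export
validate_polygon <- function(vertices, what = "polygon") {
  v <- as_vertex_matrix(vertices)
  if (nrow(v) < 3L)
    stop("invalid geometry: ", what, " has fewer than 3 vertices")
  if (!all(is.finite(v)))
    stop("invalid geometry: ", what, " has non-finite coordinates")
  d <- rbind(diff(v), v[1L, ] - v[nrow(v), ])
  if (any(rowSums(d^2) == 0))
    stop("invalid geometry: ", what, " has repeated consecutive vertices")
  if (!polygon_is_simple(v))
    stop("invalid geometry: ", what, " is self-intersecting")
  if (abs(shoelace_signed(v)) == 0)
    stop("invalid geometry: ", what, " has zero signed area")
  v
}

shoelace_signed <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area by the shoelace formula
#'
#' Absolute value of the signed (shoelace) area, so the result is
#' independent of vertex orientation. The polygon must be simple; traced
#' outlines that self-intersect are rejected with an error.
#'
#' @param vertices n x 2 matrix of vertices in micrometres, implicitly
#'   closed.
#' @return Area in square micrometres.
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # 1
#' @export
polygon_area <- function(vertices) {
  v <- validate_polygon(vertices)
  abs(shoelace_signed(v))
}

#' Polygon perimeter by edge-length summation
#'
#' Sum of Euclidean edge lengths, including the closing edge from the last
#' vertex back to the first.
#'
#' @inheritParams polygon_area
#' @return Perimeter in micrometres.
#' @export
polygon_perimeter <- function(vertices) {
  v <- validate_polygon(vertices)
  d <- rbind(diff(v), v[1L, ] - v[nrow(v), ])
  sum(sqrt(rowSums(d^2)))
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon; used as the canonical point
#' reduction of a cell outline for spatial analysis.
#'
#' @inheritParams polygon_area
#' @return Numeric length-2 vector (x, y) in micrometres.
#' @export
polygon_centroid <- function(vertices) {
  v <- as_vertex_matrix(vertices)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Simplicity: no two non-adjacent edges intersect or touch. O(n^2) over edge
# pairs, vectorised over the second edge; outlines have <= ~100 vertices.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  a <- v
  b <- v[nxt, , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    # edges adjacent to i share a vertex and may "touch" legitimately
    j <- j[!(j == i + 1L) & !(i == 1L & j == n)]
    if (!length(j)) next
    if (any(segment_intersects(a[i, ], b[i, ], a[j, , drop = FALSE],
                               b[j, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# Does segment p-q intersect (incl. touch / collinear overlap) each segment
# a[k,]-b[k,]? Exact double-precision orientation tests.
segment_intersects <- function(p, q, a, b) {
  orient <- function(o1, o2, s1, s2, t1, t2)
    (s1 - o1) * (t2 - o2) - (s2 - o2) * (t1 - o1)
  d1 <- orient(p[1], p[2], q[1], q[2], a[, 1], a[, 2])
  d2 <- orient(p[1], p[2], q[1], q[2], b[, 1], b[, 2])
  d3 <- orient(a[, 1], a[, 2], b[, 1], b[, 2], rep(p[1], nrow(a)), rep(p[2], nrow(a)))
  d4 <- orient(a[, 1], a[, 2], b[, 1], b[, 2], rep(q[1], nrow(a)), rep(q[2], nrow(a)))
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  on_seg <- function(d, u1, u2, w1, w2, z1, z2) {
    # collinear point (z) within bounding box of segment (u, w)
    d == 0 &
      pmin(u1, w1) <= z1 & z1 <= pmax(u1, w1) &
      pmin(u2, w2) <= z2 & z2 <= pmax(u2, w2)
  }
  touch <- on_seg(d1, p[1], p[2], q[1], q[2], a[, 1], a[, 2]) |
    on_seg(d2, p[1], p[2], q[1], q[2], b[, 1], b[, 2]) |
    on_seg(d3, a[, 1], a[, 2], b[, 1], b[, 2], p[1], p[2]) |
    on_seg(d4, a[, 1], a[, 2], b[, 1], b[, 2], q[1], q[2])
  proper | touch
}

# Minimum distance from each point (m x 2) to the boundary of polygon v
# (closed). Vectorised over points, looped over the polygon's edges.
dist_to_polygon <- function(points, v) {
  p <- as_vertex_matrix(points)
  v <- as_vertex_matrix(v)
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  d2 <- rep(Inf, nrow(p))
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[nxt[i], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- p[, 1] - (a[1] + t * ab[1])
    dy <- p[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Point-in-polygon (strict interior test is not needed; boundary points are
# measure-zero for the raster uses here).
points_in_polygon <- function(points, v) {
  p <- as_vertex_matrix(points)
  v <- as_vertex_matrix(v)
  pracma::inpolygon(p[, 1], p[, 2], v[, 1], v[, 2])
}
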