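# Independent oracles, kept deliberately separate from the package's own
# computational routes.

# fan triangulation from a given interior point (valid for star-shaped
# polygons around that point); sums signed triangle areas
fan_area <- function(v, centre = c(0, 0)) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    a <- v[i, ] - centre
    b <- v[(i %% n) + 1L, ] - centre
    s <- s + (a[1] * b[2] - a[2] * b[1]) / 2
  }
  abs(s)
}

# direct pairwise edge-length summation
edge_sum_perimeter <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- (i %% n) + 1L
    s <- s + sqrt(sum((v[j, ] - v[i, ])^2))
  }
  s
}

# random simple polygon: star-shaped around the origin by construction
# (jittered equispaced angles keep every angular gap in (0, pi), so the
# boundary crosses each ray from the origin exactly once)
random_star_polygon <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:40, 1)
  ang <- 2 * pi * (seq_len(n) - 1) / n + runif(n, -0.45, 0.45) * 2 * pi / n
  r <- runif(n, 0.2, 1) * runif(1, 1, 50)
  cbind(r * cos(ang), r * sin(ang))
}

# tie-corrected pair-concordance AUC: P(case > control) + 0.5 P(tie)
pair_concordance_auc <- function(values, events) {
  pos <- values[as.logical(events)]
  neg <- values[!as.logical(events)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# two-group log-rank by explicit per-event-time 2x2 hypergeometric tables
logrank_oracle <- function(times, events, group) {
  g <- as.integer(factor(group)) == 1L
  ts <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# hand product-limit estimator (no package calls)
km_hand <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# brute-force all-pairs count of points within r of each probe centre
brute_count <- function(points, centres, r) {
  pts <- as.matrix(points)
  apply(as.matrix(centres), 1, function(ctr) {
    if (nrow(pts) == 0) return(0L)
    sum((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 <= r^2)
  })
}

# independent 8-connectivity labeling by explicit-stack flood fill
flood_fill_labels <- function(bin) {
  bin[is.na(bin)] <- FALSE
  lab <- matrix(0L, nrow(bin), ncol(bin))
  cur <- 0L
  for (start in which(bin & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[s] != 0L) next
      lab[s] <- cur
      r <- ((s - 1L) %% nrow(bin)) + 1L
      cl <- ((s - 1L) %/% nrow(bin)) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cl + dc
        if (r2 >= 1 && r2 <= nrow(bin) && c2 >= 1 && c2 <= ncol(bin) &&
            bin[r2, c2] && lab[r2, c2] == 0L)
          stack <- c(stack, (c2 - 1L) * nrow(bin) + r2)
      }
    }
  }
  lab
}

# square cell outline of a given area (simple deterministic fixture)
square_outline <- function(area, cell_id, slide_id = "S1", zone_id = "Z1") {
  s <- sqrt(area)
  cell_outline(cell_id, slide_id, zone_id,
               cbind(c(0, s, s, 0), c(0, 0, s, s)))
}

# a slide's worth of square outlines with prescribed per-zone areas
make_slide <- function(slide_id, zone_areas) {
  out <- list()
  for (z in names(zone_areas)) {
    for (k in seq_along(zone_areas[[z]])) {
      out[[length(out) + 1L]] <- square_outline(
        zone_areas[[z]][k], sprintf("%s_%s_C%02d", slide_id, z, k),
        slide_id, z)
    }
  }
  out
}

# regular n-gon of circumradius r centred at the origin
regular_ngon <- function(n, r) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}
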