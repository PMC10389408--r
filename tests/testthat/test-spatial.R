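circle_geom <- function(R = 500, band = 500, n = 360)
  tumor_geometry(regular_ngon(n, R), band)

test_that("band area matches closed forms for circle and square", {
  g <- circle_geom(500, 500)
  expect_equal(band_area(g), pi * (1000^2 - 500^2), tolerance = 0.005)
  sq <- tumor_geometry(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)), 500)
  expect_equal(band_area(sq), 4 * 1000 * 500 + pi * 500^2, tolerance = 0.005)
  # band width -> 0 collapses the band
  expect_equal(band_area(tumor_geometry(regular_ngon(90, 500), 0)), 0)
  thin <- band_area(tumor_geometry(regular_ngon(90, 50), 5))
  expect_equal(thin, pi * (55^2 - 50^2), tolerance = 0.02)
})

test_that("band membership excludes the tumor interior and distant points", {
  g <- circle_geom(500, 500)
  expect_false(in_band(g, 0, 0))        # tumor centre
  expect_true(in_band(g, 700, 0))       # 200 um outside the contour
  expect_false(in_band(g, 1200, 0))     # beyond the band
  pts <- tamorph:::uniform_in_band(200, g)
  r <- sqrt(rowSums(pts^2))
  expect_true(all(r >= 500 * cos(pi / 360) - 1e-9 & r <= 1000 + 1e-9))
})

test_that("density counts are exact against the brute-force oracle", {
  g <- circle_geom(400, 400, n = 90)
  # single centroid: a pixel within the radius counts 1, beyond counts 0
  dm1 <- density_map(cbind(600, 0), g, count_radius = 500, pixel_size = 25)
  grid <- tamorph:::band_grid(g, 25)
  centres <- cbind(rep(grid$cx, times = grid$ny), rep(grid$cy, each = grid$nx))
  inb <- which(!is.na(dm1$counts))
  d <- sqrt((centres[inb, 1] - 600)^2 + (centres[inb, 2] - 0)^2)
  expect_equal(as.vector(dm1$counts[inb]), as.integer(d <= 500))
  # k coincident centroids read k everywhere within the radius
  k <- 7
  dmk <- density_map(matrix(rep(c(600, 0), each = k), ncol = 2), g,
                     count_radius = 500, pixel_size = 25)
  expect_equal(as.vector(dmk$counts[inb]), k * as.integer(d <= 500))
  # 200 random centroids vs all-pairs scan, exact integer equality
  withr::local_seed(14)
  pts <- tamorph:::uniform_in_band(200, g)
  dm <- density_map(pts, g, count_radius = 500, pixel_size = 25)
  expect_identical(as.integer(dm$counts[inb]),
                   as.integer(brute_count(pts, centres[inb, ], 500)))
  # a second configuration at a different radius
  dm2 <- density_map(pts, g, count_radius = 200, pixel_size = 25)
  expect_identical(as.integer(dm2$counts[inb]),
                   as.integer(brute_count(pts, centres[inb, ], 200)))
})

test_that("foci detection matches the thresholded-count + flood-fill oracle", {
  g <- circle_geom(400, 500, n = 90)
  # fewer centroids than the threshold can never form a focus
  withr::local_seed(9)
  few <- tamorph:::uniform_in_band(60, g)
  expect_equal(detect_foci(few, g)$total_area_um2, 0)
  # one tight cluster of 150 cells -> a single focus
  ctr <- c(650, 0)
  clus <- cbind(ctr[1] + runif(150, -50, 50), ctr[2] + runif(150, -50, 50))
  fs <- detect_foci(clus, g)
  expect_equal(nrow(fs$foci), 1)
  expect_gt(fs$total_area_um2, 0)
  # oracle: brute-force counts, threshold, flood fill
  grid <- tamorph:::band_grid(g, 20)
  centres <- cbind(rep(grid$cx, times = grid$ny), rep(grid$cy, each = grid$nx))
  mask <- matrix(in_band(g, centres[, 1], centres[, 2]), grid$nx, grid$ny)
  cnt <- matrix(brute_count(clus, centres, 200), grid$nx, grid$ny)
  bin <- mask & cnt >= 100
  lab <- flood_fill_labels(bin)
  expect_equal(fs$total_area_um2, sum(bin) * 20^2)
  expect_equal(nrow(fs$foci), max(lab))
  # two clusters far apart -> exactly two disjoint foci
  clus2 <- rbind(clus, cbind(-clus[, 1], clus[, 2]))  # mirrored, ~1300 um away
  fs2 <- detect_foci(clus2, g)
  expect_equal(nrow(fs2$foci), 2)
  expect_equal(fs2$total_area_um2, sum(fs2$foci$area_um2))
})

test_that("total foci area is monotone in threshold and radius", {
  g <- circle_geom(400, 500, n = 90)
  withr::local_seed(17)
  ctr <- tamorph:::uniform_in_band(2, g)
  pts <- rbind(cbind(rnorm(160, ctr[1, 1], 60), rnorm(160, ctr[1, 2], 60)),
               cbind(rnorm(120, ctr[2, 1], 80), rnorm(120, ctr[2, 2], 80)))
  pts <- pts[in_band(g, pts[, 1], pts[, 2]), ]
  by_thr <- sapply(c(40, 80, 120, 160), function(th)
    detect_foci(pts, g, threshold = th)$total_area_um2)
  expect_true(all(diff(by_thr) <= 0))
  by_rad <- sapply(c(100, 150, 200, 300), function(r)
    detect_foci(pts, g, foci_radius = r)$total_area_um2)
  expect_true(all(diff(by_rad) >= 0))
})

test_that("foci area is stable under grid refinement and rigid motion", {
  g <- circle_geom(400, 500, n = 120)
  withr::local_seed(23)
  ctr <- c(600, 100)
  pts <- cbind(rnorm(400, ctr[1], 90), rnorm(400, ctr[2], 90))
  pts <- pts[in_band(g, pts[, 1], pts[, 2]), ]
  a20 <- detect_foci(pts, g, pixel_size = 20)$total_area_um2
  a10 <- detect_foci(pts, g, pixel_size = 10)$total_area_um2
  expect_lt(abs(a20 - a10) / a10, 0.05)
  # translation by whole pixels: bit-identical counts
  sh <- 40
  g2 <- tumor_geometry(sweep(g$contour, 2, c(sh, sh), `+`), g$band_width)
  a_sh <- detect_foci(sweep(pts, 2, c(sh, sh), `+`), g2,
                      pixel_size = 20)$total_area_um2
  expect_identical(a_sh, a20)
  # rotation: equal up to re-discretization
  th <- pi / 7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g3 <- tumor_geometry(g$contour %*% rot, g$band_width)
  a_rot <- detect_foci(pts %*% rot, g3, pixel_size = 20)$total_area_um2
  expect_lt(abs(a_rot - a20) / a20, 0.05)
})

test_that("foci-area comparison is the exact Mann-Whitney at 6 vs 6", {
  same <- c(10, 20, 30, 40, 50, 60)
  expect_equal(compare_foci(same, same)$p_value, 1)
  res <- compare_foci(c(5e4, 3e4, 9e4, 6e4, 4e4, 7e4), rep(0, 6))
  expect_equal(res$p_value, 2 / choose(12, 6), tolerance = 1e-12)
  expect_match(res$method, "exact")
  # rank statistics are scale-free in the shift: any positive offset gives
  # the same p, and exactly tied groups are null
  tied <- compare_foci(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))$p_value
  expect_equal(tied, 1)
  p_small <- compare_foci(c(0, 0, 0, 1, 1, 1) + 1e-9,
                          c(0, 0, 0, 1, 1, 1))$p_value
  p_large <- compare_foci(c(0, 0, 0, 1, 1, 1) + 0.5,
                          c(0, 0, 0, 1, 1, 1))$p_value
  expect_equal(p_small, p_large, tolerance = 1e-12)
  expect_error(compare_foci(numeric(0), 1:3), "empty")
})

test_that("density maps round-trip through the raster writer", {
  g <- circle_geom(300, 300, n = 60)
  withr::local_seed(3)
  pts <- tamorph:::uniform_in_band(50, g)
  dm <- density_map(pts, g, count_radius = 400, pixel_size = 30)
  stem <- withr::local_tempfile()
  write_density_map(dm, stem)
  back <- read_density_map(stem)
  expect_identical(unname(back$counts), unname(dm$counts))
  expect_equal(back$origin, dm$origin)
  expect_equal(back$pixel_size, dm$pixel_size)
  # foci export is valid GeoJSON with one feature per focus
  ctr <- c(450, 0)
  clus <- cbind(rnorm(200, ctr[1], 40), rnorm(200, ctr[2], 40))
  fs <- detect_foci(clus, g, pixel_size = 30)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_foci_geojson(fs, gj)
  parsed <- jsonlite::fromJSON(gj, simplifyVector = FALSE)
  expect_identical(parsed$type, "FeatureCollection")
  expect_length(parsed$features, nrow(fs$foci))
})
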