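three_zone_slide <- function(slide_id = "S1", per_zone = 10) {
  make_slide(slide_id, list(Z1 = 100 + seq_len(per_zone),
                            Z2 = 200 + seq_len(per_zone),
                            Z3 = 300 + seq_len(per_zone)))
}

test_that("the sampling protocol returns 3 zones x 7 cells per slide", {
  sl <- three_zone_slide()
  s <- sample_cells(sl, seed = 5)
  expect_length(s, 21)
  zones <- table(vapply(s, `[[`, "", "zone_id"))
  expect_equal(as.vector(zones), c(7, 7, 7))
  # no replacement
  expect_false(any(duplicated(vapply(s, `[[`, "", "cell_id"))))
  # single zone, single cell
  s1 <- sample_cells(sl, zones_per_slide = 1, cells_per_zone = 1, seed = 5)
  expect_length(s1, 1)
})

test_that("sampling is deterministic and per-slide streams are stable", {
  sl <- c(three_zone_slide("A"), three_zone_slide("B"))
  ids <- function(x) vapply(x, `[[`, "", "cell_id")
  expect_identical(ids(sample_cells(sl, seed = 7)),
                   ids(sample_cells(sl, seed = 7)))
  expect_false(identical(ids(sample_cells(sl, seed = 7)),
                         ids(sample_cells(sl, seed = 8))))
  # adding a slide must not perturb earlier slides' draws
  with_c <- sample_cells(c(sl, three_zone_slide("C")), seed = 7)
  a_only <- ids(sample_cells(sl, seed = 7))
  a_with_c <- ids(with_c)[vapply(with_c, `[[`, "", "slide_id") %in% c("A", "B")]
  expect_identical(sort(a_only), sort(a_with_c))
})

test_that("under-populated zones and slides raise named errors", {
  sl <- make_slide("S9", list(Z1 = 1:10, Z2 = 1:10, Z3 = 1:3))
  expect_error(sample_cells(sl, seed = 1), "zone 'Z3'.*slide 'S9'")
  two_zones <- make_slide("S8", list(Z1 = 1:10, Z2 = 1:10))
  expect_error(sample_cells(two_zones, seed = 1), "2 zones")
})

test_that("slide summary is the mean of zone means, not the pooled mean", {
  sl <- make_slide("S1", list(Z1 = c(100, 200), Z2 = 300))
  m <- measure_cells(sl)
  s <- summarize_slides(m)
  z <- summarize_zones(m)
  expect_equal(sort(z$mean_area_um2), c(150, 300))
  expect_equal(s$mean_area_um2, 225)           # (150 + 300) / 2
  expect_equal(s$pooled_mean_area_um2, 200)    # (100+200+300)/3
  expect_equal(s$n_cells, 3)
  # single zone, single cell: identity
  one <- summarize_slides(measure_cells(make_slide("S2", list(Z1 = 42))))
  expect_equal(one$mean_area_um2, 42)
})

test_that("equal-sized zones make the slide mean equal the pooled mean", {
  withr::local_seed(3)
  areas <- lapply(1:3, function(i) runif(7, 80, 350))
  sl <- make_slide("S1", setNames(areas, paste0("Z", 1:3)))
  s <- summarize_slides(measure_cells(sl))
  expect_equal(s$mean_area_um2, mean(unlist(areas)), tolerance = 1e-12)
  expect_equal(s$mean_area_um2, mean(sapply(areas, mean)), tolerance = 1e-12)
})

test_that("cohort summary reports cell-level and slide-level dispersions", {
  sl <- c(make_slide("S1", list(Z1 = c(100, 120), Z2 = c(180, 200))),
          make_slide("S2", list(Z1 = c(220, 260), Z2 = c(300, 320))))
  cs <- cohort_morphometry_summary(measure_cells(sl))
  expect_identical(cs$level, c("cell", "slide"))
  expect_equal(cs$n, c(8, 2))
  expect_gt(cs$sd_area_um2[1], 0)
  expect_false(isTRUE(all.equal(cs$sd_area_um2[1], cs$sd_area_um2[2])))
})
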