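test_that("habitat lattice covers the buffered extent with the expected cell count", {
  hb0 <- build_habitat_grid(c(0, 100, 0, 100), cell_size = 20,
                            buffer_width = 0)
  expect_equal(nrow(hb0$cells), 25)
  hb <- build_habitat_grid(c(0, 100, 0, 100), cell_size = 20,
                           buffer_width = 60)
  expect_equal(nrow(hb$cells), 121)
  expect_equal(hb$extent, c(-60, 160, -60, 160))
  # row-major 0-based ids from the lower-left corner
  expect_equal(hb$cells$cell, seq_len(121) - 1L)
  expect_equal(hb$cells$x[1:3], c(-50, -30, -10))
  expect_equal(hb$cells$y[1], -50)
})

test_that("constant-raster resampling is the identity and coverage is enforced", {
  r <- structure(list(x0 = -70, y0 = -70, cellsize = 10, nrow = 24, ncol = 24,
                      values = matrix(3.5, 24, 24)), class = "asc_raster")
  hb <- build_habitat_grid(c(0, 100, 0, 100), cell_size = 20,
                           buffer_width = 60, covariate = r)
  expect_true(all(hb$cells$X == 3.5))
  small <- structure(list(x0 = 0, y0 = 0, cellsize = 10, nrow = 10, ncol = 10,
                          values = matrix(1, 10, 10)), class = "asc_raster")
  expect_error(build_habitat_grid(c(0, 100, 0, 100), cell_size = 20,
                                  buffer_width = 60, covariate = small),
               "does not cover")
})

test_that("area-weighted resampling averages raster cells by overlap", {
  # 10 km raster under 20 km habitat cells: each habitat cell averages
  # exactly four raster cells
  vals <- matrix(seq_len(16), 4, 4, byrow = TRUE) # row 1 = north
  r <- structure(list(x0 = 0, y0 = 0, cellsize = 10, nrow = 4, ncol = 4,
                      values = vals), class = "asc_raster")
  hb <- build_habitat_grid(c(0, 40, 0, 40), cell_size = 20, buffer_width = 0,
                           covariate = r)
  # lower-left habitat cell covers raster rows 3-4 (from north), cols 1-2
  expect_equal(hb$cells$X[1], mean(c(9, 10, 13, 14)))
  expect_equal(hb$cells$X[4], mean(c(3, 4, 7, 8)))
})

test_that("NODATA regions of the raster drop habitat cells", {
  vals <- matrix(1, 4, 4); vals[3:4, 1:2] <- NA # south-west block absent
  r <- structure(list(x0 = 0, y0 = 0, cellsize = 10, nrow = 4, ncol = 4,
                      values = vals), class = "asc_raster")
  hb <- build_habitat_grid(c(0, 40, 0, 40), cell_size = 20, buffer_width = 0,
                           covariate = r)
  expect_equal(nrow(hb$cells), 3)
  expect_false(any(hb$cells$x == 10 & hb$cells$y == 10))
  expect_true(is.na(habitat_cell_at(hb, 5, 5)))
  expect_false(is.na(habitat_cell_at(hb, 35, 5)))
})

test_that("fully habitat-covered detectors have 25 subdetectors at 10 km / 2 km", {
  hb <- build_habitat_grid(c(0, 40, 0, 40), cell_size = 20, buffer_width = 20)
  det <- build_detector_grid(c(0, 40, 0, 40), detector_size = 10,
                             subdetector_size = 2, habitat = hb)
  expect_equal(nrow(det$detectors), 16)
  expect_true(all(det$detectors$K == 25))
})

test_that("detectors outside the habitat are dropped; partial coverage counts centres", {
  # habitat strip x in [0, 5] only (one column of 5 km cells)
  hb <- build_habitat_grid(c(0, 5, 0, 10), cell_size = 5, buffer_width = 0)
  det <- build_detector_grid(c(0, 20, 0, 10), detector_size = 10,
                             subdetector_size = 2, habitat = hb)
  # detector at x = 15 has no subdetector centre inside -> dropped
  expect_equal(nrow(det$detectors), 1)
  # remaining detector: centres at x in {1, 3} qualify, 2 columns x 5 rows
  expect_equal(det$detectors$K, 10)
  # brute-force point-in-habitat over all 25 centres agrees
  m <- 5; off <- (seq_len(m) - 3) * 2
  cx <- rep(5 + off, times = m); cy <- rep(5 + off, each = m)
  expect_equal(det$detectors$K, sum(!is.na(habitat_cell_at(hb, cx, cy))))
})

test_that("non-divisible detector/subdetector sizes are a configuration error", {
  hb <- make_tiny_habitat()
  expect_error(build_detector_grid(c(0, 60, 0, 60), 10, 3, hb),
               "integer multiple")
})

test_that("K is conserved against brute-force enumeration of subdetector centres", {
  hb <- build_habitat_grid(c(0, 30, 0, 30), cell_size = 20, buffer_width = 0)
  det <- build_detector_grid(c(0, 30, 0, 30), detector_size = 10,
                             subdetector_size = 2, habitat = hb)
  # habitat lattice (ceiling cover) spans [0,40]^2, so every centre inside
  total <- 0
  for (jx in c(5, 15, 25)) for (jy in c(5, 15, 25)) {
    off <- (seq_len(5) - 3) * 2
    cx <- rep(jx + off, times = 5); cy <- rep(jy + off, each = 5)
    total <- total + sum(!is.na(habitat_cell_at(hb, cx, cy)))
  }
  expect_equal(sum(det$detectors$K), total)
})

test_that("detection records aggregate to distinct-subdetector counts", {
  hb <- make_tiny_habitat()
  det <- build_detector_grid(c(0, 60, 0, 60), 20, 10, hb)
  # three samples in one subdetector, same season -> y = 1
  r1 <- data.frame(individual_id = "a", season = 1L,
                   x = c(12, 13, 14), y = c(12, 12, 13))
  y1 <- assign_detections(r1, det)
  expect_equal(y1$y, 1L)
  # three samples in three different subdetectors of one detector -> y = 3
  r3 <- data.frame(individual_id = "a", season = 1L,
                   x = c(4, 16, 4), y = c(4, 4, 16))
  y3 <- assign_detections(r3, det)
  expect_equal(nrow(y3), 1)
  expect_equal(y3$y, 3L)
  # far-outside record is excluded and counted
  rout <- rbind(r1, data.frame(individual_id = "a", season = 1L,
                               x = 500, y = 500))
  expect_message(yout <- assign_detections(rout, det), "excluded")
  expect_equal(attr(yout, "excluded"), 1L)
  expect_equal(yout$y, 1L)
})

test_that("nearest-detector ties resolve to the lowest index", {
  hb <- make_tiny_habitat()
  det <- build_detector_grid(c(0, 60, 0, 60), 20, 10, hb)
  # point equidistant between detectors 0 (10,10) and 1 (30,10)
  r <- data.frame(individual_id = "a", season = 1L, x = 20, y = 10)
  yt <- assign_detections(r, det)
  d2 <- (det$detectors$x - 20)^2 + (det$detectors$y - 10)^2
  expect_equal(sum(d2 == min(d2)), 2) # genuinely tied
  expect_equal(yt$detector, det$detectors$detector[which.min(d2)])
})

test_that("retention filter keeps exactly the records within the radius", {
  ref <- cbind(x = c(0, 100), y = c(0, 0))
  rec <- data.frame(individual_id = "a", season = 1L,
                    x = c(69.9 + 100, 70.1 + 100), y = c(0, 0))
  kept <- retain_within_radius(rec, ref, 70)
  expect_equal(kept$x, 169.9)
  expect_error(retain_within_radius(rec, ref[0, , drop = FALSE], 70),
               "empty reference")
  # mixed constructed set vs brute-force all-pairs distances
  set.seed(42)
  rec2 <- data.frame(individual_id = "b", season = 1L,
                     x = runif(10, -200, 300), y = runif(10, -200, 200))
  kept2 <- retain_within_radius(rec2, ref, 70)
  brute <- sapply(seq_len(10), function(r)
    min(sqrt((ref[, 1] - rec2$x[r])^2 + (ref[, 2] - rec2$y[r])^2)) <= 70)
  expect_equal(rownames(kept2), rownames(rec2)[brute])
})

test_that("buffer narrower than six sigma_max warns", {
  expect_warning(build_habitat_grid(c(0, 40, 0, 40), 20, buffer_width = 20,
                                    sigma_max = 5),
                 "6 \\* sigma_max")
  expect_silent(build_habitat_grid(c(0, 40, 0, 40), 20, buffer_width = 30,
                                   sigma_max = 5))
})

test_that("ASCII grids round-trip through write_asc/read_asc", {
  m <- matrix(c(1.5, NA, -2.25, 4, 0, 7), nrow = 2)
  p <- tempfile(fileext = ".asc")
  write_asc(m, p, x0 = -10, y0 = 5, cellsize = 2.5)
  r <- read_asc(p)
  expect_equal(r$values, m)
  expect_equal(r$x0, -10)
  expect_equal(r$cellsize, 2.5)
  unlink(p)
})
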