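test_that("grids tile the image with near-equal cells, larger cells last", {
  g <- make_grid(240, 320, 10, 10)
  expect_equal(length(g$cells), 100L)
  heights <- vapply(g$cells, function(c) c$row_end - c$row_start, integer(1))
  widths <- vapply(g$cells, function(c) c$col_end - c$col_start, integer(1))
  expect_true(all(heights == 24L))
  expect_true(all(widths == 32L))

  # non-divisible case: 240 = 34*5 + 35*2, 320 = 45*2 + 46*5
  g7 <- make_grid(240, 320, 7, 7)
  rh <- vapply(g7$cells[seq(1, 49, by = 7)],
               function(c) c$row_end - c$row_start, integer(1))
  cw <- vapply(g7$cells[1:7], function(c) c$col_end - c$col_start, integer(1))
  expect_equal(rh, c(34L, 34L, 34L, 34L, 34L, 35L, 35L))
  expect_equal(cw, c(45L, 45L, 46L, 46L, 46L, 46L, 46L))
  expect_equal(sum(rh), 240L)
  expect_equal(sum(cw), 320L)

  expect_error(make_grid(2, 2, 3, 3), "degenerate")
})

test_that("grid cells are disjoint and cover every pixel exactly once", {
  for (mn in list(c(3, 3), c(5, 5), c(7, 7), c(10, 10))) {
    g <- make_grid(97, 131, mn[1], mn[2])
    cover <- matrix(0L, 97, 131)
    for (cell in g$cells) {
      rows <- (cell$row_start + 1):cell$row_end
      cols <- (cell$col_start + 1):cell$col_end
      cover[rows, cols] <- cover[rows, cols] + 1L
    }
    expect_true(all(cover == 1L))
  }
})

test_that("per-cell means filter masked pixels and flag empty cells", {
  refs <- reference_readings(20, 30)

  img <- radiometric_image(matrix(25, 6, 6))
  g <- make_grid(6, 6, 2, 3)
  stats <- cell_temperatures(img, build_mask(img, refs), g, refs)
  expect_true(all(stats$t_canopy == 25))
  expect_true(all(stats$valid_pixels == 6L))

  # one above-dry pixel inside a cell must not contaminate the mean
  img2 <- tiny_image(c(25, 40, 25, 25, 25, 25, 25, 25, 25), 3)
  g1 <- make_grid(3, 3, 1, 1)
  stats2 <- cell_temperatures(img2, build_mask(img2, refs), g1, refs)
  expect_equal(stats2$t_canopy, 25)
  expect_equal(stats2$valid_pixels, 8L)

  # all-sky cell is missing, not an error
  img3 <- radiometric_image(matrix(c(rep(5, 18), rep(25, 18)), 6, 6))
  stats3 <- cell_temperatures(img3, build_mask(img3, refs),
                              make_grid(6, 6, 1, 2), refs)
  expect_equal(stats3$valid_pixels, c(0L, 18L))
  expect_true(is.na(stats3$t_canopy[1]))
  expect_true(is.na(stats3$ig[1]))
  expect_equal(stats3$t_canopy[2], 25)
})

test_that("grid pipeline matches the naive double-loop oracle", {
  set.seed(7)
  for (i in 1:10) {
    h <- sample(6:20, 1)
    w <- sample(6:20, 1)
    img <- radiometric_image(matrix(runif(h * w, 10, 40), h, w))
    refs <- reference_readings(15, 35)
    mask <- build_mask(img, refs)
    m <- sample(2:4, 1)
    n <- sample(2:4, 1)
    g <- make_grid(h, w, m, n)
    fast <- cell_temperatures(img, mask, g)$t_canopy
    slow <- brute_cell_means(img, mask, g)
    expect_equal(fast, slow, tolerance = 1e-9)
    # pixel conservation
    expect_equal(sum(cell_temperatures(img, mask, g)$valid_pixels),
                 sum(mask))
  }
})

test_that("whole-image statistics equal the 1x1 grid and obey the indices", {
  refs <- reference_readings(20, 30)
  img <- radiometric_image(matrix(25, 8, 8))
  mask <- build_mask(img, refs)
  w <- whole_image_statistics(img, mask, refs)
  expect_equal(w$t_canopy, 25)
  expect_equal(w$ig, 1)
  expect_equal(w$cwsi, 0.5)
  g1 <- cell_temperatures(img, mask, make_grid(8, 8, 1, 1), refs)
  expect_equal(w, g1)

  empty <- whole_image_statistics(img, mask & FALSE, refs)
  expect_true(is.na(empty$t_canopy))
})

test_that("refining the grid preserves the area-weighted mean temperature", {
  set.seed(11)
  img <- radiometric_image(matrix(runif(240 * 320, 21, 29), 240, 320))
  refs <- reference_readings(20, 30)
  mask <- build_mask(img, refs)
  means <- vapply(c(3, 5, 10), function(k) {
    s <- cell_temperatures(img, mask, make_grid(240, 320, k, k))
    sum(s$t_canopy * s$valid_pixels) / sum(s$valid_pixels)
  }, numeric(1))
  expect_equal(means[1], means[2], tolerance = 1e-12)
  expect_equal(means[1], means[3], tolerance = 1e-12)
})

test_that("feature vectors have fixed length with imputed empty cells", {
  refs <- reference_readings(20, 30)
  # top half sky: several empty cells at 3x3
  vals <- matrix(25, 60, 60)
  vals[1:30, ] <- 5
  img <- radiometric_image(vals)
  f <- thermal_features(img, refs, 3, 3)
  expect_length(f, 27L)
  expect_true(all(is.finite(f)))
  expect_true(length(attr(f, "imputed")) >= 3L)
  # imputed cells carry the image-wide mean temperature (25)
  expect_equal(unname(f[attr(f, "imputed")]), rep(25, length(attr(f, "imputed"))))
  expect_equal(cell_area_cm2(10, 10), 154)
})
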