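test_that("CSV rasters read and round-trip at the 0.01-degree dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("20,21", "22,23"), path)
  img <- read_raster(path)
  expect_equal(dim(img), c(2L, 2L))
  expect_equal(as.numeric(t(unclass(img))), c(20, 21, 22, 23))

  img2 <- radiometric_image(matrix(runif(30, 15, 35), 5, 6))
  out <- withr::local_tempfile(fileext = ".csv")
  write_raster(img2, out)
  back <- read_raster(out)
  expect_lt(max(abs(back - img2)), 0.01 + 1e-12)
})

test_that("malformed rasters are rejected with clear errors", {
  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("20,21", "22,23,24"), ragged)
  expect_error(read_raster(ragged), "ragged")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("20,x", "22,23"), bad)
  expect_error(read_raster(bad), "non-numeric")

  hot <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("20,1500", "22,23"), hot)
  expect_error(read_raster(hot), "camera range")

  expect_error(radiometric_image(matrix(c(1, NA), 1)), "non-finite")
  expect_error(read_raster("no/such/file.csv"), "no such file")
})

test_that("float TIFF rasters round-trip within camera quantisation", {
  skip_if_not_installed("tiff")
  img <- radiometric_image(matrix(runif(48, -5, 45), 6, 8))
  path <- withr::local_tempfile(fileext = ".tif")
  write_raster(img, path)
  back <- read_raster(path)
  expect_lt(max(abs(back - img)), 1e-3)
})

test_that("reference extraction averages painted-leaf ROIs", {
  img <- radiometric_image(matrix(25, 10, 10))
  img[1:2, 1:2] <- 20
  img[1:2, 9:10] <- 30
  refs <- extract_reference(img, roi(0, 2, 0, 2), roi(0, 2, 8, 10))
  expect_equal(refs$t_wet, 20)
  expect_equal(refs$t_dry, 30)

  # arithmetic mean of non-constant ROIs, invariant to pixel arrangement
  img[1:2, 1:2] <- c(19, 21, 21, 19)
  img[1:2, 9:10] <- c(31, 29, 29, 31)
  refs <- extract_reference(img, roi(0, 2, 0, 2), roi(0, 2, 8, 10))
  expect_equal(refs$t_wet, 20)
  expect_equal(refs$t_dry, 30)

  # median option
  img[1:2, 1:2] <- c(19, 19, 19, 35)  # one stray hot pixel
  refs_med <- extract_reference(img, roi(0, 2, 0, 2), roi(0, 2, 8, 10),
                                stat = "median")
  expect_equal(refs_med$t_wet, 19)
})

test_that("swapped reference ROIs raise a reference-inversion error", {
  img <- radiometric_image(matrix(25, 10, 10))
  img[1:2, 1:2] <- 30
  img[1:2, 9:10] <- 20
  expect_error(extract_reference(img, roi(0, 2, 0, 2), roi(0, 2, 8, 10)),
               "reference inversion")
  expect_error(reference_readings(25, 25), "reference inversion")
})

test_that("mask keeps exactly the closed interval [t_wet, t_dry]", {
  img <- tiny_image(c(15, 20, 25, 30, 35, 25, 10, 28, 40), 3)
  refs <- reference_readings(20, 30)
  mask <- build_mask(img, refs)
  expect_equal(sum(mask), 5L)
  expect_equal(sort(img[mask]), c(20, 25, 25, 28, 30))

  all_wet <- radiometric_image(matrix(20, 3, 3))
  expect_true(all(build_mask(all_wet, refs)))
  all_hot <- radiometric_image(matrix(31, 3, 3))
  expect_false(any(build_mask(all_hot, refs)))
})

test_that("widening the reference interval never drops a kept pixel", {
  set.seed(42)
  for (i in 1:20) {
    img <- radiometric_image(matrix(runif(100, 0, 50), 10, 10))
    lo <- runif(1, 10, 20)
    hi <- runif(1, 30, 40)
    narrow <- build_mask(img, reference_readings(lo, hi))
    wide <- build_mask(img, reference_readings(lo - runif(1, 0, 5),
                                               hi + runif(1, 0, 5)))
    expect_true(all(wide[narrow]))
  }
})

test_that("ROI sidecars round-trip and validate", {
  rois <- list(wet = roi(4, 14, 4, 14), dry = roi(4, 14, 306, 316))
  path <- withr::local_tempfile(fileext = ".json")
  write_roi_sidecar(rois, path)
  back <- read_roi_sidecar(path)
  expect_equal(back, rois)
  expect_error(roi(5, 5, 0, 2), "empty")
  expect_error(roi(-1, 5, 0, 2), "non-negative")
})
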