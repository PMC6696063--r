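test_that("absorbance transform is log10(1/R) and invertible", {
  s <- spectrum(700:710, rep(c(1, 0.1, 0.5), length.out = 11))
  a <- to_absorbance(s)
  expect_equal(a$mode, "absorbance")
  expect_equal(a$values[1], 0)
  expect_equal(a$values[2], 1)
  expect_equal(a$values[3], log10(2))
  expect_equal(10^(-a$values), s$values, tolerance = 1e-12)

  expect_error(spectrum(700:704, c(0.5, 0.4, 0, 0.2, 0.1)), "\\(0, 1\\]")
  expect_error(to_absorbance(a), "reflectance")
})

test_that("windowing is inclusive, idempotent, and errors when empty", {
  s <- spectrum(350:1850, rep(0.5, 1501))
  w <- spectral_window(s, 700, 1100)
  expect_length(w$wavelengths, 401L)
  expect_equal(range(w$wavelengths), c(700, 1100))
  expect_equal(spectral_window(w, 700, 1100), w)
  expect_equal(spectral_window(s, 350, 1850), s)
  expect_error(spectral_window(s, 2000, 2100), "empty window")
})

test_that("Savitzky-Golay second derivative recovers analytic curvature", {
  lam <- 700:1100
  lin <- spectrum(lam, 0.1 + 1e-4 * (lam - 700), mode = "absorbance")
  d2_lin <- second_derivative(lin)
  expect_lt(max(abs(d2_lin$values)), 1e-10)

  a <- 0.001
  quad <- spectrum(lam, a * ((lam - 900) / 10)^2, mode = "absorbance")
  d2_quad <- second_derivative(quad)
  interior <- 20:380
  expect_equal(d2_quad$values[interior],
               rep(2 * a / 100, length(interior)), tolerance = 1e-10)

  # superposition: linear + quadratic has the quadratic's curvature
  both <- spectrum(lam, lin$values + quad$values, mode = "absorbance")
  expect_equal(second_derivative(both)$values, d2_quad$values,
               tolerance = 1e-10)

  # scalar homogeneity
  scaled <- spectrum(lam, 3 * quad$values, mode = "absorbance")
  expect_equal(second_derivative(scaled)$values, 3 * d2_quad$values,
               tolerance = 1e-12)

  # agrees with plain central differences away from the bands' edges
  fd <- second_derivative(quad, method = "diff")
  expect_equal(d2_quad$values[interior], fd$values[interior],
               tolerance = 1e-8)

  short <- spectrum(700:709, rep(0.2, 10), mode = "absorbance")
  expect_error(second_derivative(short), "shorter")
})

test_that("feature assembly aligns spectra and targets by sample", {
  samples <- small_spectra()
  feat <- assemble_features(samples)
  expect_equal(dim(feat$x), c(8L, 401L))
  expect_equal(dim(feat$y), c(8L, 3L))
  expect_equal(colnames(feat$y), c("gg_berry", "gg_wine", "guaiacol_wine"))
  expect_equal(feat$meta$sample_id, rownames(feat$x))
  expect_equal(colnames(feat$x)[1], "nm700")

  single <- assemble_features(samples[1])
  expect_equal(nrow(single$x), 1L)

  # grid mismatch is an alignment error
  off <- samples
  off[[2]]$spectrum <- spectrum(351:1851, off[[2]]$spectrum$values)
  expect_error(assemble_features(off), "different wavelength grid")
})

test_that("long-CSV spectra round-trip", {
  samples <- small_spectra()[1:3]
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(samples, path)
  back <- read_spectra_csv(path)
  expect_length(back, 3L)
  s1 <- back[[samples[[1]]$sample_id]]
  expect_equal(s1$values, samples[[1]]$spectrum$values, tolerance = 1e-12)
  expect_equal(s1$mode, "reflectance")
})

test_that("berry samples rebuild from spectra + targets CSVs", {
  samples <- small_spectra()[1:4]
  dir <- withr::local_tempdir()
  write_spectra_csv(samples, file.path(dir, "spectra.csv"))
  write_targets_csv(samples, file.path(dir, "targets.csv"))
  back <- read_berry_samples(file.path(dir, "spectra.csv"),
                             file.path(dir, "targets.csv"))
  expect_length(back, 4L)
  expect_equal(back[[1]]$targets, samples[[1]]$targets, tolerance = 1e-12)
  expect_equal(back[[1]]$cultivar, samples[[1]]$cultivar)
  feat <- assemble_features(back)
  expect_equal(dim(feat$x), c(4L, 401L))

  # malformed targets: the schema error names the missing column
  bad <- read.csv(file.path(dir, "targets.csv"))
  bad$treatment <- NULL
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_berry_samples(file.path(dir, "spectra.csv"),
                                  file.path(dir, "bad.csv")), "treatment")
})
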