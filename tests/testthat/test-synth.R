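test_that("scene generation is deterministic and validates downstream", {
  cfg <- small_scene_config(seed = 42)
  sc1 <- make_scene(cfg)
  sc2 <- make_scene(cfg)
  expect_identical(unclass(sc1$image), unclass(sc2$image))

  refs <- extract_reference(sc1$image, sc1$wet_roi, sc1$dry_roi)
  expect_equal(refs$t_wet, cfg$t_wet)
  expect_equal(refs$t_dry, cfg$t_dry)
  mask <- build_mask(sc1$image, refs)
  expect_gt(sum(mask), 0)

  # full camera resolution, raster convention: 240 rows x 320 cols
  full <- make_scene(scene_config(seed = 1))
  expect_equal(dim(full$image), c(240L, 320L))
})

test_that("zero coupling drives all leaf pixels to the dry reference", {
  cfg <- small_scene_config(coupling = 0, noise_sd = 0, seed = 3)
  sc <- make_scene(cfg)
  refs <- extract_reference(sc$image, sc$wet_roi, sc$dry_roi)
  mask <- build_mask(sc$image, refs)
  w <- whole_image_statistics(sc$image, mask, refs)
  expect_lt(w$ig, 0.05)
  expect_gt(w$cwsi, 0.95)
})

test_that("the linear coupling is analytically invertible from whole-image Ig", {
  # gs = 385 with coupling c chosen so c*gs/(span - c*gs) = 1.06
  span <- 12
  target_ig <- 1.06
  gs <- 385
  coupling <- span * target_ig / (1 + target_ig) / gs
  cfg <- scene_config(
    gs_profile = list(top = c(mean = gs, sd = 5),
                      mid = c(mean = gs, sd = 5),
                      bottom = c(mean = gs, sd = 5)),
    coupling = coupling, noise_sd = 0.02, seed = 17)
  sc <- make_scene(cfg)
  refs <- extract_reference(sc$image, sc$wet_roi, sc$dry_roi)
  w <- whole_image_statistics(sc$image, build_mask(sc$image, refs), refs)
  expect_lt(abs(w$ig - target_ig), 0.1)
})

test_that("datasets are balanced, distinct, and yield the full feature table", {
  ds <- small_dataset(n_each = 4L, seed = 13)
  expect_length(ds$scenes, 8L)
  expect_equal(as.vector(table(ds$labels)), c(4L, 4L))
  # disjoint per-scene seeds: no identical pair
  imgs <- lapply(ds$scenes, function(s) unclass(s$image))
  for (i in 1:7) expect_false(identical(imgs[[i]], imgs[[i + 1]]))

  feat <- dataset_features(ds, 10, 10)
  expect_equal(dim(feat$x), c(8L, 300L))
  expect_true(all(is.finite(feat$x)))
})

test_that("synthetic berry sets honour the printed concentration ranges", {
  samples <- make_spectra(spectra_config(seed = 2))
  expect_length(samples, 112L)
  expect_equal(sum(vapply(samples, function(s) s$treatment == "smoked",
                          logical(1))), 56L)
  rng <- list(gg_berry = list(control = c(37, 602), smoked = c(253, 2452)),
              gg_wine = list(control = c(8, 334), smoked = c(111, 1480)),
              guaiacol_wine = list(control = c(0, 9), smoked = c(0, 26)))
  for (s in samples) {
    for (tgt in names(rng)) {
      lim <- rng[[tgt]][[s$treatment]]
      expect_gte(s$targets[[tgt]], lim[1])
      expect_lte(s$targets[[tgt]], lim[2])
    }
    expect_true(all(s$spectrum$values > 0 & s$spectrum$values <= 1))
  }
})

test_that("white cultivars sit ~0.05 absorbance above red cultivars", {
  samples <- make_spectra(spectra_config(seed = 4))
  mean_abs <- function(s) {
    a <- spectral_window(to_absorbance(s$spectrum), 820, 1100)
    mean(a$values)
  }
  whites <- vapply(Filter(function(s) s$cultivar == "Chardonnay", samples),
                   mean_abs, numeric(1))
  reds <- vapply(Filter(function(s) s$cultivar == "Merlot", samples),
                 mean_abs, numeric(1))
  expect_lt(abs(mean(whites) - mean(reds) - 0.05), 0.02)
})

test_that("severing the concentration link removes the spectral signal", {
  samples <- make_spectra(spectra_config(n_per_cultivar = 8L,
                                         link_strength = 0, noise_sd = 0,
                                         seed = 6))
  feat <- assemble_features(samples)
  band <- feat$x[, "nm982"]
  # identical spectra up to the cultivar offset: no concentration signal
  expect_lt(stats::sd(band[feat$meta$cultivar == "Merlot"]), 1e-12)

  strong <- make_spectra(spectra_config(n_per_cultivar = 8L, noise_sd = 0,
                                        seed = 6))
  feat2 <- assemble_features(strong)
  r <- abs(stats::cor(feat2$x[, "nm982"], feat2$y[, "gg_berry"]))
  expect_gt(r, 0.9)
})
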