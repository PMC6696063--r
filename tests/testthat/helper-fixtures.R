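# shared fixtures: tiny images, brute-force oracles, small scene configs

tiny_image <- function(values, nrow) {
  radiometric_image(matrix(values, nrow = nrow, byrow = TRUE))
}

# brute-force per-cell mean of kept pixels: naive double loop, independent
# of the grid pipeline's vectorised path
brute_cell_means <- function(img, mask, grid) {
  out <- numeric(length(grid$cells))
  for (k in seq_along(grid$cells)) {
    cell <- grid$cells[[k]]
    acc <- c()
    for (r in (cell$row_start + 1):cell$row_end) {
      for (cc in (cell$col_start + 1):cell$col_end) {
        if (mask[r, cc]) acc <- c(acc, img[r, cc])
      }
    }
    out[k] <- if (length(acc)) mean(acc) else NA_real_
  }
  out
}

# small fast scene for pipeline tests (quarter-resolution camera)
small_scene_config <- function(...) {
  scene_config(height = 120L, width = 160L, ...)
}

small_dataset <- function(n_each = 6L, seed = 99L) {
  make_dataset(n_each, n_each, base_cfg = small_scene_config(), seed = seed)
}

# compact spectra set: 2 cultivars x 4 berries = 8 samples
small_spectra <- function(seed = 3L, ...) {
  make_spectra(spectra_config(n_per_cultivar = 4L,
                              cultivars = c("Merlot", "Chardonnay"),
                              seed = seed, ...))
}
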