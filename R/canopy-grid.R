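#' Subdivide an image into an m-by-n grid
#'
#' Partitions the pixel raster into `m` row-bands times `n` column-bands of
#' near-equal size, the matrix A(m, n) whose entries are per-cell canopy
#' temperatures. Supported analysis presets are 3x3, 5x5, 7x7 and 10x10,
#' but any `m <= height`, `n <= width` is accepted. When a dimension does
#' not divide evenly, cell sizes differ by at most one pixel and the larger
#' cells are placed last (e.g. 240 rows over 7 bands gives heights
#' 34,34,34,34,34,35,35).
#'
#' @param height,width image dimensions in pixels.
#' @param m,n subdivision counts (rows, columns).
#' @return An object of class `grid_partition`: list with `m`, `n` and
#'   `cells`, a row-major list of `m * n` [roi()]s that tile the image
#'   exactly.
#' @export
#' @examples
#' g <- make_grid(240, 320, 10, 10)
#' length(g$cells)  # 100
make_grid <- function(height, width, m, n) {
  stopifnot(height >= 1, width >= 1, m >= 1, n >= 1)
  if (m > height || n > width) {
    stop(sprintf("degenerate grid: %d x %d cells cannot tile %d x %d px",
                 m, n, height, width), call. = FALSE)
  }
  # near-equal integer partition, remainder pixels on the last cells
  part <- function(total, k) {
    base <- total %/% k
    rem <- total %% k
    sizes <- rep(base, k)
    if (rem > 0) sizes[(k - rem + 1L):k] <- base + 1L
    sizes
  }
  rh <- part(height, m)
  cw <- part(width, n)
  r0 <- cumsum(c(0L, rh))
  c0 <- cumsum(c(0L, cw))
  cells <- vector("list", m * n)
  k <- 1L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      cells[[k]] <- roi(r0[i], r0[i + 1L], c0[j], c0[j + 1L])
      k <- k + 1L
    }
  }
  structure(list(m = as.integer(m), n = as.integer(n), cells = cells),
            class = "grid_partition")
}

#' Per-cell canopy statistics
#'
#' For every grid cell, averages the masked (canopy) pixel temperatures to
#' the cell's canopy temperature T_canopy and, when reference readings are
#' supplied, computes the infrared index Ig and the crop water stress index
#' CWSI from that mean. Cells containing no canopy pixels (all sky or
#' overheated material) are reported as missing rather than raising an
#' error: an empty cell is data.
#'
#' By default indices are computed from the per-cell mean temperature
#' (matching the averaged-T_canopy-per-subdivision convention);
#' `per_pixel = TRUE` instead averages per-pixel index values over the
#' cell, as a cross-check mode.
#'
#' @param image a [radiometric_image()].
#' @param mask logical canopy mask from [build_mask()].
#' @param grid a [make_grid()] partition.
#' @param refs optional [reference_readings()]; needed for `ig`/`cwsi`.
#' @param per_pixel compute indices per pixel then average (default FALSE).
#' @return A data frame with one row per cell: `row`, `col` (1-based cell
#'   indices), `valid_pixels`, `t_canopy`, and, with `refs`, `ig` and
#'   `cwsi` (`NA` for empty cells).
#' @export
cell_temperatures <- function(image, mask, grid, refs = NULL,
                              per_pixel = FALSE) {
  stopifnot(inherits(image, "radiometric_image"),
            is.logical(mask), all(dim(mask) == dim(image)),
            inherits(grid, "grid_partition"))
  ncell <- grid$m * grid$n
  out <- data.frame(
    row = rep(seq_len(grid$m), each = grid$n),
    col = rep(seq_len(grid$n), times = grid$m),
    valid_pixels = integer(ncell),
    t_canopy = rep(NA_real_, ncell)
  )
  if (!is.null(refs)) {
    out$ig <- NA_real_
    out$cwsi <- NA_real_
  }
  for (k in seq_len(ncell)) {
    cell <- grid$cells[[k]]
    sub <- image[roi_rows(cell), roi_cols(cell), drop = FALSE]
    keep <- mask[roi_rows(cell), roi_cols(cell), drop = FALSE]
    vals <- sub[keep]
    out$valid_pixels[k] <- length(vals)
    if (length(vals) == 0L) next
    tc <- mean(vals)
    out$t_canopy[k] <- tc
    if (!is.null(refs)) {
      if (per_pixel) {
        out$ig[k] <- mean(suppressWarnings(ig(vals, refs)))
        out$cwsi[k] <- mean(cwsi(vals, refs))
      } else {
        out$ig[k] <- suppressWarnings(ig(tc, refs))
        out$cwsi[k] <- as.numeric(cwsi(tc, refs))
      }
    }
  }
  out
}

#' Whole-image canopy statistics
#'
#' The single-cell (1x1 grid) case of [cell_temperatures()]: the canopy
#' temperature, Ig and CWSI of a whole image without subdivision.
#'
#' @inheritParams cell_temperatures
#' @return One-row data frame as from [cell_temperatures()].
#' @export
whole_image_statistics <- function(image, mask, refs = NULL,
                                   per_pixel = FALSE) {
  grid <- make_grid(nrow(image), ncol(image), 1L, 1L)
  cell_temperatures(image, mask, grid, refs, per_pixel)
}

#' Thermal feature vector of one image
#'
#' Flattens the per-cell statistics of an m-by-n subdivision into the
#' fixed-length feature vector used as classifier input: `3 * m * n` values,
#' ordered as all T_canopy cells (row-major), then all Ig, then all CWSI.
#' Empty cells are imputed with the image-wide mean canopy temperature (and
#' the indices recomputed from it) so the input dimension never varies; the
#' indices of imputed cells are recorded in the `"imputed"` attribute.
#'
#' @inheritParams cell_temperatures
#' @param m,n subdivision counts.
#' @return Named numeric vector of length `3 * m * n` with attribute
#'   `imputed` (integer cell indices that were empty).
#' @export
thermal_features <- function(image, refs, m, n, mask = NULL) {
  if (is.null(mask)) mask <- build_mask(image, refs)
  grid <- make_grid(nrow(image), ncol(image), m, n)
  stats <- cell_temperatures(image, mask, grid, refs)
  empty <- which(stats$valid_pixels == 0L)
  if (length(empty)) {
    fill <- mean(stats$t_canopy, na.rm = TRUE)
    if (!is.finite(fill)) fill <- (refs$t_wet + refs$t_dry) / 2
    stats$t_canopy[empty] <- fill
    stats$ig[empty] <- suppressWarnings(ig(fill, refs))
    stats$cwsi[empty] <- as.numeric(cwsi(fill, refs))
  }
  # Ig diverges as a cell mean touches t_wet (e.g. a cell holding only the
  # wet reference patch); nudge such means just inside the interval so the
  # feature vector stays finite.
  bad <- which(!is.finite(stats$ig))
  if (length(bad)) {
    tc <- pmax(stats$t_canopy[bad], refs$t_wet + 0.01)
    stats$t_canopy[bad] <- tc
    stats$ig[bad] <- suppressWarnings(ig(tc, refs))
    stats$cwsi[bad] <- as.numeric(cwsi(tc, refs))
  }
  lab <- sprintf("r%dc%d", stats$row, stats$col)
  out <- c(setNames(stats$t_canopy, paste0("t_", lab)),
           setNames(as.numeric(stats$ig), paste0("ig_", lab)),
           setNames(as.numeric(stats$cwsi), paste0("cwsi_", lab)))
  attr(out, "imputed") <- empty
  out
}

#' Ground area of one grid cell
#'
#' At the standard acquisition geometry (2.5 m range) a thermal image
#' covers about 140 x 110 cm of canopy, so an m-by-n subdivision yields
#' cells of `140 * 110 / (m * n)` cm2 - e.g. 154 cm2 for the 10x10 grid,
#' about twice a single leaf (50-80 cm2).
#'
#' @param m,n subdivision counts.
#' @param fov_cm field-of-view width and height in cm.
#' @return Cell area in cm2.
#' @export
#' @examples
#' cell_area_cm2(10, 10)  # 154
cell_area_cm2 <- function(m, n, fov_cm = FOV_CM) {
  stopifnot(m >= 1, n >= 1)
  unname(fov_cm["width"] * fov_cm["height"] / (m * n))
}

#' Export per-cell statistics as tidy CSV
#'
#' @param stats data frame from [cell_temperatures()].
#' @param image_id identifier recorded in the first column.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_statistics <- function(stats, image_id, path) {
  out <- cbind(image_id = image_id, stats)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
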