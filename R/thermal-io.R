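# Camera measurement range of the FLIR T-series (B360) sensor, degrees C.
# Values outside it cannot be genuine radiometric readings.
CAMERA_RANGE <- c(-20, 1200)

#' Radiometric thermal image
#'
#' A radiometric image is a numeric matrix whose entries are calibrated
#' temperatures in degrees Celsius: every pixel is an effective temperature
#' reading, not a colour. The constructor validates that all values are
#' finite and within the camera measurement range (-20 to +1200 degrees C).
#'
#' The coordinate convention is raster-standard: the matrix is indexed
#' `[row, col]` with row 1 at the top of the scene.
#'
#' @param values numeric matrix of temperatures in degrees C.
#' @return An object of class `radiometric_image` (a validated matrix).
#' @seealso [read_raster()], [build_mask()], [extract_reference()]
#' @export
#' @examples
#' img <- radiometric_image(matrix(c(20, 21, 22, 23), 2, 2))
#' dim(img)
radiometric_image <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix of temperatures (degrees C)",
         call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("image contains non-finite temperatures", call. = FALSE)
  }
  if (any(values < CAMERA_RANGE[1]) || any(values > CAMERA_RANGE[2])) {
    stop(sprintf(
      "temperatures outside the camera range [%g, %g] degrees C",
      CAMERA_RANGE[1], CAMERA_RANGE[2]), call. = FALSE)
  }
  structure(values, class = c("radiometric_image", class(values)))
}

#' Rectangular region of interest
#'
#' Pixel-index rectangle in 0-based half-open convention: row indices
#' `row_start <= r < row_end`, likewise columns. This houses the painted
#' reference-leaf regions cropped from each image, and the grid cells of a
#' canopy subdivision.
#'
#' @param row_start,row_end,col_start,col_end integer pixel bounds
#'   (0-based, half-open).
#' @return An object of class `roi`.
#' @export
roi <- function(row_start, row_end, col_start, col_end) {
  b <- c(row_start, row_end, col_start, col_end)
  if (any(b != floor(b)) || any(b < 0)) {
    stop("ROI bounds must be non-negative integers", call. = FALSE)
  }
  if (row_end <= row_start || col_end <= col_start) {
    stop("ROI is empty: end indices must exceed start indices", call. = FALSE)
  }
  structure(list(row_start = as.integer(row_start),
                 row_end   = as.integer(row_end),
                 col_start = as.integer(col_start),
                 col_end   = as.integer(col_end)),
            class = "roi")
}

# 1-based index sequences for an ROI.
roi_rows <- function(r) (r$row_start + 1L):r$row_end
roi_cols <- function(r) (r$col_start + 1L):r$col_end

roi_in_bounds <- function(r, image) {
  r$row_end <= nrow(image) && r$col_end <= ncol(image)
}

roi_overlap <- function(a, b) {
  a$row_start < b$row_end && b$row_start < a$row_end &&
    a$col_start < b$col_end && b$col_start < a$col_end
}

#' Reference temperatures from painted leaves
#'
#' `t_wet` is the temperature of a fully transpiring reference leaf (painted
#' with water) and `t_dry` that of a non-transpiring one (painted with
#' petroleum jelly). They anchor both the leaf mask and the two canopy
#' indices, so `t_dry > t_wet` is enforced strictly: equal references make
#' CWSI and Ig undefined.
#'
#' @param t_wet,t_dry reference temperatures in degrees C.
#' @return An object of class `reference_readings`.
#' @export
reference_readings <- function(t_wet, t_dry) {
  stopifnot(is.numeric(t_wet), is.numeric(t_dry),
            length(t_wet) == 1L, length(t_dry) == 1L)
  if (!is.finite(t_wet) || !is.finite(t_dry)) {
    stop("reference temperatures must be finite", call. = FALSE)
  }
  if (t_dry <= t_wet) {
    stop(sprintf(
      "reference inversion: t_dry (%.2f) must exceed t_wet (%.2f); check ROI labels",
      t_dry, t_wet), call. = FALSE)
  }
  structure(list(t_wet = t_wet, t_dry = t_dry), class = "reference_readings")
}

#' @export
print.reference_readings <- function(x, ...) {
  cat(sprintf("Reference readings: t_wet = %.2f C, t_dry = %.2f C\n",
              x$t_wet, x$t_dry))
  invisible(x)
}

#' Extract reference temperatures from painted-leaf regions
#'
#' Crops the radiometric data inside the wet- and dry-reference ROIs and
#' aggregates each to a single temperature. The aggregation statistic is the
#' arithmetic mean by default; the median is available for robustness to
#' stray non-leaf pixels inside an ROI.
#'
#' @param image a [radiometric_image()].
#' @param wet_roi,dry_roi disjoint in-bounds [roi()]s over the water-painted
#'   and petroleum-jelly-painted reference leaves.
#' @param stat aggregation statistic, `"mean"` (default) or `"median"`.
#' @return A [reference_readings()] object. Errors with a
#'   reference-inversion message if the aggregated dry temperature does not
#'   exceed the wet one (a sign of swapped ROI labels).
#' @export
extract_reference <- function(image, wet_roi, dry_roi,
                              stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(image, "radiometric_image"),
            inherits(wet_roi, "roi"), inherits(dry_roi, "roi"))
  if (!roi_in_bounds(wet_roi, image) || !roi_in_bounds(dry_roi, image)) {
    stop("reference ROI extends beyond image bounds", call. = FALSE)
  }
  if (roi_overlap(wet_roi, dry_roi)) {
    stop("wet and dry reference ROIs overlap", call. = FALSE)
  }
  agg <- if (stat == "mean") mean else stats::median
  t_wet <- agg(image[roi_rows(wet_roi), roi_cols(wet_roi)])
  t_dry <- agg(image[roi_rows(dry_roi), roi_cols(dry_roi)])
  reference_readings(t_wet, t_dry)
}

#' Binary leaf mask from reference thresholds
#'
#' Keeps the pixels whose temperature lies within the closed interval
#' `[t_wet, t_dry]` - the minimum and maximum physically possible canopy
#' temperatures - and drops sky, soil and other overheated or overcooled
#' non-leaf material. The interval is closed so the reference leaves
#' themselves survive masking.
#'
#' @param image a [radiometric_image()].
#' @param refs a [reference_readings()] object.
#' @return A logical matrix of the same shape as `image`, `TRUE` where the
#'   pixel is retained as canopy.
#' @export
build_mask <- function(image, refs) {
  stopifnot(inherits(image, "radiometric_image"),
            inherits(refs, "reference_readings"))
  keep <- image >= refs$t_wet & image <= refs$t_dry
  dimnames(keep) <- NULL
  keep
}

#' Read and write radiometric rasters
#'
#' Two interchange formats are supported. The CSV dialect is a headerless
#' comma-separated matrix of temperatures written with two decimals (0.01
#' degrees C resolution). The TIFF format is single-band 32-bit float with
#' sample values normalised over the camera range -20..1200 degrees C
#' (round trip accurate to about 1e-4 degrees C); it requires the
#' suggested \pkg{tiff} package.
#'
#' An optional JSON sidecar `<path>.roi.json` of the form
#' `{"wet": [r0, r1, c0, c1], "dry": [r0, r1, c0, c1]}` (0-based half-open
#' bounds) carries the reference-leaf ROIs; see [read_roi_sidecar()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"tiff"`.
#' @return `read_raster()` returns a [radiometric_image()]; `write_raster()`
#'   invisibly returns `path`.
#' @export
read_raster <- function(path, format = c("auto", "csv", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "csv"
  }
  if (format == "csv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty raster file: ", path, call. = FALSE)
    rows <- strsplit(lines, ",", fixed = TRUE)
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      stop("ragged rows in CSV raster: widths ", paste(unique(widths), collapse = ", "),
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(unlist(rows)))
    if (anyNA(vals)) stop("non-numeric cell in CSV raster: ", path, call. = FALSE)
    m <- matrix(vals, nrow = length(rows), byrow = TRUE)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to read TIFF rasters", call. = FALSE)
    }
    v <- tiff::readTIFF(path)
    if (length(dim(v)) != 2L) stop("expected a single-band TIFF", call. = FALSE)
    m <- v * diff(CAMERA_RANGE) + CAMERA_RANGE[1]
  }
  radiometric_image(m)
}

#' @rdname read_raster
#' @param image a [radiometric_image()] (or plain numeric matrix) to write.
#' @export
write_raster <- function(image, path, format = c("auto", "csv", "tiff")) {
  format <- match.arg(format)
  if (!inherits(image, "radiometric_image")) image <- radiometric_image(image)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "csv"
  }
  if (format == "csv") {
    txt <- apply(unclass(image), 1L, function(r) paste(sprintf("%.2f", r), collapse = ","))
    writeLines(txt, path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to write TIFF rasters", call. = FALSE)
    }
    scaled <- (unclass(image) - CAMERA_RANGE[1]) / diff(CAMERA_RANGE)
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a reference-ROI JSON sidecar
#'
#' @param path path to a JSON file `{"wet": [r0,r1,c0,c1], "dry": [...]}`
#'   with 0-based half-open pixel bounds.
#' @return A list with elements `wet` and `dry`, both [roi()] objects.
#' @export
read_roi_sidecar <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("wet", "dry")) {
    if (is.null(spec[[k]]) || length(spec[[k]]) != 4L) {
      stop("ROI sidecar must contain 4-element 'wet' and 'dry' entries",
           call. = FALSE)
    }
  }
  list(wet = do.call(roi, as.list(as.numeric(spec$wet))),
       dry = do.call(roi, as.list(as.numeric(spec$dry))))
}

#' @rdname read_roi_sidecar
#' @param rois a list with [roi()] elements `wet` and `dry`.
#' @export
write_roi_sidecar <- function(rois, path) {
  stopifnot(inherits(rois$wet, "roi"), inherits(rois$dry, "roi"))
  flat <- function(r) c(r$row_start, r$row_end, r$col_start, r$col_end)
  jsonlite::write_json(list(wet = flat(rois$wet), dry = flat(rois$dry)),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @export
print.radiometric_image <- function(x, ...) {
  cat(sprintf("Radiometric image: %d x %d px, %.2f to %.2f degrees C\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}
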