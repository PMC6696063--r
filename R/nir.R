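#' Berry NIR spectrum
#'
#' A wavelength-indexed series in one of three modes: raw `reflectance`
#' (referenced against a white tile, values in (0, 1]), `absorbance`
#' (log10(1/reflectance), values >= 0) or `d2` (second-derivative
#' absorbance, unitless curvature).
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   ascending, length >= 5.
#' @param values numeric vector, same length.
#' @param mode one of `"reflectance"`, `"absorbance"`, `"d2"`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, values,
                     mode = c("reflectance", "absorbance", "d2")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(wavelengths), is.numeric(values))
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 5L) {
    stop("spectrum needs at least 5 points", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly ascending", call. = FALSE)
  }
  if (mode == "reflectance" && (any(values <= 0) || any(values > 1))) {
    stop("reflectance values must lie in (0, 1]", call. = FALSE)
  }
  if (mode == "absorbance" && any(values < 0)) {
    stop("absorbance values must be non-negative", call. = FALSE)
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values), mode = mode),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum [%s]: %d points, %.0f-%.0f nm\n",
              x$mode, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  plot.default(x$wavelengths, x$values, type = "l",
               xlab = "wavelength (nm)", ylab = x$mode, ...)
}

#' Reflectance to absorbance
#'
#' Applies the standard chemometric transform
#' `absorbance = log10(1 / reflectance)` elementwise; wavelengths are
#' untouched.
#'
#' @param s a reflectance-mode [spectrum()].
#' @return An absorbance-mode spectrum.
#' @export
#' @examples
#' s <- spectrum(700:710, rep(0.5, 11))
#' to_absorbance(s)$values[1]  # log10(2)
to_absorbance <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  if (s$mode != "reflectance") {
    stop("to_absorbance() expects a reflectance spectrum", call. = FALSE)
  }
  spectrum(s$wavelengths, log10(1 / s$values), mode = "absorbance")
}

#' Wavelength window
#'
#' Retains the samples with `lo <= wavelength <= hi` (inclusive bounds).
#' The analysis window for berry spectra is 700-1100 nm, covering the O-H
#' overtone near 982 nm and the onset of the C-H bands.
#'
#' @param s a [spectrum()].
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return The windowed spectrum (same mode).
#' @export
spectral_window <- function(s, lo = 700, hi = 1100) {
  stopifnot(inherits(s, "spectrum"), lo < hi)
  keep <- s$wavelengths >= lo & s$wavelengths <= hi
  if (!any(keep)) {
    stop(sprintf("empty window: no samples in [%g, %g] nm", lo, hi),
         call. = FALSE)
  }
  out <- s
  out$wavelengths <- s$wavelengths[keep]
  out$values <- s$values[keep]
  out
}

#' Savitzky-Golay second derivative
#'
#' Second-derivative transform of an absorbance spectrum, the chemometric
#' preprocessing that suppresses additive baseline and linear slope and
#' sharpens band structure. Uses a Savitzky-Golay filter (local polynomial
#' least squares) with the stated window and polynomial order; the output
#' has the same length as the input, with the border points handled by the
#' filter's transient-correcting polynomial fits. A plain central
#' finite-difference mode is available as a cross-check.
#'
#' @param s an absorbance-mode [spectrum()] on a uniform wavelength grid.
#' @param sg_window odd filter length in points (default 15).
#' @param sg_poly polynomial order, `2 <= sg_poly < sg_window` (default 3).
#' @param method `"sgolay"` (default) or `"diff"` (central differences).
#' @return A `d2`-mode spectrum, units of absorbance per nm squared.
#' @export
second_derivative <- function(s, sg_window = 15L, sg_poly = 3L,
                              method = c("sgolay", "diff")) {
  method <- match.arg(method)
  stopifnot(inherits(s, "spectrum"))
  if (s$mode != "absorbance") {
    stop("second_derivative() expects an absorbance spectrum", call. = FALSE)
  }
  step <- diff(s$wavelengths)
  if (max(step) - min(step) > 1e-8) {
    stop("second_derivative() requires a uniform wavelength grid", call. = FALSE)
  }
  h <- step[1]
  n <- length(s$values)
  if (method == "sgolay") {
    if (sg_window %% 2L == 0L || sg_poly < 2L || sg_window <= sg_poly) {
      stop("need odd sg_window > sg_poly >= 2", call. = FALSE)
    }
    if (n < sg_window) {
      stop(sprintf("spectrum (%d points) shorter than filter window (%d)",
                   n, sg_window), call. = FALSE)
    }
    d2 <- signal::sgolayfilt(s$values, p = sg_poly, n = sg_window,
                             m = 2L, ts = h)
  } else {
    if (n < 3L) stop("need at least 3 points for central differences", call. = FALSE)
    d2 <- rep(NA_real_, n)
    d2[2:(n - 1)] <- (s$values[3:n] - 2 * s$values[2:(n - 1)] +
                        s$values[1:(n - 2)]) / h^2
    d2[1] <- d2[2]
    d2[n] <- d2[n - 1]
  }
  spectrum(s$wavelengths, d2, mode = "d2")
}

#' Assemble the NIR feature table
#'
#' Runs each berry's reflectance spectrum through the full preprocessing
#' chain (absorbance transform, wavelength window, Savitzky-Golay second
#' derivative) and stacks the results into the regression design: one row
#' per berry, one column per retained wavelength in ascending order, with
#' the target-concentration matrix aligned by sample.
#'
#' @param samples list of `berry_sample` objects (see [make_spectra()]):
#'   each has `sample_id`, `cultivar`, `treatment`, `spectrum`
#'   (reflectance) and `targets` (named numeric vector).
#' @param lo,hi wavelength window in nm (default 700-1100).
#' @param sg_window,sg_poly Savitzky-Golay parameters, see
#'   [second_derivative()].
#' @return A list: `x` (samples-by-wavelengths matrix of d2 absorbance),
#'   `y` (samples-by-targets matrix), `meta` (data frame of sample_id,
#'   cultivar, treatment).
#' @export
assemble_features <- function(samples, lo = 700, hi = 1100,
                              sg_window = 15L, sg_poly = 3L) {
  stopifnot(length(samples) >= 1L)
  grid0 <- samples[[1]]$spectrum$wavelengths
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    sp <- samples[[i]]$spectrum
    if (length(sp$wavelengths) != length(grid0) ||
        any(sp$wavelengths != grid0)) {
      stop(sprintf("sample '%s' is on a different wavelength grid",
                   samples[[i]]$sample_id), call. = FALSE)
    }
    d2 <- second_derivative(
      spectral_window(to_absorbance(sp), lo, hi), sg_window, sg_poly)
    rows[[i]] <- d2$values
  }
  wl <- spectral_window(samples[[1]]$spectrum, lo, hi)$wavelengths
  x <- do.call(rbind, rows)
  colnames(x) <- paste0("nm", wl)
  y <- do.call(rbind, lapply(samples, function(s) s$targets))
  meta <- data.frame(
    sample_id = vapply(samples, function(s) s$sample_id, character(1)),
    cultivar = vapply(samples, function(s) s$cultivar, character(1)),
    treatment = vapply(samples, function(s) s$treatment, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(x) <- rownames(y) <- meta$sample_id
  list(x = x, y = y, meta = meta)
}

#' Read and write spectra in long CSV form
#'
#' Long format: columns `sample_id, wavelength_nm, value, mode`.
#'
#' @param samples list of `berry_sample` objects.
#' @param path CSV path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns a list of `spectrum` objects keyed by
#'   sample_id.
#' @export
write_spectra_csv <- function(samples, path) {
  long <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id,
               wavelength_nm = s$spectrum$wavelengths,
               value = s$spectrum$values,
               mode = s$spectrum$mode)
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "wavelength_nm", "value", "mode")
  if (!all(need %in% names(d))) {
    stop("spectra CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(d, d$sample_id), function(g) {
    g <- g[order(g$wavelength_nm), ]
    spectrum(g$wavelength_nm, g$value, mode = g$mode[1])
  })
}

#' Rebuild berry samples from spectra and targets CSV files
#'
#' Joins a long-format spectra CSV (see [write_spectra_csv()]) with a
#' targets table (see [write_targets_csv()]) into the list of
#' `berry_sample` objects that [assemble_features()] and [run_nir()]
#' consume.
#'
#' @param spectra_path long-format spectra CSV.
#' @param targets_path targets CSV with columns `sample_id`, `cultivar`,
#'   `treatment` and one numeric column per target compound.
#' @return list of `berry_sample` objects, ordered as in the targets file.
#' @export
read_berry_samples <- function(spectra_path, targets_path) {
  spectra <- read_spectra_csv(spectra_path)
  tg <- read.csv(targets_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cultivar", "treatment")
  missing_cols <- setdiff(need, names(tg))
  if (length(missing_cols)) {
    stop("targets CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  target_cols <- setdiff(names(tg), need)
  if (!length(target_cols)) {
    stop("targets CSV has no target concentration columns", call. = FALSE)
  }
  lapply(seq_len(nrow(tg)), function(i) {
    sid <- tg$sample_id[i]
    sp <- spectra[[sid]]
    if (is.null(sp)) {
      stop("no spectrum found for sample_id '", sid, "'", call. = FALSE)
    }
    structure(list(
      sample_id = sid,
      cultivar = tg$cultivar[i],
      treatment = tg$treatment[i],
      spectrum = sp,
      targets = unlist(tg[i, target_cols])
    ), class = "berry_sample")
  })
}
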