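# Printed per-treatment concentration ranges of the three smoke-taint
# targets: guaiacol glycoconjugates in berries (ug/kg), in wine (ug/L),
# and guaiacol in wine (ug/L).
TAINT_RANGES <- list(
  gg_berry = list(control = c(37, 602), smoked = c(253, 2452)),
  gg_wine = list(control = c(8, 334), smoked = c(111, 1480)),
  guaiacol_wine = list(control = c(0, 9), smoked = c(0, 26))
)

SYNTH_CULTIVARS <- c("Merlot", "Shiraz", "Pinot Noir", "Cabernet Sauvignon",
                     "Pinot Gris", "Chardonnay", "Sauvignon Blanc")
WHITE_CULTIVARS <- c("Pinot Gris", "Chardonnay", "Sauvignon Blanc")

#' Configuration for synthetic berry NIR spectra
#'
#' Describes the synthetic berry dataset: 7 cultivars times
#' `n_per_cultivar` berries (default 16, half control / half smoked,
#' 112 in total) on a uniform 1 nm grid from 350 to 1850 nm. Each
#' berry's absorbance is a smooth baseline plus Gaussian bands - the O-H
#' overtone at 982 nm, a C-H shoulder near 1190 nm and a fixed water band
#' at 1450 nm - whose 982 nm depth and side-band shape increase
#' monotonically with the berry's smoke-taint load. White cultivars carry
#' a constant absorbance offset (default +0.05). Target concentrations
#' are drawn uniformly within the printed per-treatment ranges, tied
#' together by a common latent exposure dose per berry.
#'
#' @param n_per_cultivar berries per cultivar (even; default 16).
#' @param cultivars character vector of cultivar names.
#' @param wl_min,wl_max,wl_step wavelength grid in nm.
#' @param link_strength added 982 nm band depth (absorbance units) at
#'   maximal taint load; 0 removes the concentration-spectrum link.
#' @param noise_sd absorbance noise standard deviation.
#' @param white_offset constant absorbance offset for white cultivars.
#' @param seed integer seed.
#' @return A list of class `spectra_config`.
#' @export
spectra_config <- function(n_per_cultivar = 16L,
                           cultivars = SYNTH_CULTIVARS,
                           wl_min = 350, wl_max = 1850, wl_step = 1,
                           link_strength = 0.15,
                           noise_sd = 5e-4,
                           white_offset = 0.05,
                           seed = 1L) {
  stopifnot(n_per_cultivar >= 2L, n_per_cultivar %% 2L == 0L,
            length(cultivars) >= 1L, wl_min < wl_max, wl_step > 0,
            link_strength >= 0, noise_sd >= 0)
  structure(list(n_per_cultivar = as.integer(n_per_cultivar),
                 cultivars = cultivars,
                 wavelengths = seq(wl_min, wl_max, by = wl_step),
                 link_strength = link_strength, noise_sd = noise_sd,
                 white_offset = white_offset, seed = as.integer(seed)),
            class = "spectra_config")
}

gauss_band <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

#' Generate synthetic berry samples
#'
#' @param cfg a [spectra_config()].
#' @return A list of `berry_sample` objects (class `berry_sample`), each
#'   with `sample_id`, `cultivar`, `treatment`, `spectrum` (reflectance
#'   [spectrum()]) and `targets` (named vector gg_berry, gg_wine,
#'   guaiacol_wine; units ug/kg, ug/L, ug/L).
#' @export
make_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "spectra_config"))
  with_seed(cfg$seed, {
    wl <- cfg$wavelengths
    half <- cfg$n_per_cultivar %/% 2L
    samples <- list()
    sid <- 0L
    for (cv in cfg$cultivars) {
      is_white <- cv %in% WHITE_CULTIVARS
      for (treatment in c("control", "smoked")) {
        for (b in seq_len(half)) {
          sid <- sid + 1L
          # latent exposure dose ties the three targets together
          u <- runif(1)
          targets <- vapply(TAINT_RANGES, function(rg) {
            lim <- rg[[treatment]]
            ut <- min(max(u + rnorm(1, 0, 0.02), 0), 1)
            lim[1] + ut * (lim[2] - lim[1])
          }, numeric(1))
          # taint load on a common 0..1 scale across treatments
          load <- targets[["gg_berry"]] / max(TAINT_RANGES$gg_berry$smoked)
          baseline <- 0.25 + 1e-4 * (wl - 350) +
            0.05 * gauss_band(wl, 650, 120)          # pigment tail
          absorb <- baseline +
            (0.10 + cfg$link_strength * load) *
              gauss_band(wl, 982, 35 + 40 * cfg$link_strength * load) +
            (0.05 + 0.4 * cfg$link_strength * load) * gauss_band(wl, 1190, 45) +
            0.30 * gauss_band(wl, 1450, 55)
          if (is_white) absorb <- absorb + cfg$white_offset
          absorb <- absorb + rnorm(length(wl), 0, cfg$noise_sd)
          absorb <- pmax(absorb, 1e-4)
          refl <- pmin(10^(-absorb), 1)
          samples[[sid]] <- structure(list(
            sample_id = sprintf("B%03d", sid),
            cultivar = cv,
            treatment = treatment,
            spectrum = spectrum(wl, refl, mode = "reflectance"),
            targets = targets
          ), class = "berry_sample")
        }
      }
    }
    samples
  })
}

#' @export
print.berry_sample <- function(x, ...) {
  cat(sprintf("Berry %s (%s, %s): gg_berry %.0f ug/kg, gg_wine %.0f ug/L, guaiacol %.1f ug/L\n",
              x$sample_id, x$cultivar, x$treatment,
              x$targets[["gg_berry"]], x$targets[["gg_wine"]],
              x$targets[["guaiacol_wine"]]))
  invisible(x)
}

#' Write berry target concentrations as CSV
#'
#' @param samples list of `berry_sample` objects.
#' @param path CSV path; columns sample_id, cultivar, treatment and one
#'   per target.
#' @return `path`, invisibly.
#' @export
write_targets_csv <- function(samples, path) {
  d <- do.call(rbind, lapply(samples, function(s) {
    cbind(data.frame(sample_id = s$sample_id, cultivar = s$cultivar,
                     treatment = s$treatment),
          as.data.frame(as.list(s$targets)))
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
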