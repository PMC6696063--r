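# Field-of-view geometry: a 320 x 240 px image covers about 140 x 110 cm
# of canopy at 2.5 m range, so one pixel is ~0.44 x 0.46 cm and one cm^2
# is ~5 px.
FOV_CM <- c(width = 140, height = 110)

#' Configuration for a synthetic thermal scene
#'
#' Describes one synthetic canopy thermogram. Leaf temperature is driven
#' by a latent stomatal conductance (gs) through a linear surrogate for
#' the leaf energy balance: `T_leaf = t_dry - coupling * gs`, so a freely
#' transpiring leaf sits near the wet reference and a closed-stomata leaf
#' near the dry one.
#'
#' Control canopies have a vertically structured gs field (bottom band
#' markedly lower, below ~200 mmol m-2 s-1) tightly coupled to leaf
#' temperature. Smoked canopies emulate patchy stomatal behaviour:
#' the thermally expressed conductance is partially decoupled from the
#' latent (porometer-scale) gs - a fraction `1 - 1/patchiness` of each
#' patch's expressed gs is replaced by an independent draw around a
#' scene-specific random level - the vertical band structure is lost, and
#' within-canopy variance is multiplied by `patchiness`.
#'
#' @param height,width scene size in pixels (camera-native 240 x 320).
#' @param treatment `"control"` or `"smoked"`.
#' @param t_wet,t_dry reference temperatures embedded in the scene
#'   (degrees C).
#' @param leaf_fraction target fraction of pixels covered by leaf
#'   material, in (0, 1).
#' @param sky_temp,hot_temp non-leaf temperatures; must lie outside
#'   `[t_wet, t_dry]` (sky below, overheated material above).
#' @param gs_profile list with numeric `mean`/`sd` pairs `top`, `mid`,
#'   `bottom`: latent gs per canopy band, mmol m-2 s-1.
#' @param coupling degrees C of leaf cooling per unit gs.
#' @param patchiness within-canopy variance multiplier and decoupling
#'   strength for smoked scenes (>= 1; 1 = fully coupled).
#' @param gs_scale scene-level multiplier on the latent gs profile
#'   (vine-to-vine variation).
#' @param noise_sd per-pixel temperature noise, degrees C.
#' @param seed integer seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(height = 240L, width = 320L,
                         treatment = c("control", "smoked"),
                         t_wet = 20, t_dry = 32,
                         leaf_fraction = 0.55,
                         sky_temp = 8, hot_temp = 40,
                         gs_profile = list(top = c(mean = 250, sd = 40),
                                           mid = c(mean = 300, sd = 40),
                                           bottom = c(mean = 150, sd = 40)),
                         coupling = 0.0175,
                         patchiness = if (match.arg(treatment) == "smoked") 3 else 1,
                         gs_scale = 1,
                         noise_sd = 0.15,
                         seed = 1L) {
  treatment <- match.arg(treatment)
  stopifnot(height >= 40L, width >= 40L,
            t_dry > t_wet, patchiness >= 1, gs_scale > 0)
  if (leaf_fraction <= 0 || leaf_fraction >= 1) {
    stop("leaf_fraction must be in (0, 1)", call. = FALSE)
  }
  if (sky_temp >= t_wet) stop("sky_temp must be below t_wet", call. = FALSE)
  if (hot_temp <= t_dry) stop("hot_temp must be above t_dry", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 treatment = treatment, t_wet = t_wet, t_dry = t_dry,
                 leaf_fraction = leaf_fraction, sky_temp = sky_temp,
                 hot_temp = hot_temp, gs_profile = gs_profile,
                 coupling = coupling, patchiness = patchiness,
                 gs_scale = gs_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# rasterise one ellipse into TRUE cells of a logical matrix
ellipse_pixels <- function(h, w, cy, cx, ry, rx, angle) {
  r0 <- max(1L, floor(cy - max(ry, rx))); r1 <- min(h, ceiling(cy + max(ry, rx)))
  c0 <- max(1L, floor(cx - max(ry, rx))); c1 <- min(w, ceiling(cx + max(ry, rx)))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1
  cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  ca <- cos(angle); sa <- sin(angle)
  u <- dy * ca + dx * sa
  v <- -dy * sa + dx * ca
  inside <- (u / ry)^2 + (v / rx)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}

#' Generate a synthetic thermal scene
#'
#' Builds a radiometric image according to a [scene_config()]: a sky/hot
#' background, elliptical leaf patches (equivalent single-leaf area 50-80
#' cm2 at the 140 x 110 cm field of view) whose temperature follows the
#' linear gs coupling, and two embedded painted-reference patches at known
#' ROIs holding exactly `t_wet` and `t_dry`.
#'
#' @param cfg a [scene_config()].
#' @return A list of class `thermal_scene`: `image`
#'   ([radiometric_image()]), `wet_roi`, `dry_roi` ([roi()]s of the
#'   embedded reference patches), and `truth` (list: `treatment`,
#'   `gs_mean` - the coverage-weighted mean latent gs, `gs_scale`,
#'   `leaf_fraction` achieved).
#' @export
make_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width
    img <- matrix(cfg$sky_temp, h, w)
    # scattered overheated background elements (soil, posts)
    n_hot <- round(0.08 * h * w)
    hot_idx <- sample.int(h * w, n_hot)
    img[hot_idx] <- cfg$hot_temp

    px_per_cm2 <- (h / FOV_CM["height"]) * (w / FOV_CM["width"])
    leaf <- matrix(FALSE, h, w)
    gs_latent <- matrix(NA_real_, h, w)
    gs_expressed <- matrix(NA_real_, h, w)
    bands <- c("top", "mid", "bottom")
    base_means <- vapply(cfg$gs_profile, function(b) b[["mean"]], numeric(1))
    overall_mean <- mean(base_means)
    # smoked scenes drift to a random scene-specific expressed level,
    # independent of the vine's latent water status
    smoked <- cfg$treatment == "smoked"
    decouple_w <- 1 - 1 / cfg$patchiness
    scene_level <- if (smoked) rnorm(1, overall_mean, 80) else NA_real_

    target_px <- cfg$leaf_fraction * h * w
    tries <- 0L
    while (sum(leaf) < target_px && tries < 4000L) {
      tries <- tries + 1L
      area_cm2 <- runif(1, 50, 80)
      area_px <- area_cm2 * px_per_cm2
      aspect <- runif(1, 0.6, 1)
      ry <- sqrt(area_px / (pi * aspect))
      rx <- ry * aspect
      cy <- runif(1, 1, h)
      cx <- runif(1, 1, w)
      px <- ellipse_pixels(h, w, cy, cx, ry, rx, runif(1, 0, pi))
      if (is.null(px)) next
      band <- bands[pmin(3L, 1L + (cy - 1) %/% (h / 3))]
      prof <- cfg$gs_profile[[band]]
      mu_lat <- if (smoked) overall_mean else prof[["mean"]]
      lat <- rnorm(1, mu_lat * cfg$gs_scale,
                   prof[["sd"]] * if (smoked) cfg$patchiness else 1)
      expr <- if (smoked) {
        (1 - decouple_w) * lat +
          decouple_w * rnorm(1, scene_level, prof[["sd"]] * cfg$patchiness)
      } else lat
      lat <- max(lat, 5)
      expr <- max(expr, 5)
      leaf[px] <- TRUE
      gs_latent[px] <- lat
      gs_expressed[px] <- expr
    }

    span <- cfg$t_dry - cfg$t_wet
    gs_cap <- (span - 0.1) / cfg$coupling
    expr_px <- pmin(gs_expressed[leaf], gs_cap)
    t_leaf <- cfg$t_dry - cfg$coupling * expr_px +
      rnorm(sum(leaf), 0, cfg$noise_sd)
    img[leaf] <- pmin(pmax(t_leaf, cfg$t_wet + 0.05), cfg$t_dry - 0.05)

    # painted reference patches: wet top-left, dry top-right
    wet_roi <- roi(4L, 14L, 4L, 14L)
    dry_roi <- roi(4L, 14L, w - 14L, w - 4L)
    img[roi_rows(wet_roi), roi_cols(wet_roi)] <- cfg$t_wet
    img[roi_rows(dry_roi), roi_cols(dry_roi)] <- cfg$t_dry

    structure(list(
      image = radiometric_image(img),
      wet_roi = wet_roi, dry_roi = dry_roi,
      truth = list(treatment = cfg$treatment,
                   gs_mean = mean(gs_latent[leaf]),
                   gs_scale = cfg$gs_scale,
                   leaf_fraction = mean(leaf)),
      config = cfg
    ), class = "thermal_scene")
  })
}

#' Generate a labelled synthetic scene collection
#'
#' Mirrors the 48-image field design: `n_control + n_smoked` scenes with
#' scene-to-scene variation in the overall conductance level (`gs_scale`
#' drawn around 1), each generated from its own derived seed.
#'
#' @param n_control,n_smoked scene counts per class (default 24 + 24).
#' @param base_cfg template [scene_config()]; `treatment`, `gs_scale` and
#'   `seed` are overridden per scene.
#' @param seed master seed for per-scene seeds and gs_scale draws.
#' @param smoked_patchiness patchiness applied to smoked scenes
#'   (default 3).
#' @return A list of class `scene_dataset`: `scenes` (list of
#'   [make_scene()] outputs) and `labels` (factor control/smoked).
#' @export
make_dataset <- function(n_control = 24L, n_smoked = 24L,
                         base_cfg = scene_config(), seed = 1L,
                         smoked_patchiness = 3) {
  stopifnot(n_control >= 1L, n_smoked >= 1L)
  n <- n_control + n_smoked
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n),
    scales = pmin(pmax(rnorm(n, 1, 0.25), 0.4), 1.6)
  ))
  labels <- factor(rep(c("control", "smoked"), c(n_control, n_smoked)),
                   levels = c("control", "smoked"))
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- as.character(labels[i])
    cfg <- base_cfg
    cfg$treatment <- tr
    cfg$patchiness <- if (tr == "smoked") smoked_patchiness else 1
    cfg$gs_scale <- draws$scales[i]
    cfg$seed <- draws$seeds[i]
    scenes[[i]] <- make_scene(cfg)
  }
  structure(list(scenes = scenes, labels = labels, seed = seed),
            class = "scene_dataset")
}

#' Thermal feature table of a scene collection
#'
#' Runs every scene through reference extraction, masking and
#' [thermal_features()] at the given subdivision, producing the
#' classifier design matrix (one row per scene, `3 * m * n` columns).
#'
#' @param dataset a [make_dataset()] collection (or list of scenes).
#' @param m,n grid subdivision.
#' @return A list: `x` (feature matrix), `labels` (factor), `gs_mean`
#'   (latent truth per scene).
#' @export
dataset_features <- function(dataset, m, n) {
  scenes <- if (inherits(dataset, "scene_dataset")) dataset$scenes else dataset
  labels <- if (inherits(dataset, "scene_dataset")) dataset$labels else NULL
  rows <- lapply(scenes, function(sc) {
    refs <- extract_reference(sc$image, sc$wet_roi, sc$dry_roi)
    thermal_features(sc$image, refs, m, n)
  })
  x <- do.call(rbind, rows)
  list(x = x, labels = labels,
       gs_mean = vapply(scenes, function(sc) sc$truth$gs_mean, numeric(1)))
}
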