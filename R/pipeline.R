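#' End-to-end thermal classification pipeline
#'
#' Extracts per-cell thermal features from a scene collection at each
#' requested grid subdivision, runs the algorithm loop with neuron
#' trimming per grid, picks the best model across grids, and evaluates it.
#' Mirrors the four-input-set design (3x3/5x5/7x7/10x10 giving 27/75/147/
#' 300 features per image).
#'
#' @param dataset a [make_dataset()] scene collection, or a directory
#'   containing raster files with `.roi.json` sidecars and a
#'   `labels.csv` (columns `file`, `label`).
#' @param grids integer vector of subdivisions (applied as m = n).
#' @param algorithms,n_hidden,seed,max_epochs passed to [select_model()].
#' @param out_dir optional output directory; when given, per-grid feature
#'   CSVs, reports and a reproducibility manifest are written.
#' @return A list of class `thermal_run`: `per_grid` (named list of
#'   [select_model()] results), `features` (named list of feature
#'   matrices), `best_grid`, `best` (the winning selection),
#'   `report` (overall [classification_report()]).
#' @export
run_thermal <- function(dataset, grids = c(3L, 5L, 7L, 10L),
                        algorithms = c("scg", "rprop", "gda",
                                       "seq_wb", "rand_wb"),
                        n_hidden = c(3L, 7L, 10L), seed = 1L,
                        max_epochs = 300L, out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_scene_dir(dataset)
  stopifnot(inherits(dataset, "scene_dataset"))
  per_grid <- list()
  features <- list()
  for (g in grids) {
    key <- sprintf("%dx%d", g, g)
    feat <- dataset_features(dataset, g, g)
    features[[key]] <- feat$x
    per_grid[[key]] <- select_model(feat$x, feat$labels,
                                    algorithms = algorithms,
                                    n_hidden = n_hidden, seed = seed,
                                    max_epochs = max_epochs)
  }
  overall <- vapply(per_grid, function(s) s$leaderboard$overall_score[
    which(!s$leaderboard$overfit)[1]], numeric(1))
  best_grid <- names(per_grid)[which.max(overall)]
  best <- per_grid[[best_grid]]
  pr <- predict(best$best)
  report <- classification_report(dataset$labels, pr$prob[, "smoked"])
  out <- structure(list(per_grid = per_grid, features = features,
                        best_grid = best_grid, best = best,
                        report = report, seed = seed),
                   class = "thermal_run")
  if (!is.null(out_dir)) write_run_artifacts(out, dataset, out_dir, seed)
  out
}

#' @export
print.thermal_run <- function(x, ...) {
  cat("Thermal smoke-contamination classification run\n")
  for (key in names(x$per_grid)) {
    lb <- x$per_grid[[key]]$leaderboard
    i <- which(!lb$overfit)[1]
    cat(sprintf("  %-6s best %s (%d neurons): overall accuracy %.2f\n",
                key, lb$algorithm[i], lb$n_hidden[i], lb$overall_score[i]))
  }
  cat(sprintf("Best grid: %s; overall accuracy %.2f, AUC %.2f\n",
              x$best_grid, x$report$accuracy, x$report$auc))
  invisible(x)
}

#' End-to-end NIR regression pipeline
#'
#' Preprocesses berry spectra (absorbance, window, second derivative),
#' runs the algorithm loop with neuron trimming on the multi-target
#' regression (one network with all targets as outputs), and evaluates
#' the winner on the pooled predicted-versus-observed cloud.
#'
#' @param samples list of `berry_sample` objects (e.g. [make_spectra()]),
#'   or a list with `spectra` and `targets` CSV paths.
#' @param lo,hi,sg_window,sg_poly preprocessing, see
#'   [assemble_features()].
#' @param exclude optional character vector of sample_ids to drop.
#' @param algorithms,n_hidden,seed,max_epochs passed to [select_model()].
#' @param out_dir optional artifact directory.
#' @return A list of class `nir_run`: `selection` ([select_model()]
#'   result), `report` (overall [regression_report()]), `features`.
#' @export
run_nir <- function(samples, lo = 700, hi = 1100, sg_window = 15L,
                    sg_poly = 3L, exclude = NULL,
                    algorithms = c("scg", "rprop", "gda",
                                   "seq_wb", "rand_wb"),
                    n_hidden = c(3L, 7L, 10L), seed = 1L,
                    max_epochs = 300L, out_dir = NULL) {
  if (!is.null(exclude)) {
    keep <- !vapply(samples, function(s) s$sample_id %in% exclude, logical(1))
    samples <- samples[keep]
  }
  feat <- assemble_features(samples, lo, hi, sg_window, sg_poly)
  selection <- select_model(feat$x, feat$y, algorithms = algorithms,
                            n_hidden = n_hidden, seed = seed,
                            max_epochs = max_epochs)
  pred <- predict(selection$best)
  report <- regression_report(feat$y, pred)
  out <- structure(list(selection = selection, report = report,
                        features = feat, seed = seed),
                   class = "nir_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pv <- data.frame(sample_id = rep(feat$meta$sample_id, ncol(feat$y)),
                     target = rep(colnames(feat$y), each = nrow(feat$y)),
                     observed = as.numeric(feat$y),
                     predicted = as.numeric(pred))
    write.csv(pv, file.path(out_dir, "predicted_vs_observed.csv"),
              row.names = FALSE)
    write_report(report, file.path(out_dir, "nir_report"))
    write_manifest(out_dir, seed,
                   list(lo = lo, hi = hi, sg_window = sg_window,
                        sg_poly = sg_poly, n = nrow(feat$x)))
  }
  out
}

#' @export
print.nir_run <- function(x, ...) {
  b <- x$selection$best$spec
  cat(sprintf("NIR smoke-taint regression run: best %s, %d neurons\n",
              b$algorithm_label, b$n_hidden))
  cat(sprintf("  overall R %.3f, slope %.3f, %.1f%% outliers (95%% band)\n",
              x$report$r, x$report$slope, 100 * x$report$outlier_fraction))
  invisible(x)
}

# read a directory of rasters + sidecars + labels.csv into a scene_dataset
read_scene_dir <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) {
    stop("scene directory needs a labels.csv (columns file, label)",
         call. = FALSE)
  }
  lab <- read.csv(lab_path, stringsAsFactors = FALSE)
  if (nrow(lab) == 0L) stop("labels.csv is empty", call. = FALSE)
  scenes <- lapply(seq_len(nrow(lab)), function(i) {
    path <- file.path(dir, lab$file[i])
    img <- read_raster(path)
    rois <- read_roi_sidecar(paste0(path, ".roi.json"))
    list(image = img, wet_roi = rois$wet, dry_roi = rois$dry,
         truth = list(treatment = lab$label[i], gs_mean = NA_real_))
  })
  structure(list(scenes = scenes,
                 labels = factor(lab$label,
                                 levels = c("control", "smoked")),
                 seed = NA_integer_),
            class = "scene_dataset")
}

write_run_artifacts <- function(run, dataset, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(run$features)) {
    d <- as.data.frame(run$features[[key]])
    d <- cbind(label = as.character(dataset$labels), d)
    write.csv(d, file.path(out_dir, paste0("features_", key, ".csv")),
              row.names = FALSE)
  }
  write_report(run$report, file.path(out_dir, "thermal_report"))
  write_manifest(out_dir, seed,
                 list(grids = names(run$features),
                      best_grid = run$best_grid,
                      n_scenes = length(dataset$scenes)))
}

# reproducibility manifest: config, seed, versions, content hashes of the
# artifacts already present in out_dir
write_manifest <- function(out_dir, seed, config) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  names(hashes) <- files
  jsonlite::write_json(
    list(seed = seed, config = config,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("smokesense")),
         files = as.list(hashes)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
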