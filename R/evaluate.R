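#' Through-origin linear regression
#'
#' Least-squares fit of `y = b x` constrained through the origin, the
#' convention used for the Ig-gs calibration: the slope is
#' `b = sum(x y) / sum(x^2)` and the goodness of fit is reported as
#' `r2 = 1 - RSS / TSS` with residuals taken about the through-origin
#' line but the total sum of squares centred on the mean of `y`. With the
#' centred total sum of squares r2 can be negative when the origin
#' constraint fits worse than a constant.
#'
#' @param x,y numeric vectors (>= 2 points). `x` must not be all zero and
#'   `y` must not be constant.
#' @return An object of class `origin_fit`: list with `slope`, `r2`, `n`.
#' @export
#' @examples
#' gs <- c(112.66, 384.93, 130.60, 211.40)
#' ig <- c(0.32, 1.06, 0.34, 0.52)
#' origin_fit(gs, ig)
origin_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  if (all(x == 0)) stop("singular fit: all x are zero", call. = FALSE)
  if (sd(y) == 0) stop("r2 undefined: y is constant", call. = FALSE)
  slope <- sum(x * y) / sum(x * x)
  rss <- sum((y - slope * x)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = slope, r2 = 1 - rss / tss, n = length(x)),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("Through-origin fit (n = %d): slope = %.4g, R2 = %.3f\n",
              x$n, x$slope, x$r2))
  invisible(x)
}

#' Classification evaluation report
#'
#' Accuracy and confusion matrix at the 0.5 probability threshold, mean
#' cross-entropy in nats, and the ROC curve traced by sweeping the
#' decision threshold over the unique scores with trapezoidal area.
#'
#' @param truth factor (or 0/1 vector) of true labels; the second factor
#'   level (or 1) is the positive class.
#' @param scores numeric vector in `[0, 1]`: predicted probability of the
#'   positive class.
#' @return A list of class `classification_report`: `confusion` (2x2
#'   table, truth in rows), `accuracy`, `cross_entropy`, `roc` (data
#'   frame `fpr`, `tpr` from (0,0) to (1,1)), `auc`.
#' @export
classification_report <- function(truth, scores) {
  if (is.factor(truth) || is.character(truth)) {
    truth <- factor(truth)
    if (nlevels(truth) != 2L) {
      stop("ROC undefined: need exactly two classes in truth", call. = FALSE)
    }
    pos <- truth == levels(truth)[2]
    lv <- levels(truth)
  } else {
    pos <- truth == 1
    lv <- c("0", "1")
  }
  stopifnot(length(pos) == length(scores))
  if (any(scores < 0 | scores > 1)) {
    stop("scores must be probabilities in [0, 1]", call. = FALSE)
  }
  if (all(pos) || all(!pos)) {
    stop("ROC undefined: truth contains a single class", call. = FALSE)
  }
  pred_pos <- scores >= 0.5
  confusion <- table(truth = factor(ifelse(pos, lv[2], lv[1]), levels = lv),
                     predicted = factor(ifelse(pred_pos, lv[2], lv[1]),
                                        levels = lv))
  accuracy <- mean(pred_pos == pos)
  p <- pmin(pmax(ifelse(pos, scores, 1 - scores), 1e-12), 1)
  cross_entropy <- mean(-log(p))
  # threshold sweep over unique scores, descending; (0,0) at +Inf
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(confusion = confusion, accuracy = accuracy,
                 cross_entropy = cross_entropy,
                 roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 n = length(scores)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (n = %d): accuracy %.3f, AUC %.3f, CE %.3f nats\n",
              x$n, x$accuracy, x$auc, x$cross_entropy))
  print(x$confusion)
  invisible(x)
}

#' Regression evaluation report
#'
#' Pools predicted and observed values (all targets together, as in an
#' overall predicted-versus-observed plot against the 1:1 line) and
#' reports the Pearson correlation R, the slope of the least-squares line
#' `predicted = a + b * observed`, the mean squared error, and the
#' fraction of points falling outside the 95% prediction band of that
#' line. On noiseless data the band has zero width; the outlier fraction
#' is then reported as 0 and flagged `degenerate_band`.
#'
#' @param truth,pred numeric vectors or matrices of equal size (>= 3
#'   points after pooling).
#' @param level prediction-band coverage (default 0.95).
#' @return A list of class `regression_report`: `r`, `slope`,
#'   `intercept`, `mse`, `outlier_fraction`, `n`, `degenerate_band`.
#' @export
regression_report <- function(truth, pred, level = 0.95) {
  truth <- as.numeric(truth)
  pred <- as.numeric(pred)
  stopifnot(length(truth) == length(pred))
  if (length(truth) < 3L) stop("need at least 3 points", call. = FALSE)
  if (sd(truth) == 0) {
    stop("degenerate input: truth has zero variance", call. = FALSE)
  }
  dat <- data.frame(truth = truth, pred = pred)
  fit <- lm(pred ~ truth, data = dat)
  r <- stats::cor(pred, truth)
  mse <- mean((pred - truth)^2)
  sigma <- summary(fit)$sigma
  degenerate <- !is.finite(sigma) || sigma < 1e-12
  if (degenerate) {
    outlier_fraction <- 0
  } else {
    band <- predict(fit, newdata = dat, interval = "prediction",
                    level = level)
    outlier_fraction <- mean(pred < band[, "lwr"] | pred > band[, "upr"])
  }
  structure(list(r = r, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), mse = mse,
                 outlier_fraction = outlier_fraction,
                 degenerate_band = degenerate, level = level,
                 n = length(truth)),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Regression report (n = %d): R %.3f, slope %.3f, MSE %.4g\n",
              x$n, x$r, x$slope, x$mse))
  cat(sprintf("  %.0f%% prediction-band outliers: %.1f%%%s\n",
              100 * x$level, 100 * x$outlier_fraction,
              if (x$degenerate_band) " (zero-width band)" else ""))
  invisible(x)
}

#' Write an evaluation report to JSON and a text summary
#'
#' @param report a `classification_report` or `regression_report`.
#' @param path output path without extension; writes `<path>.json` and
#'   `<path>.txt` (plus `<path>_roc.csv` for classification).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  flat <- unclass(report)
  flat$confusion <- if (!is.null(flat$confusion)) as.data.frame(flat$confusion)
  flat$roc <- NULL
  jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, txt_path)
  paths <- c(json_path, txt_path)
  if (inherits(report, "classification_report")) {
    roc_path <- paste0(path, "_roc.csv")
    write.csv(report$roc, roc_path, row.names = FALSE)
    paths <- c(paths, roc_path)
  }
  invisible(paths)
}
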