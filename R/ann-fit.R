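#' Random data partition
#'
#' Splits `n_samples` indices at random into the stage sets the training
#' protocol uses. Two schemes exist, matching the two algorithm families:
#' `"train_val_test"` (60/20/20: training, validation for early stopping,
#' test) for 3-stage algorithms, and `"train_test"` (70/30) for 2-stage
#' incremental algorithms. The minor splits receive round-half-up of their
#' fraction and training the remainder, which yields 28/10/10 and 34/14
#' for 48 samples and 78/33 for 111 samples.
#'
#' @param n_samples number of samples (>= 5).
#' @param scheme `"train_val_test"` or `"train_test"`.
#' @param seed integer seed controlling the random assignment.
#' @return An object of class `partition_plan`: list with `scheme`,
#'   `seed`, `n`, and integer index vectors `train`, `val` (absent for
#'   train_test), `test`.
#' @export
#' @examples
#' lengths(partition(48, "train_val_test", 1)[c("train", "val", "test")])
partition <- function(n_samples, scheme = c("train_val_test", "train_test"),
                      seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_samples >= 5L)
  rhu <- function(x) floor(x + 0.5)  # round half up
  perm <- with_seed(seed, sample.int(n_samples))
  if (scheme == "train_val_test") {
    n_val <- rhu(0.2 * n_samples)
    n_test <- rhu(0.2 * n_samples)
    n_train <- n_samples - n_val - n_test
    if (min(n_train, n_val, n_test) < 1L) {
      stop("partition produced an empty split", call. = FALSE)
    }
    plan <- list(scheme = scheme, seed = seed, n = n_samples,
                 train = sort(perm[seq_len(n_train)]),
                 val = sort(perm[n_train + seq_len(n_val)]),
                 test = sort(perm[n_train + n_val + seq_len(n_test)]))
  } else {
    n_test <- rhu(0.3 * n_samples)
    n_train <- n_samples - n_test
    if (min(n_train, n_test) < 1L) {
      stop("partition produced an empty split", call. = FALSE)
    }
    plan <- list(scheme = scheme, seed = seed, n = n_samples,
                 train = sort(perm[seq_len(n_train)]),
                 test = sort(perm[n_train + seq_len(n_test)]))
  }
  structure(plan, class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  sizes <- vapply(x[c("train", "val", "test")], length, integer(1))
  sizes <- sizes[sizes > 0]
  cat(sprintf("Partition (%s, seed %d): %s of %d samples\n", x$scheme,
              x$seed, paste(names(sizes), sizes, sep = "=", collapse = ", "),
              x$n))
  invisible(x)
}

#' Fit a one-hidden-layer feedforward network
#'
#' The modelling core: a shallow network with tan-sigmoid hidden units and
#' a softmax output trained on mean cross-entropy (classification, `y` a
#' factor) or a linear output trained on mean squared error (regression,
#' `y` a numeric vector or matrix of target concentrations). Training uses
#' one of the registry algorithms (see [ann_algorithms()]); 3-stage
#' algorithms early-stop on a validation split.
#'
#' Features are standardised to zero mean and unit variance on the
#' training split only; regression targets are min-max scaled to
#' \[-1, 1\] per column on the training split (for stability with
#' mixed-unit multi-target fits) and back-transformed at prediction.
#'
#' @param x numeric feature matrix, samples in rows.
#' @param y factor (2+ classes) or numeric vector/matrix of targets.
#' @param n_hidden hidden-layer width; the trimming set used for model
#'   selection is 3, 7 and 10.
#' @param algorithm registry id from [ann_algorithms()].
#' @param plan optional [partition()]; defaults to the scheme the
#'   algorithm's family prescribes, built from `seed`.
#' @param seed integer seed for weight initialisation and partitioning.
#' @param max_epochs iteration/epoch budget (default 300).
#' @param max_fail early-stopping patience on the validation loss.
#' @param ... tuning parameters passed to the specific trainer
#'   (e.g. `lr`, `momentum`).
#' @return An object of class `smoke_ann` with `print()`, `summary()`,
#'   `coef()`, `predict()`, `residuals()`, `plot()` and `simulate()`
#'   methods. Component `performance` tabulates loss and
#'   accuracy/correlation per stage.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 3), 30))
#' y <- factor(rep(c("control", "smoked"), each = 30))
#' fit <- ann_fit(x, y, n_hidden = 3, algorithm = "scg", seed = 7)
#' fit
ann_fit <- function(x, y, n_hidden = 10L, algorithm = "scg", plan = NULL,
                    seed = 1L, max_epochs = 300L, max_fail = 6L, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  entry <- algorithm_entry(algorithm)
  task <- if (is.factor(y) || is.character(y)) "classification" else "regression"

  if (task == "classification") {
    y <- factor(y)
    if (nlevels(y) < 2L) stop("classification needs >= 2 classes", call. = FALSE)
    levels_y <- levels(y)
    Tmat <- t(stats::model.matrix(~ y - 1))  # k x N one-hot
    k <- nlevels(y)
  } else {
    y <- as.matrix(y)
    storage.mode(y) <- "double"
    if (is.null(colnames(y))) colnames(y) <- paste0("target", seq_len(ncol(y)))
    levels_y <- NULL
    k <- ncol(y)
  }
  n <- nrow(x)
  if ((task == "classification" && length(y) != n) ||
      (task == "regression" && nrow(y) != n)) {
    stop("x and y disagree on the number of samples", call. = FALSE)
  }
  if (anyNA(x)) stop("x contains missing values; impute first", call. = FALSE)

  if (is.null(plan)) {
    scheme <- if (entry$stages == 3L) "train_val_test" else "train_test"
    plan <- partition(n, scheme, seed)
  }
  stopifnot(inherits(plan, "partition_plan"), plan$n == n)

  # standardise features on the training split only
  xc <- colMeans(x[plan$train, , drop = FALSE])
  xs <- apply(x[plan$train, , drop = FALSE], 2L, sd)
  xs[!is.finite(xs) | xs == 0] <- 1
  Xall <- t((x - rep(xc, each = n)) / rep(xs, each = n))  # p x N

  if (task == "regression") {
    ymin <- apply(y[plan$train, , drop = FALSE], 2L, min)
    ymax <- apply(y[plan$train, , drop = FALSE], 2L, max)
    span <- ymax - ymin
    span[span == 0] <- 1
    Tall <- t(2 * (y - rep(ymin, each = n)) / rep(span, each = n) - 1)
  } else {
    ymin <- ymax <- NULL
    Tall <- Tmat
  }

  d <- net_dims(nrow(Xall), as.integer(n_hidden), k)
  Xtr <- Xall[, plan$train, drop = FALSE]
  Ttr <- Tall[, plan$train, drop = FALSE]
  fn <- function(theta) net_loss_grad(theta, Xtr, Ttr, task, d)
  val_fn <- NULL
  if (!is.null(plan$val)) {
    Xv <- Xall[, plan$val, drop = FALSE]
    Tv <- Tall[, plan$val, drop = FALSE]
    val_fn <- function(theta) net_loss(theta, Xv, Tv, task, d)
  }

  res <- with_seed(seed, {
    theta0 <- net_init(d)
    switch(algorithm,
      scg = train_scg(theta0, fn, val_fn, max_epochs, max_fail),
      rprop = train_rprop(theta0, fn, val_fn, max_epochs, max_fail),
      gdm = train_gdm(theta0, fn, val_fn, max_epochs, max_fail, ...),
      gda = train_gda(theta0, fn, val_fn, max_epochs, max_fail, ...),
      lm = train_lm(theta0, Xtr, Ttr, task, d, val_fn, max_epochs, max_fail, ...),
      seq_wb = train_incremental(theta0, Xtr, Ttr, task, d, max_epochs,
                                 order = "sequential", algorithm = "seq_wb", ...),
      rand_wb = train_incremental(theta0, Xtr, Ttr, task, d, max_epochs,
                                  order = "random", algorithm = "rand_wb", ...)
    )
  })

  fit <- structure(list(
    spec = list(n_inputs = d$p, n_hidden = d$h, n_outputs = d$k,
                task = task, algorithm = algorithm,
                algorithm_label = entry$label, seed = seed),
    weights = net_unpack(res$theta, d),
    theta = res$theta,
    scaling = list(x_center = xc, x_scale = xs,
                   y_min = ymin, y_max = ymax,
                   levels = levels_y,
                   targets = if (task == "regression") colnames(y) else NULL),
    plan = plan,
    training_log = res$log,
    data = list(x = x, y = y),
    call = match.call()
  ), class = "smoke_ann")
  fit$performance <- stage_performance(fit)
  fit
}

# loss + headline score (accuracy or pooled Pearson R) per partition stage
stage_performance <- function(fit) {
  plan <- fit$plan
  stages <- c("train", "val", "test")
  rows <- list()
  for (st in stages) {
    idx <- plan[[if (st == "train") "train" else st]]
    if (is.null(idx)) next
    xs <- fit$data$x[idx, , drop = FALSE]
    pr <- predict(fit, xs)
    if (fit$spec$task == "classification") {
      truth <- fit$data$y[idx]
      acc <- mean(pr$class == truth)
      p <- pmin(pmax(pr$prob[cbind(seq_along(idx),
                                   as.integer(truth))], 1e-12), 1)
      loss <- mean(-log(p))
      rows[[st]] <- data.frame(stage = st, n = length(idx),
                               loss = loss, score = acc)
    } else {
      truth <- fit$data$y[idx, , drop = FALSE]
      loss <- model_scale_mse(fit, truth, pr)
      r <- stats::cor(as.numeric(pr), as.numeric(truth))
      rows[[st]] <- data.frame(stage = st, n = length(idx),
                               loss = loss, score = r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# MSE on the internal [-1, 1] target scale (the training objective).
model_scale_mse <- function(fit, truth, pred) {
  sc <- fit$scaling
  span <- sc$y_max - sc$y_min
  span[span == 0] <- 1
  tt <- 2 * sweep(sweep(truth, 2L, sc$y_min), 2L, span, "/") - 1
  pp <- 2 * sweep(sweep(pred, 2L, sc$y_min), 2L, span, "/") - 1
  mean((tt - pp)^2)
}

#' Predict from a fitted shallow network
#'
#' @param object a `smoke_ann` fit.
#' @param newdata feature matrix with `n_inputs` columns; defaults to the
#'   training data.
#' @param ... unused.
#' @return For classification, a list with `class` (factor) and `prob`
#'   (matrix of softmax probabilities, rows summing to 1); for regression,
#'   a matrix of predicted concentrations on the original target scale.
#' @export
predict.smoke_ann <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else as.matrix(newdata)
  if (ncol(x) != object$spec$n_inputs) {
    stop(sprintf("feature width %d does not match the %d network inputs",
                 ncol(x), object$spec$n_inputs), call. = FALSE)
  }
  sc <- object$scaling
  Xs <- t((x - rep(sc$x_center, each = nrow(x))) / rep(sc$x_scale, each = nrow(x)))
  fw <- net_forward(object$weights, Xs, object$spec$task)
  if (object$spec$task == "classification") {
    prob <- t(fw$Y)
    colnames(prob) <- sc$levels
    cls <- factor(sc$levels[max.col(prob, ties.method = "first")],
                  levels = sc$levels)
    list(class = cls, prob = prob)
  } else {
    span <- sc$y_max - sc$y_min
    span[span == 0] <- 1
    out <- t((fw$Y + 1) / 2)
    out <- sweep(sweep(out, 2L, span, "*"), 2L, sc$y_min, "+")
    colnames(out) <- sc$targets
    out
  }
}

#' @export
print.smoke_ann <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Shallow feedforward %s network (%d-%d-%d)\n",
              s$task, s$n_inputs, s$n_hidden, s$n_outputs))
  cat(sprintf("  algorithm: %s ('%s'), seed %d\n",
              s$algorithm_label, s$algorithm, s$seed))
  cat(sprintf("  partition: %s\n", x$plan$scheme))
  perf <- x$performance
  lab <- if (s$task == "classification") "accuracy" else "R"
  for (i in seq_len(nrow(perf))) {
    cat(sprintf("  %-5s n=%3d  loss=%.4f  %s=%.3f\n", perf$stage[i],
                perf$n[i], perf$loss[i], lab, perf$score[i]))
  }
  invisible(x)
}

#' @export
summary.smoke_ann <- function(object, ...) {
  structure(list(spec = object$spec, performance = object$performance,
                 plan = object$plan,
                 n_par = length(object$theta),
                 epochs = nrow(object$training_log)),
            class = "summary.smoke_ann")
}

#' @export
print.summary.smoke_ann <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Shallow %s network %d-%d-%d (%d parameters)\n", s$task,
              s$n_inputs, s$n_hidden, s$n_outputs, x$n_par))
  cat(sprintf("Trained by %s for %d epochs; partition %s (seed %d)\n",
              s$algorithm_label, x$epochs, x$plan$scheme, s$seed))
  print(x$performance, row.names = FALSE)
  invisible(x)
}

#' @export
coef.smoke_ann <- function(object, ...) object$weights

#' @export
residuals.smoke_ann <- function(object, ...) {
  if (object$spec$task != "regression") {
    stop("residuals are defined for regression fits", call. = FALSE)
  }
  object$data$y - predict(object)
}

#' @export
plot.smoke_ann <- function(x, ...) {
  log <- x$training_log
  if (is.null(log) || nrow(log) == 0) {
    stop("no training log to plot", call. = FALSE)
  }
  has_val <- any(is.finite(log$val_loss))
  ylim <- range(c(log$train_loss, if (has_val) log$val_loss), finite = TRUE)
  plot.default(log$epoch, log$train_loss, type = "l", xlab = "epoch",
               ylab = "loss", ylim = ylim, ...)
  if (has_val) {
    lines(log$epoch, log$val_loss, lty = 2)
    legend("topright", legend = c("training", "validation"),
           lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Simulate responses from a fitted network
#'
#' Classification fits draw labels from the predicted class probabilities;
#' regression fits add Gaussian noise with the residual standard deviation
#' per target to the predictions.
#'
#' @param object a `smoke_ann` fit.
#' @param nsim number of simulated response sets.
#' @param seed integer seed.
#' @param newdata optional feature matrix (defaults to training data).
#' @param ... unused.
#' @return A list of length `nsim`; each element is a factor (labels) or a
#'   numeric matrix (concentrations).
#' @export
simulate.smoke_ann <- function(object, nsim = 1, seed = NULL,
                               newdata = NULL, ...) {
  pr <- predict(object, newdata)
  runner <- function() {
    if (object$spec$task == "classification") {
      lv <- object$scaling$levels
      factor(apply(pr$prob, 1L, function(p) sample(lv, 1L, prob = p)),
             levels = lv)
    } else {
      sds <- apply(residuals(object), 2L, sd)
      pr + matrix(rnorm(length(pr), 0, rep(sds, each = nrow(pr))),
                  nrow(pr))
    }
  }
  if (is.null(seed)) {
    replicate(nsim, runner(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, runner(), simplify = FALSE))
  }
}
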