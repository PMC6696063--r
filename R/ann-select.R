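#' Algorithm loop with neuron trimming
#'
#' Reproduces the model-selection protocol: every candidate training
#' algorithm is run at each hidden-layer width of the trimming set
#' (3, 7 and 10 neurons), each with the data-partition scheme its family
#' prescribes, and the candidates are ranked by test-stage score
#' (classification accuracy or regression correlation R). A candidate
#' whose training score exceeds its test score by more than the relative
#' `overfit_margin` is flagged as overfitting and cannot be selected; the
#' best model is the top-ranked unflagged candidate.
#'
#' @inheritParams ann_fit
#' @param algorithms character vector of registry ids (>= 1; see
#'   [ann_algorithms()]).
#' @param n_hidden trimming set of hidden-layer widths.
#' @param overfit_margin relative train-minus-test score gap above which a
#'   candidate is flagged (default 0.10).
#' @param refit_best if `TRUE` (default) the winning configuration's fit is
#'   kept as `$best`.
#' @return An object of class `smoke_ann_selection`: list with `best` (a
#'   [ann_fit()] object), `leaderboard` (one row per algorithm-width
#'   candidate, ranked), `task` and `seed`. Errors with class
#'   `smokesense_selection_failure` (leaderboard attached as the
#'   `leaderboard` condition field) if every candidate overfits.
#' @export
select_model <- function(x, y, algorithms = c("scg", "rprop", "gda",
                                              "seq_wb", "rand_wb"),
                         n_hidden = c(3L, 7L, 10L), seed = 1L,
                         overfit_margin = 0.10, max_epochs = 300L, ...) {
  stopifnot(length(algorithms) >= 1L, length(n_hidden) >= 1L)
  x <- as.matrix(x)
  n <- nrow(x)
  plans <- list(
    train_val_test = partition(n, "train_val_test", seed),
    train_test = partition(n, "train_test", seed)
  )
  rows <- list()
  fits <- list()
  for (alg in algorithms) {
    entry <- algorithm_entry(alg)
    scheme <- if (entry$stages == 3L) "train_val_test" else "train_test"
    for (h in n_hidden) {
      fit <- ann_fit(x, y, n_hidden = h, algorithm = alg,
                     plan = plans[[scheme]], seed = seed,
                     max_epochs = max_epochs, ...)
      perf <- fit$performance
      g <- function(st, col) {
        v <- perf[[col]][perf$stage == st]
        if (length(v)) v else NA_real_
      }
      train_score <- g("train", "score")
      test_score <- g("test", "score")
      # overall score pools every sample regardless of stage
      pr <- predict(fit)
      overall <- if (fit$spec$task == "classification") {
        mean(pr$class == fit$data$y)
      } else {
        stats::cor(as.numeric(pr), as.numeric(fit$data$y))
      }
      gap <- (train_score - test_score) / max(abs(train_score), 1e-12)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, n_hidden = h, scheme = scheme,
        train_loss = g("train", "loss"), val_loss = g("val", "loss"),
        test_loss = g("test", "loss"),
        train_score = train_score, test_score = test_score,
        overall_score = overall, gap = gap,
        overfit = is.finite(gap) && gap > overfit_margin,
        stringsAsFactors = FALSE)
      fits[[length(fits) + 1L]] <- fit
    }
  }
  lb <- do.call(rbind, rows)
  ord <- order(-lb$test_score, -lb$overall_score, lb$n_hidden)
  lb <- lb[ord, ]
  fits <- fits[ord]
  rownames(lb) <- NULL
  ok <- which(!lb$overfit)
  if (length(ok) == 0L) {
    cond <- structure(
      class = c("smokesense_selection_failure", "error", "condition"),
      list(message = "model selection failed: every candidate shows overfitting",
           call = sys.call(-1), leaderboard = lb))
    stop(cond)
  }
  task <- fits[[1]]$spec$task
  structure(list(best = fits[[ok[1]]], leaderboard = lb,
                 task = task, seed = seed,
                 overfit_margin = overfit_margin),
            class = "smoke_ann_selection")
}

#' @export
print.smoke_ann_selection <- function(x, ...) {
  lab <- if (x$task == "classification") "accuracy" else "R"
  cat(sprintf("Model selection over %d candidates (%s)\n",
              nrow(x$leaderboard), x$task))
  b <- x$best$spec
  i <- which(x$leaderboard$algorithm == b$algorithm &
               x$leaderboard$n_hidden == b$n_hidden)[1]
  cat(sprintf("Best: %s, %d neurons - test %s %.3f, overall %s %.3f\n",
              b$algorithm_label, b$n_hidden, lab,
              x$leaderboard$test_score[i], lab,
              x$leaderboard$overall_score[i]))
  invisible(x)
}

#' @export
summary.smoke_ann_selection <- function(object, ...) {
  cat(sprintf("Leaderboard (%s; overfit margin %.0f%%):\n", object$task,
              100 * object$overfit_margin))
  lb <- object$leaderboard
  lb[c("train_loss", "val_loss", "test_loss", "train_score",
       "test_score", "overall_score", "gap")] <-
    lapply(lb[c("train_loss", "val_loss", "test_loss", "train_score",
                "test_score", "overall_score", "gap")],
           function(v) round(v, 3))
  print(lb, row.names = FALSE)
  invisible(object)
}

#' @export
plot.smoke_ann_selection <- function(x, ...) {
  lb <- x$leaderboard
  algs <- unique(lb$algorithm)
  widths <- sort(unique(lb$n_hidden))
  m <- sapply(algs, function(a) {
    sapply(widths, function(h) {
      v <- lb$test_score[lb$algorithm == a & lb$n_hidden == h]
      if (length(v)) v[1] else NA_real_
    })
  })
  m <- matrix(m, nrow = length(widths),
              dimnames = list(widths, algs))
  matplot(widths, m, type = "b", pch = seq_along(algs), lty = 1,
          xlab = "hidden neurons", ylab = "test score", ...)
  legend("bottomright", legend = algs, pch = seq_along(algs),
         col = seq_along(algs), bty = "n", cex = 0.8)
  invisible(x)
}
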