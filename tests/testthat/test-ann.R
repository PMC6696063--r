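test_that("partition reproduces the protocol's printed split sizes", {
  p1 <- partition(48, "train_val_test", 1)
  expect_equal(lengths(p1[c("train", "val", "test")]),
               c(train = 28L, val = 10L, test = 10L))
  p2 <- partition(48, "train_test", 1)
  expect_equal(lengths(p2[c("train", "test")]), c(train = 34L, test = 14L))
  p3 <- partition(111, "train_test", 1)
  expect_equal(lengths(p3[c("train", "test")]), c(train = 78L, test = 33L))
})

test_that("partitions are disjoint, exhaustive, and size-stable in the seed", {
  for (n in c(23, 48, 111, 200)) {
    p <- partition(n, "train_val_test", 5)
    all_idx <- sort(c(p$train, p$val, p$test))
    expect_equal(all_idx, seq_len(n))
    q <- partition(n, "train_val_test", 6)
    expect_equal(lengths(p[c("train", "val", "test")]),
                 lengths(q[c("train", "val", "test")]))
    expect_false(identical(p$train, q$train))
  }
})

test_that("a linearly separable problem is learned perfectly", {
  set.seed(4)
  x <- rbind(matrix(rnorm(90, 0), 30), matrix(rnorm(90, 3), 30))
  y <- factor(rep(c("control", "smoked"), each = 30))
  fit <- ann_fit(x, y, n_hidden = 3, algorithm = "scg", seed = 8)
  perf <- fit$performance
  expect_equal(perf$score[perf$stage == "train"], 1)
  # predicting the training set agrees with the labels
  pr <- predict(fit, x[fit$plan$train, ])
  expect_equal(as.character(pr$class), as.character(y[fit$plan$train]))
})

test_that("noiseless linear targets are fit to R >= 0.999 on test", {
  set.seed(5)
  x <- matrix(rnorm(500), 100, 5)
  y <- x %*% c(1, -2, 0.5, 3, -1)
  fit <- ann_fit(x, y, n_hidden = 5, algorithm = "lm", seed = 2,
                 max_epochs = 100)
  perf <- fit$performance
  expect_gte(perf$score[perf$stage == "test"], 0.999)
})

test_that("training is deterministic given seed, data and spec", {
  set.seed(9)
  x <- matrix(rnorm(200), 40, 5)
  y <- factor(rep(c("a", "b"), 20))
  f1 <- ann_fit(x, y, n_hidden = 3, algorithm = "rprop", seed = 31)
  f2 <- ann_fit(x, y, n_hidden = 3, algorithm = "rprop", seed = 31)
  expect_identical(f1$theta, f2$theta)
  f3 <- ann_fit(x, y, n_hidden = 3, algorithm = "rprop", seed = 32)
  expect_false(identical(f1$theta, f3$theta))
})

test_that("softmax probabilities are normalised and errors are typed", {
  set.seed(10)
  x <- matrix(rnorm(100), 20, 5)
  y <- factor(rep(c("a", "b"), 10))
  fit <- ann_fit(x, y, n_hidden = 3, algorithm = "scg", seed = 1,
                 max_epochs = 20)
  pr <- predict(fit, matrix(rnorm(50), 10, 5))
  expect_equal(unname(rowSums(pr$prob)), rep(1, 10), tolerance = 1e-9)
  expect_error(predict(fit, matrix(0, 3, 4)), "feature width")
  expect_error(ann_fit(x, y, algorithm = "no_such"), "unknown training algorithm")
})

test_that("constant features yield chance-level accuracy", {
  x <- matrix(1, 40, 5)
  y <- factor(rep(c("a", "b"), 20))
  fit <- ann_fit(x, y, n_hidden = 3, algorithm = "scg", seed = 1,
                 max_epochs = 50)
  perf <- fit$performance
  expect_lte(abs(perf$score[perf$stage == "train"] - 0.5), 0.2)
})

test_that("the algorithm loop covers algorithms x widths and ranks by test score", {
  set.seed(12)
  x <- rbind(matrix(rnorm(150, 0), 30), matrix(rnorm(150, 2.5), 30))
  y <- factor(rep(c("control", "smoked"), each = 30))
  sel <- select_model(x, y, algorithms = c("scg", "rprop"),
                      n_hidden = c(3, 7), seed = 2, max_epochs = 100)
  expect_equal(nrow(sel$leaderboard), 4L)
  expect_true(all(diff(sel$leaderboard$test_score) <= 1e-12))
  expect_false(sel$leaderboard$overfit[
    sel$leaderboard$algorithm == sel$best$spec$algorithm &
      sel$leaderboard$n_hidden == sel$best$spec$n_hidden][1])

  one <- select_model(x, y, algorithms = "scg", n_hidden = 3, seed = 2,
                      max_epochs = 50)
  expect_equal(nrow(one$leaderboard), 1L)
})

test_that("model methods expose weights, residuals and simulations", {
  set.seed(20)
  x <- matrix(rnorm(300), 60, 5)
  y <- x %*% c(2, 1, 0, -1, 0.5) + rnorm(60, 0, 0.1)
  fit <- ann_fit(x, y, n_hidden = 7, algorithm = "scg", seed = 3,
                 max_epochs = 200)
  w <- coef(fit)
  expect_named(w, c("W1", "b1", "W2", "b2"))
  expect_equal(dim(w$W1), c(7L, 5L))
  res <- residuals(fit)
  expect_equal(dim(res), dim(as.matrix(y)))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(as.matrix(y)))
  s <- summary(fit)
  expect_s3_class(s, "summary.smoke_ann")
})
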