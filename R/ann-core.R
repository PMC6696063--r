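# One-hidden-layer feedforward network internals.
#
# Architecture: input (p) -> tanh hidden layer (h) -> output (k), with
# softmax output + mean cross-entropy for classification and linear output
# + mean squared error for regression. Parameters are kept as a flat
# vector `theta` = [vec(W1), b1, vec(W2), b2]; X is stored p x N
# (columns = samples) so forward/backward passes are single matrix
# products.

net_dims <- function(p, h, k) {
  list(p = p, h = h, k = k, n_par = h * p + h + k * h + k)
}

net_unpack <- function(theta, d) {
  i <- 0L
  W1 <- matrix(theta[(i + 1):(i + d$h * d$p)], d$h, d$p); i <- i + d$h * d$p
  b1 <- theta[(i + 1):(i + d$h)]; i <- i + d$h
  W2 <- matrix(theta[(i + 1):(i + d$k * d$h)], d$k, d$h); i <- i + d$k * d$h
  b2 <- theta[(i + 1):(i + d$k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

net_pack <- function(w) c(as.numeric(w$W1), w$b1, as.numeric(w$W2), w$b2)

# Small uniform initial weights scaled by fan-in, seeded by the caller's
# RNG state.
net_init <- function(d) {
  a1 <- 1 / sqrt(d$p)
  a2 <- 1 / sqrt(d$h)
  c(runif(d$h * d$p, -a1, a1), runif(d$h, -a1, a1),
    runif(d$k * d$h, -a2, a2), runif(d$k, -a2, a2))
}

net_forward <- function(w, X, task) {
  Z1 <- w$W1 %*% X + w$b1
  A1 <- tanh(Z1)
  Z2 <- w$W2 %*% A1 + w$b2
  Y <- if (task == "classification") softmax_cols(Z2) else Z2
  list(A1 = A1, Z2 = Z2, Y = Y)
}

softmax_cols <- function(Z) {
  Zs <- sweep(Z, 2L, apply(Z, 2L, max), "-")
  E <- exp(Zs)
  sweep(E, 2L, colSums(E), "/")
}

# Loss and gradient at theta over the columns of X/T.
# classification: mean per-sample cross-entropy in nats (stable via
# log-sum-exp); regression: mean squared error over all outputs.
net_loss_grad <- function(theta, X, T, task, d, grad = TRUE) {
  w <- net_unpack(theta, d)
  N <- ncol(X)
  Z1 <- w$W1 %*% X + w$b1
  A1 <- tanh(Z1)
  Z2 <- w$W2 %*% A1 + w$b2
  if (task == "classification") {
    zmax <- apply(Z2, 2L, max)
    lse <- zmax + log(colSums(exp(sweep(Z2, 2L, zmax, "-"))))
    loss <- mean(lse - colSums(Z2 * T))
    if (!grad) return(list(loss = loss))
    Y <- softmax_cols(Z2)
    dZ2 <- (Y - T) / N
  } else {
    R <- Z2 - T
    loss <- sum(R * R) / (N * d$k)
    if (!grad) return(list(loss = loss))
    dZ2 <- 2 * R / (N * d$k)
  }
  dW2 <- dZ2 %*% t(A1)
  db2 <- rowSums(dZ2)
  dA1 <- crossprod(w$W2, dZ2)
  dZ1 <- dA1 * (1 - A1 * A1)
  dW1 <- dZ1 %*% t(X)
  db1 <- rowSums(dZ1)
  list(loss = loss,
       grad = c(as.numeric(dW1), db1, as.numeric(dW2), db2))
}

net_loss <- function(theta, X, T, task, d) {
  net_loss_grad(theta, X, T, task, d, grad = FALSE)$loss
}

#' Training-algorithm registry
#'
#' The classical training algorithms implemented for the shallow network,
#' one or more per family: Jacobian-based (Levenberg-Marquardt),
#' gradient-based batch methods (scaled conjugate gradient, resilient
#' backpropagation, gradient descent with momentum or with adaptive
#' learning rate) and supervised weight-and-bias incremental updates in
#' sequential or random sample order. `stages` records the data-partition
#' protocol each algorithm uses: 3-stage algorithms train with a
#' validation split for early stopping (60/20/20), 2-stage ones use a
#' plain train/test split (70/30).
#'
#' @return A data frame with columns `id`, `label`, `family`, `stages`.
#' @export
ann_algorithms <- function() {
  data.frame(
    id = c("lm", "scg", "rprop", "gdm", "gda", "seq_wb", "rand_wb"),
    label = c("Levenberg-Marquardt",
              "Scaled conjugate gradient",
              "Resilient backpropagation",
              "Gradient descent with momentum",
              "Gradient descent with adaptive rate",
              "Sequential order weight and bias",
              "Random order weight and bias"),
    family = c("jacobian", "gradient", "gradient", "gradient", "gradient",
               "weight_bias", "weight_bias"),
    stages = c(3L, 3L, 3L, 3L, 3L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

algorithm_entry <- function(id) {
  reg <- ann_algorithms()
  i <- match(id, reg$id)
  if (is.na(i)) {
    stop(sprintf("unknown training algorithm '%s'; see ann_algorithms()", id),
         call. = FALSE)
  }
  reg[i, ]
}

# --- trainers -------------------------------------------------------------
# Each trainer receives the training objective and an optional validation
# loss function for early stopping (restore-best, patience `max_fail`),
# and returns list(theta, log = data.frame(epoch, train_loss, val_loss)).

check_finite <- function(loss, algorithm) {
  if (!is.finite(loss)) {
    stop(sprintf("divergence: non-finite loss in algorithm '%s'", algorithm),
         call. = FALSE)
  }
}

run_early_stop <- function(state, val_loss, theta, max_fail) {
  if (is.null(state$best_val) || val_loss < state$best_val) {
    state$best_val <- val_loss
    state$best_theta <- theta
    state$fails <- 0L
  } else {
    state$fails <- state$fails + 1L
  }
  state$stop <- state$fails >= max_fail
  state
}

# Moller's scaled conjugate gradient (batch).
train_scg <- function(theta, fn, val_fn, max_epochs, max_fail) {
  sigma0 <- 5e-5
  lambda <- 5e-7
  lambdabar <- 0
  ev <- fn(theta)
  check_finite(ev$loss, "scg")
  g <- ev$grad
  r <- -g
  p <- r
  success <- TRUE
  n_par <- length(theta)
  es <- list(best_val = NULL, best_theta = theta, fails = 0L, stop = FALSE)
  log <- vector("list", max_epochs)
  delta <- 1
  for (k in seq_len(max_epochs)) {
    p2 <- sum(p * p)
    if (p2 < 1e-30) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      g2 <- fn(theta + sigma * p)$grad
      s <- (g2 - g) / sigma
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambdabar) * p2
    if (delta <= 0) {
      lambdabar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambdabar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    theta_new <- theta + alpha * p
    loss_new <- fn(theta_new)$loss
    check_finite(loss_new, "scg")
    Delta <- 2 * delta * (ev$loss - loss_new) / (mu * mu)
    if (Delta >= 0) {
      theta <- theta_new
      ev <- fn(theta)
      g_new <- ev$grad
      r_new <- -g_new
      lambdabar <- 0
      success <- TRUE
      if (k %% n_par == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      g <- g_new
      if (Delta >= 0.75) lambda <- max(lambda * 0.25, 1e-15)
    } else {
      lambdabar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (lambda > 1e15) break
    vl <- NA_real_
    if (!is.null(val_fn)) {
      vl <- val_fn(theta)
      es <- run_early_stop(es, vl, theta, max_fail)
    }
    log[[k]] <- c(epoch = k, train_loss = ev$loss, val_loss = vl)
    if (!is.null(val_fn) && es$stop) break
    if (sqrt(sum(g * g)) < 1e-8) break
  }
  if (!is.null(val_fn) && !is.null(es$best_val)) theta <- es$best_theta
  list(theta = theta, log = as.data.frame(do.call(rbind, Filter(Negate(is.null), log))))
}

# iRprop- resilient backpropagation (batch, sign-based step adaptation).
train_rprop <- function(theta, fn, val_fn, max_epochs, max_fail) {
  step <- rep(0.01, length(theta))
  eta_plus <- 1.2; eta_minus <- 0.5
  step_max <- 50; step_min <- 1e-9
  g_prev <- rep(0, length(theta))
  es <- list(best_val = NULL, best_theta = theta, fails = 0L, stop = FALSE)
  log <- vector("list", max_epochs)
  for (k in seq_len(max_epochs)) {
    ev <- fn(theta)
    check_finite(ev$loss, "rprop")
    g <- ev$grad
    prod_sign <- g_prev * g
    step <- ifelse(prod_sign > 0, pmin(step * eta_plus, step_max),
                   ifelse(prod_sign < 0, pmax(step * eta_minus, step_min), step))
    g[prod_sign < 0] <- 0
    theta <- theta - sign(g) * step
    g_prev <- g
    vl <- NA_real_
    if (!is.null(val_fn)) {
      vl <- val_fn(theta)
      es <- run_early_stop(es, vl, theta, max_fail)
    }
    log[[k]] <- c(epoch = k, train_loss = ev$loss, val_loss = vl)
    if (!is.null(val_fn) && es$stop) break
  }
  if (!is.null(val_fn) && !is.null(es$best_val)) theta <- es$best_theta
  list(theta = theta, log = as.data.frame(do.call(rbind, Filter(Negate(is.null), log))))
}

# Batch gradient descent with momentum (fixed learning rate).
train_gdm <- function(theta, fn, val_fn, max_epochs, max_fail,
                      lr = 0.1, momentum = 0.9) {
  v <- rep(0, length(theta))
  es <- list(best_val = NULL, best_theta = theta, fails = 0L, stop = FALSE)
  log <- vector("list", max_epochs)
  for (k in seq_len(max_epochs)) {
    ev <- fn(theta)
    check_finite(ev$loss, "gdm")
    v <- momentum * v - lr * ev$grad
    theta <- theta + v
    vl <- NA_real_
    if (!is.null(val_fn)) {
      vl <- val_fn(theta)
      es <- run_early_stop(es, vl, theta, max_fail)
    }
    log[[k]] <- c(epoch = k, train_loss = ev$loss, val_loss = vl)
    if (!is.null(val_fn) && es$stop) break
  }
  if (!is.null(val_fn) && !is.null(es$best_val)) theta <- es$best_theta
  list(theta = theta, log = as.data.frame(do.call(rbind, Filter(Negate(is.null), log))))
}

# Batch gradient descent with adaptive learning rate: accept a step when
# the loss rises by no more than 4%, then grow the rate; otherwise reject
# and shrink it.
train_gda <- function(theta, fn, val_fn, max_epochs, max_fail,
                      lr = 0.05, lr_inc = 1.05, lr_dec = 0.7,
                      max_perf_inc = 1.04) {
  ev <- fn(theta)
  check_finite(ev$loss, "gda")
  es <- list(best_val = NULL, best_theta = theta, fails = 0L, stop = FALSE)
  log <- vector("list", max_epochs)
  for (k in seq_len(max_epochs)) {
    theta_new <- theta - lr * ev$grad
    ev_new <- fn(theta_new)
    check_finite(ev_new$loss, "gda")
    if (ev_new$loss <= ev$loss * max_perf_inc) {
      theta <- theta_new
      if (ev_new$loss < ev$loss) lr <- lr * lr_inc
      ev <- ev_new
    } else {
      lr <- lr * lr_dec
      if (lr < 1e-12) break
    }
    vl <- NA_real_
    if (!is.null(val_fn)) {
      vl <- val_fn(theta)
      es <- run_early_stop(es, vl, theta, max_fail)
    }
    log[[k]] <- c(epoch = k, train_loss = ev$loss, val_loss = vl)
    if (!is.null(val_fn) && es$stop) break
  }
  if (!is.null(val_fn) && !is.null(es$best_val)) theta <- es$best_theta
  list(theta = theta, log = as.data.frame(do.call(rbind, Filter(Negate(is.null), log))))
}

# Levenberg-Marquardt on the residual vector (Gauss-Newton with adaptive
# damping). For classification the residuals are softmax output minus
# one-hot target, with the Jacobian taken through the softmax.
train_lm <- function(theta, X, T, task, d, val_fn, max_epochs, max_fail,
                     mu = 1e-3, mu_inc = 10, mu_dec = 0.1, mu_max = 1e10) {
  N <- ncol(X)
  resid_jac <- function(theta) {
    w <- net_unpack(theta, d)
    fw <- net_forward(w, X, task)
    R <- fw$Y - T                      # k x N residuals
    J <- matrix(0, N * d$k, d$n_par)
    for (i in seq_len(N)) {
      a1 <- fw$A1[, i]
      x <- X[, i]
      # dz2/dtheta for sample i (k x n_par)
      Jz <- matrix(0, d$k, d$n_par)
      dA1 <- (1 - a1 * a1)
      for (j in seq_len(d$k)) {
        dz1 <- w$W2[j, ] * dA1        # h
        ej <- as.numeric(seq_len(d$k) == j)
        Jz[j, ] <- c(as.numeric(outer(dz1, x)), dz1,
                     as.numeric(a1 %x% ej),   # column-major vec of k x h
                     ej)
      }
      Ji <- if (task == "classification") {
        y <- fw$Y[, i]
        (diag(y) - tcrossprod(y)) %*% Jz
      } else Jz
      J[((i - 1) * d$k + 1):(i * d$k), ] <- Ji
    }
    list(R = as.numeric(R), J = J, sse = sum(R * R) / (N * d$k))
  }
  rj <- resid_jac(theta)
  check_finite(rj$sse, "lm")
  es <- list(best_val = NULL, best_theta = theta, fails = 0L, stop = FALSE)
  log <- vector("list", max_epochs)
  for (k in seq_len(max_epochs)) {
    JtJ <- crossprod(rj$J)
    Jtr <- crossprod(rj$J, rj$R)
    improved <- FALSE
    while (mu <= mu_max) {
      H <- JtJ + mu * diag(d$n_par)
      step <- tryCatch(solve(H, Jtr), error = function(e) NULL)
      if (is.null(step)) { mu <- mu * mu_inc; next }
      theta_new <- theta - as.numeric(step)
      rj_new <- resid_jac(theta_new)
      if (is.finite(rj_new$sse) && rj_new$sse < rj$sse) {
        theta <- theta_new
        rj <- rj_new
        mu <- max(mu * mu_dec, 1e-20)
        improved <- TRUE
        break
      }
      mu <- mu * mu_inc
    }
    vl <- NA_real_
    if (!is.null(val_fn)) {
      vl <- val_fn(theta)
      es <- run_early_stop(es, vl, theta, max_fail)
    }
    log[[k]] <- c(epoch = k, train_loss = rj$sse, val_loss = vl)
    if (!improved || (!is.null(val_fn) && es$stop)) break
  }
  if (!is.null(val_fn) && !is.null(es$best_val)) theta <- es$best_theta
  list(theta = theta, log = as.data.frame(do.call(rbind, Filter(Negate(is.null), log))))
}

# Incremental (per-sample) weight-and-bias updates with momentum and a
# slowly decaying learning rate; samples visited in fixed sequential order
# or reshuffled each epoch.
train_incremental <- function(theta, X, T, task, d, max_epochs,
                              order = c("sequential", "random"),
                              lr = 0.05, momentum = 0.6, lr_decay = 0.99,
                              algorithm = "seq_wb") {
  order <- match.arg(order)
  N <- ncol(X)
  v <- rep(0, length(theta))
  log <- vector("list", max_epochs)
  for (k in seq_len(max_epochs)) {
    idx <- if (order == "random") sample.int(N) else seq_len(N)
    for (i in idx) {
      gi <- net_loss_grad(theta, X[, i, drop = FALSE],
                          T[, i, drop = FALSE], task, d)$grad
      v <- momentum * v - lr * gi
      theta <- theta + v
    }
    tl <- net_loss(theta, X, T, task, d)
    check_finite(tl, algorithm)
    log[[k]] <- c(epoch = k, train_loss = tl, val_loss = NA_real_)
    lr <- lr * lr_decay
  }
  list(theta = theta, log = as.data.frame(do.call(rbind, Filter(Negate(is.null), log))))
}
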