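# Minimal dense feed-forward network with Adam training.
# Matrix-based, CPU-only; sized for per-element atomistic regressors
# (a few thousand samples, descriptor dimension of order 10-100).

activation_funs <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(a) 1 - a^2),
         relu = list(f = function(z) pmax(z, 0), df = function(a) (a > 0) * 1),
         sigmoid = list(f = stats::plogis, df = function(a) a * (1 - a)),
         stop("unknown activation: '", name, "' (use tanh, relu or sigmoid)"))
}

# Xavier-style initialization for hidden layers, zero-initialized linear
# output (so an untrained net predicts the target mean exactly); relies on
# the caller having seeded the RNG.
mlp_init <- function(n_in, hidden, activation = "tanh") {
  sizes <- c(n_in, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    sd <- sqrt(1 / sizes[l])
    W[[l]] <- if (l < length(W)) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sd),
             sizes[l], sizes[l + 1L])
    } else {
      matrix(0, sizes[l], sizes[l + 1L])
    }
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, activation = activation, sizes = sizes)
}

# Forward pass; X is n x d. Returns activations per layer when train = TRUE.
mlp_forward <- function(net, X, train = FALSE) {
  act <- activation_funs(net$activation)
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$W[[l]] + rep(net$b[[l]], each = nrow(X))
    A[[l + 1L]] <- if (l < L) act$f(Z) else Z  # linear output layer
  }
  if (train) A else as.numeric(A[[L + 1L]])
}

# One full-batch Adam step on the mean-squared-error loss; returns updated
# net + optimizer state and the loss before the step.
mlp_adam_step <- function(net, state, X, y, lr, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8) {
  act <- activation_funs(net$activation)
  n <- nrow(X)
  L <- length(net$W)
  A <- mlp_forward(net, X, train = TRUE)
  resid <- as.numeric(A[[L + 1L]]) - y
  loss <- mean(resid^2)
  delta <- matrix(2 * resid / n, n, 1L)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * act$df(A[[l]])
    }
  }
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (l in seq_len(L)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * gW[[l]]^2
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * gb[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / corr1) /
      (sqrt(state$vW[[l]] / corr2) + eps)
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / corr1) /
      (sqrt(state$vb[[l]] / corr2) + eps)
  }
  list(net = net, state = state, loss = loss)
}

mlp_adam_state <- function(net) {
  zeroes <- function(x) lapply(x, function(m) m * 0)
  list(t = 0L, mW = zeroes(net$W), vW = zeroes(net$W),
       mb = zeroes(net$b), vb = zeroes(net$b))
}

# Train on standardized data with early stopping on a validation split.
# Returns the best (lowest validation loss) network seen.
mlp_train <- function(X_train, y_train, X_val, y_val, hidden, activation,
                      lr, epochs, patience) {
  net <- mlp_init(ncol(X_train), hidden, activation)
  state <- mlp_adam_state(net)
  best <- net
  best_val <- Inf
  since_best <- 0L
  for (epoch in seq_len(epochs)) {
    step <- mlp_adam_step(net, state, X_train, y_train, lr)
    net <- step$net
    state <- step$state
    if (!is.finite(step$loss)) {
      stop("non-finite training loss at epoch ", epoch,
           "; try a smaller learning rate")
    }
    val_loss <- mean((mlp_forward(net, X_val) - y_val)^2)
    if (val_loss < best_val) {
      best_val <- val_loss
      best <- net
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
  }
  list(net = best, val_loss = best_val, epochs_run = epoch)
}
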