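# Independent reference implementations used as oracles. These are written
# as explicit scalar loops over the update equations and share no code with
# the package internals.

logistic <- function(v) 1 / (1 + exp(-v))

# Simulate `steps` synchronous inference steps (and optionally one Hebbian
# update after every `per_cycle` steps) with plain loops.
oracle_simulate <- function(W, x, y, frame, eps_inf, eps_learn, dx,
                            steps, per_cycle = Inf) {
  L <- length(W)
  y[[1]] <- as.numeric(frame)
  beta <- vector("list", L)
  since_learn <- 0
  for (s in seq_len(steps)) {
    for (l in 1:L) {
      pred <- numeric(length(y[[l]]))
      for (i in seq_along(pred))
        for (j in seq_along(y[[l + 1]]))
          pred[i] <- pred[i] + W[[l]][i, j] * y[[l + 1]][j]
      beta[[l]] <- y[[l]] - pred
    }
    for (l in 2:(L + 1)) {
      up <- numeric(length(x[[l]]))
      for (j in seq_along(up))
        for (i in seq_along(beta[[l - 1]]))
          up[j] <- up[j] + W[[l - 1]][i, j] * beta[[l - 1]][i]
      if (l <= L) up <- up - beta[[l]]
      x[[l]] <- x[[l]] + eps_inf * up
      y[[l]] <- logistic(x[[l]] + dx)
    }
    since_learn <- since_learn + 1
    if (since_learn == per_cycle) {
      for (l in 1:L)
        for (i in seq_len(nrow(W[[l]])))
          for (j in seq_len(ncol(W[[l]])))
            W[[l]][i, j] <- W[[l]][i, j] + eps_learn * beta[[l]][i] * y[[l + 1]][j]
      since_learn <- 0
    }
  }
  list(W = W, x = x, y = y, beta = beta)
}

# Objective: half the summed squared prediction errors for given rates.
oracle_objective_W <- function(W, y) {
  e <- 0
  for (l in seq_along(W))
    e <- e + 0.5 * sum((y[[l]] - as.numeric(W[[l]] %*% y[[l + 1]]))^2)
  e
}

# Same objective as a function of activations x (rates recomputed).
oracle_objective_x <- function(W, x, y0, dx) {
  y <- c(list(y0), lapply(x[-1], function(v) logistic(v + dx)))
  oracle_objective_W(W, y)
}

# Small random network for gradient checks.
tiny_setup <- function(sizes = c(6, 5, 4), seed = 7) {
  set.seed(seed)
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l)
    matrix(runif(sizes[l] * sizes[l + 1], -0.3, 0.5), sizes[l], sizes[l + 1]))
  x <- lapply(sizes, function(n) rnorm(n, 0, 0.7))
  y0 <- runif(sizes[1])
  list(sizes = sizes, W = W, x = x, y0 = y0, dx = -0.5)
}

wrap_weights <- function(W, seed = NA_integer_) {
  structure(W, class = "pcnet_weights", seed = as.integer(seed))
}
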