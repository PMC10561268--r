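test_that("weight initialization is clipped, scaled and reproducible", {
  cfg <- pcnet_config(area_sizes = c(4, 3))
  W <- init_weights(cfg, seed = 1)
  expect_identical(dim(W[[1]]), c(4L, 3L))
  expect_true(all(W[[1]] >= 0))
  expect_identical(init_weights(cfg, seed = 1), W)
  expect_false(identical(init_weights(cfg, seed = 2), W))
})

test_that("initial weight magnitude matches the clipped-Gaussian mean", {
  # Monte-Carlo oracle for E[max(0, N(0, 0.5))], independent draws
  set.seed(99)
  mc <- mean(pmax(rnorm(1e6, 0, 0.5), 0))
  cfg <- pcnet_config(area_sizes = c(1000, 1000))
  W <- init_weights(cfg, seed = 3)
  # entries are divided by the next-area size (1000)
  expect_equal(mean(W[[1]]) * 1000, mc, tolerance = 0.01)
  expect_equal(mc, 0.5 / sqrt(2 * pi), tolerance = 0.005)
})

test_that("reset installs the uniform low rate and its pre-activation", {
  cfg <- pcnet_config(area_sizes = c(4, 3, 2), reset_rate = 0.5,
                      activation_offset = 0)
  st <- reset_state(cfg)
  expect_equal(st$x[[2]], rep(0, 3))                    # logit(0.5) = 0
  cfg2 <- pcnet_config(area_sizes = c(4, 3), reset_rate = 0.1,
                       activation_offset = 0)
  st2 <- reset_state(cfg2)
  expect_equal(st2$x[[2]], rep(log(1 / 9), 3))          # logit oracle
  # offset shifts the pre-activation so that the rate is unchanged
  cfg3 <- pcnet_config(area_sizes = c(4, 3), reset_rate = 0.1,
                       activation_offset = -2)
  expect_equal(1 / (1 + exp(-(reset_state(cfg3)$x[[2]] - 2))), rep(0.1, 3))
  expect_true(all(vapply(st$beta, function(b) all(b == 0), TRUE)))
  expect_true(all(vapply(st$y, function(v) all(v == 0.5), TRUE)))
})

test_that("input clamping reflects pixels linearly and checks shapes", {
  cfg <- pcnet_config(area_sizes = c(4, 2))
  st <- reset_state(cfg)
  expect_equal(clamp_input(st, rep(0, 4))$y[[1]], rep(0, 4))
  expect_equal(clamp_input(st, c(0, 1, 0, 0))$y[[1]], c(0, 1, 0, 0))
  expect_equal(clamp_input(st, rep(0.25, 4))$y[[1]], rep(0.25, 4))
  expect_equal(clamp_input(st, rep(0.25, 4))$y[[2]], st$y[[2]])
  expect_error(clamp_input(st, rep(0, 5)), "pixels")
  expect_error(clamp_input(st, c(0, 0, 0, 1.5)), "\\[0, 1\\]")
})

test_that("error neurons compute rate minus top-down prediction", {
  cfg <- pcnet_config(area_sizes = c(1, 2))
  st <- reset_state(cfg)
  st$y[[1]] <- 0.5
  st$y[[2]] <- c(1, 1)
  W <- wrap_weights(list(matrix(c(0.2, 0.1), 1, 2)))
  expect_equal(compute_errors(st, W)$beta[[1]], 0.2)
  Wz <- wrap_weights(list(matrix(0, 1, 2)))
  expect_equal(compute_errors(st, Wz)$beta[[1]], st$y[[1]])
  Wp <- wrap_weights(list(matrix(c(0.5, 0), 1, 2)))    # perfect prediction
  expect_equal(compute_errors(st, Wp)$beta[[1]], 0)
})

test_that("activation updates follow the signed error drive", {
  cfg <- pcnet_config(area_sizes = c(1, 1, 1), inference_rate = 0.05,
                      activation_offset = 0)
  st <- reset_state(cfg)
  st$x[[2]] <- 0
  st$beta[[1]] <- 0.5          # bottom-up error into area 1
  st$beta[[2]] <- 0.5          # area 1's own error
  W <- wrap_weights(list(matrix(2), matrix(1)))
  st2 <- update_activations(st, W, cfg)
  # x_1 += eps * (t(W_0) beta_0 - beta_1) = 0.05 * (2*0.5 - 0.5)
  expect_equal(st2$x[[2]], 0.025)
  # top area: only the bottom-up term
  expect_equal(st2$x[[3]], st$x[[3]] + 0.05 * (1 * 0.5))
  # zero errors are a fixed point (rates kept consistent with x)
  st$beta[[1]] <- 0; st$beta[[2]] <- 0
  st$y[[2]] <- 1 / (1 + exp(-st$x[[2]]))
  st$y[[3]] <- 1 / (1 + exp(-st$x[[3]]))
  st3 <- update_activations(st, W, cfg)
  expect_equal(st3$x, st$x)
  expect_equal(st3$y, st$y)
})

test_that("hidden rates stay strictly inside (0,1) under strong drive", {
  cfg <- pcnet_config(area_sizes = c(2, 2), inference_rate = 0.5)
  st <- reset_state(cfg)
  W <- wrap_weights(list(matrix(c(3, -3, 2, -1), 2, 2)))
  for (i in 1:50) {
    st <- compute_errors(st, W)
    st <- update_activations(st, W, cfg)
    expect_true(all(st$y[[2]] > 0 & st$y[[2]] < 1))
  }
})

test_that("the Hebbian update is the scaled error-rate outer product", {
  cfg <- pcnet_config(area_sizes = c(1, 1), learning_rate = 0.1)
  st <- reset_state(cfg)
  st$beta[[1]] <- 1
  st$y[[2]] <- 0.5
  W <- wrap_weights(list(matrix(0.3)))
  expect_equal(hebbian_update(W, st, cfg)[[1]], matrix(0.3 + 0.05))
  st$beta[[1]] <- 0
  expect_equal(hebbian_update(W, st, cfg)[[1]], W[[1]])
  st$beta[[1]] <- -1                       # over-prediction weakens the synapse
  expect_lt(hebbian_update(W, st, cfg)[[1]][1, 1], W[[1]][1, 1])
})

test_that("an inference cycle matches the step-by-step scalar-loop oracle", {
  sizes <- c(2, 2)
  set.seed(5)
  Wm <- list(matrix(runif(4, 0, 0.4), 2, 2))
  cfg <- pcnet_config(area_sizes = sizes, inference_rate = 0.05,
                      activation_offset = -1, reset_rate = 0.2)
  st <- reset_state(cfg)
  frame <- c(0.8, 0.1)
  got <- inference_cycle(st, wrap_weights(Wm), frame, cfg, steps = 10)
  ref <- oracle_simulate(Wm, st$x, st$y, frame, 0.05, 0, -1, steps = 10)
  expect_equal(got$y[[2]], ref$y[[2]], tolerance = 1e-12)
  expect_equal(got$x[[2]], ref$x[[2]], tolerance = 1e-12)
  # zero steps: dynamics untouched
  got0 <- inference_cycle(st, wrap_weights(Wm), frame, cfg, steps = 0)
  expect_equal(got0$x, st$x)
  # zero weights: the top area receives no drive on the first step
  gz <- inference_cycle(st, wrap_weights(list(matrix(0, 2, 2))), frame, cfg,
                        steps = 1)
  expect_equal(gz$x[[2]], st$x[[2]])
})

test_that("three-area inference matches the scalar-loop oracle", {
  sizes <- c(3, 3, 2)
  set.seed(11)
  Wm <- list(matrix(runif(9, 0, 0.3), 3, 3), matrix(runif(6, 0, 0.3), 3, 2))
  cfg <- pcnet_config(area_sizes = sizes, activation_offset = -2)
  st <- reset_state(cfg)
  frame <- runif(3)
  got <- inference_cycle(st, wrap_weights(Wm), frame, cfg, steps = 7)
  ref <- oracle_simulate(Wm, st$x, st$y, frame, 0.05, 0, -2, steps = 7)
  for (l in 2:3) expect_equal(got$y[[l]], ref$y[[l]], tolerance = 1e-12)
})

test_that("inference converges and the error trace decreases", {
  cfg <- pcnet_config(area_sizes = c(2, 2), convergence_tol = 1e-6,
                      max_convergence_steps = 3000, activation_offset = 0,
                      reset_rate = 0.3)
  # identity weights make the 0.5-frame perfectly predictable
  W <- wrap_weights(list(diag(2)))
  out <- run_to_convergence(reset_state(cfg), W, c(0.5, 0.5), cfg)
  expect_true(out$converged)
  expect_lt(tail(out$err_trace, 1), 1e-4)
  expect_true(all(diff(out$err_trace) <= 1e-12))   # monotone decrease
  # infinite tolerance returns after a single cycle
  cfg_inf <- pcnet_config(area_sizes = c(2, 2), convergence_tol = Inf)
  out_inf <- run_to_convergence(reset_state(cfg_inf), W, c(0.5, 0.5), cfg_inf)
  expect_identical(out_inf$cycles, 1L)
  expect_length(out_inf$err_trace, 1)
})

test_that("the Hebbian rule is the exact negative weight gradient", {
  ts <- tiny_setup()
  y <- c(list(ts$y0), lapply(ts$x[-1], function(v) logistic(v + ts$dx)))
  # package route
  cfg <- pcnet_config(area_sizes = ts$sizes, learning_rate = 1,
                      activation_offset = ts$dx)
  st <- reset_state(cfg)
  st$y <- y
  st <- compute_errors(st, wrap_weights(ts$W))
  dW <- lapply(seq_along(ts$W), function(l)
    hebbian_update(wrap_weights(ts$W), st, cfg)[[l]] - ts$W[[l]])
  # central finite differences of E = 0.5 * sum ||beta||^2 w.r.t. W
  h <- 1e-5
  for (l in seq_along(ts$W)) {
    grad <- matrix(0, nrow(ts$W[[l]]), ncol(ts$W[[l]]))
    for (i in seq_len(nrow(grad))) for (j in seq_len(ncol(grad))) {
      Wp <- ts$W; Wp[[l]][i, j] <- Wp[[l]][i, j] + h
      Wm <- ts$W; Wm[[l]][i, j] <- Wm[[l]][i, j] - h
      grad[i, j] <- (oracle_objective_W(Wp, y) - oracle_objective_W(Wm, y)) /
        (2 * h)
    }
    expect_equal(dW[[l]], -grad, tolerance = 1e-6)
  }
})

test_that("inference updates share the sign of the negative activity gradient", {
  ts <- tiny_setup(seed = 21)
  cfg <- pcnet_config(area_sizes = ts$sizes, activation_offset = ts$dx)
  st <- reset_state(cfg)
  st$x <- ts$x
  st$y <- c(list(ts$y0), lapply(ts$x[-1], function(v) logistic(v + ts$dx)))
  st <- compute_errors(st, wrap_weights(ts$W))
  h <- 1e-6
  L <- length(ts$W)
  for (l in 2:(L + 1)) {
    drive <- drop(crossprod(ts$W[[l - 1]], st$beta[[l - 1]]))
    if (l <= L) drive <- drive - st$beta[[l]]
    for (j in seq_along(ts$x[[l]])) {
      xp <- ts$x; xp[[l]][j] <- xp[[l]][j] + h
      xm <- ts$x; xm[[l]][j] <- xm[[l]][j] - h
      g <- (oracle_objective_x(ts$W, xp, ts$y0, ts$dx) -
              oracle_objective_x(ts$W, xm, ts$y0, ts$dx)) / (2 * h)
      if (abs(g) > 1e-8 && abs(drive[j]) > 1e-8)
        expect_identical(sign(drive[j]), -sign(g))
    }
  }
})

test_that("identical seeds and inputs give bit-identical trajectories", {
  cfg <- pcnet_config(area_sizes = c(4, 3, 2), cycles_per_frame = 3)
  W <- init_weights(cfg, seed = 9)
  frame <- c(0.1, 0.9, 0.4, 0.2)
  a <- run_to_convergence(reset_state(cfg), W, frame, cfg)
  b <- run_to_convergence(reset_state(cfg), W, frame, cfg)
  expect_identical(a$state, b$state)
  expect_identical(a$err_trace, b$err_trace)
})

test_that("the same matrix serves prediction and error routing", {
  cfg <- pcnet_config(area_sizes = c(2, 2))
  W <- wrap_weights(list(matrix(c(0.2, 0.05, 0.1, 0.4), 2, 2)))
  st <- reset_state(cfg)
  st$y[[1]] <- c(0.7, 0.3)
  st <- compute_errors(st, W)
  expect_equal(st$beta[[1]], st$y[[1]] - drop(W[[1]] %*% st$y[[2]]))
  st2 <- update_activations(st, W, cfg)
  expect_equal(st2$x[[2]] - st$x[[2]],
               cfg$inference_rate * drop(t(W[[1]]) %*% st$beta[[1]]))
})

test_that("weights round-trip through the archive with their config sidecar", {
  cfg <- pcnet_config(area_sizes = c(6, 4, 2), learning_rate = 0.02)
  W <- init_weights(cfg, seed = 4)
  path <- tempfile(fileext = ".rds")
  write_weights(W, path, config = cfg)
  back <- read_weights(path)
  expect_equal(lapply(back$weights, unclass), lapply(W, unclass))
  expect_identical(attr(back$weights, "seed"), 4L)
  expect_identical(back$config$area_sizes, cfg$area_sizes)
  expect_equal(back$config$learning_rate, 0.02)
  unlink(c(path, paste0(path, ".json")))
})
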