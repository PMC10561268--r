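test_that("autocorrelation matches its algebra and a naive double loop", {
  # constant activity c gives R = c^2 at every lag
  z <- matrix(0.3, 50, 4)
  for (lag in c(0, 10, 49)) expect_equal(autocorrelation(z, lag), 0.09)
  expect_equal(autocorrelation(matrix(0, 20, 3), 5), 0)
  # hand-computed scalar example: (1*2 + 2*3) / 2
  expect_equal(autocorrelation(matrix(c(1, 2, 3), ncol = 1), 1), 4)
  expect_equal(autocorrelation(matrix(c(1, 2, 3), ncol = 1), 0),
               (1 + 4 + 9) / 3)
  # vectorized implementation vs naive double loop
  set.seed(3)
  zr <- matrix(rnorm(40 * 5), 40, 5)
  for (lag in c(0, 1, 7, 20)) {
    naive <- 0
    for (t in seq_len(40 - lag))
      for (n in 1:5) naive <- naive + zr[t, n] * zr[t + lag, n]
    naive <- naive / (5 * (40 - lag))
    expect_equal(autocorrelation(zr, lag), naive, tolerance = 1e-10)
  }
  expect_error(autocorrelation(zr, 40), "lag")
  expect_error(autocorrelation(zr, -1), "lag")
})

test_that("decay constants recover exponential and extrapolated timescales", {
  # densely sampled exponential: recovered within one lag sample
  tau0 <- 370
  lags <- seq(0, 5000, by = 10)
  R <- exp(-lags / tau0)
  attr(R, "lags") <- lags
  dc <- decay_constant(R)
  expect_false(dc$censored)
  expect_lt(abs(dc$tau - tau0), 10)
  # constant curve never decays: censored at the cap
  Rc <- rep(2, 11); attr(Rc, "lags") <- seq(0, 100, by = 10)
  dcc <- decay_constant(Rc)
  expect_true(dcc$censored)
  expect_equal(dcc$tau, 1000)
  # line-crossing algebra: R(0)=1, R(T)=0.5 without an in-range crossing
  Tend <- 6000
  lags2 <- seq(0, Tend, by = 100)
  R2 <- 1 - 0.5 * lags2 / Tend
  attr(R2, "lags") <- lags2
  dc2 <- decay_constant(R2)
  expect_false(dc2$censored)
  expect_equal(dc2$tau, Tend * (1 - exp(-1)) / 0.5, tolerance = 1e-10)
  expect_error(decay_constant(c(0, 1, 2)), "positive")
})

test_that("activity recording has the stated shape and fixed-point behavior", {
  cfg <- pcnet_config(area_sizes = c(16, 8, 4), cycles_per_frame = 30,
                      inference_steps_per_cycle = 10)
  W <- init_weights(cfg, 2)
  frames <- array(rep(runif(16), 4), c(4, 4, 4))     # constant frame
  sq <- pcnet:::new_sequence(frames)
  tr <- record_activity(W, sq, population = "RN", area = 2, config = cfg)
  expect_identical(dim(tr$z), c(4L * 30L, 4L))       # frames*cycles x neurons
  expect_identical(tr$T, 4L * 30L * 10L)
  # a network with a reachable fixed point settles on a constant frame:
  # identity weights let the hidden rates converge onto the frame
  cfg_id <- pcnet_config(area_sizes = c(16, 16), cycles_per_frame = 120)
  W_id <- wrap_weights(list(diag(16)))
  set.seed(4)
  const <- array(rep(runif(16, 0.2, 0.8), 3), c(4, 4, 3))
  tr_id <- record_activity(W_id, pcnet:::new_sequence(const),
                           population = "RN", area = 1, config = cfg_id)
  n <- nrow(tr_id$z)
  expect_lt(max(abs(tr_id$z[n, ] - tr_id$z[n - 1, ])), 1e-6)
  expect_lt(max(abs(tr_id$z[n, ] - as.numeric(const[, , 1]))), 0.01)
  tr2 <- record_activity(W, sq, population = "RN", area = 2, config = cfg)
  expect_identical(tr$z, tr2$z)                      # deterministic
  en <- record_activity(W, sq, population = "EN", area = 0, config = cfg)
  expect_identical(ncol(en$z), 16L)
  expect_error(record_activity(W, sq, population = "EN", area = 2,
                               config = cfg), "no error population")
  expect_error(record_activity(W, sq, population = "RN", area = 0,
                               config = cfg), "areas 1")
})

test_that("the timescale experiment tabulates all populations and speeds", {
  cfg <- pcnet_config(area_sizes = c(16, 8, 6, 4), cycles_per_frame = 8)
  seqs <- lapply(0:1, function(cl) {
    set.seed(cl + 50)
    pcnet:::new_sequence(array(runif(16 * 3), c(4, 4, 3)), label = cl)
  })
  ds <- structure(list(sequences = seqs, n_classes = 2L,
                       image_shape = c(4L, 4L)), class = "pcnet_dataset")
  fits <- lapply(1:2, function(s) {
    f <- list(weights = init_weights(cfg, s), config = cfg, seed = s)
    class(f) <- "pcnet"
    f
  })
  tab <- timescale_experiment(fits, ds, speeds = c(1, 2))
  expect_identical(nrow(tab), 6L * 2L * 2L)          # populations x speeds x seeds
  expect_identical(sort(unique(tab$speed)), c(1, 2))
  expect_true(all(tab$tau > 0))
  expect_identical(sum(tab$population == "RN"), 3L * 2L * 2L)
})

test_that("Welch ANOVA and Games-Howell match textbook computations", {
  taus <- data.frame(
    population = rep(c("RN", "EN"), each = 4),
    area = rep(c(1, 1), each = 4),
    speed = 1,
    seed = rep(1:4, 2),
    tau = c(10.1, 9.9, 10.05, 9.95, 0.1, -0.1, 0.05, -0.05) + 0,
    censored = FALSE)
  taus$tau <- taus$tau + c(rep(0, 4), rep(0, 4))
  out <- timescale_stats(taus, speed = 1)
  expect_lt(out$anova$p, 0.01)
  pw <- out$pairwise
  expect_identical(nrow(pw), 1L)
  expect_equal(abs(pw$diff), 10, tolerance = 0.01)
  # textbook Games-Howell: Welch SE, Satterthwaite df, studentized range
  a <- taus$tau[taus$population == "EN"]; b <- taus$tau[taus$population == "RN"]
  se2 <- var(a) / 4 + var(b) / 4
  df <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_ref <- ptukey(abs(mean(a) - mean(b)) / sqrt(se2) * sqrt(2),
                  nmeans = 2, df = df, lower.tail = FALSE)
  expect_equal(pw$p, p_ref, tolerance = 1e-12)
  expect_lt(pw$p, 0.01)
})

test_that("timescale statistics cover all pairs and flag equal groups", {
  taus <- expand.grid(seed = 1:4, population = c("RN", "EN"), area = 1:3)
  taus$speed <- 1
  # every group carries the identical set of observations
  taus$tau <- rep(c(4.8, 5.2, 4.9, 5.1), times = 6)
  taus$censored <- FALSE
  out <- timescale_stats(taus, speed = 1)
  expect_equal(nrow(out$pairwise), choose(6, 2))     # 15 comparisons
  expect_gt(out$anova$p, 0.99)
  expect_equal(out$pairwise$diff, rep(0, 15))
  expect_true(all(out$pairwise$p > 0.99, na.rm = TRUE))
  expect_error(timescale_stats(taus[taus$seed == 1, ], speed = 1), ">= 2")
})
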