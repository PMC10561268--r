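#' Record subpopulation activity during a sequence
#'
#' Presents the sequence continuously (one reset at the start, activity
#' carried across frames) to a network with frozen weights, recording
#' the chosen area's representation-neuron rates (`"RN"`) or
#' error-neuron activity (`"EN"`), block-averaged over each cycle of
#' `inference_steps_per_cycle` inference steps.
#'
#' @param object A `pcnet` fit or `pcnet_weights`.
#' @param sequence A `pcnet_sequence`.
#' @param population `"RN"` (rates; areas 1..L) or `"EN"` (errors; areas
#'   0..L-1 - the top area has no error population).
#' @param area Area index.
#' @param config Configuration when `object` is a bare weight set; pass a
#'   speed-adjusted configuration (see [set_speed()]) to change the
#'   stimulus timescale.
#' @return An object of class `pcnet_trace`: list with `z` (matrix, time
#'   blocks x neurons), `population`, `area`, `block` (inference steps
#'   per block) and `T` (total inference steps).
#' @export
record_activity <- function(object, sequence, population = c("RN", "EN"),
                            area = 1, config = NULL) {
  population <- match.arg(population)
  rw <- resolve_weights(object, config)
  cfg <- rw$config
  L <- length(cfg$area_sizes) - 1L
  if (population == "EN" && (area < 0 || area > L - 1))
    stop("the top area has no error population; EN areas are 0..", L - 1,
         call. = FALSE)
  if (population == "RN" && (area < 1 || area > L))
    stop("RN recording covers areas 1..", L, call. = FALSE)
  st <- reset_state(cfg)
  out <- cpp_run_frames(unclass(rw$weights), st$x, st$y,
                        sequence_matrix(sequence),
                        cfg$inference_rate, 0, cfg$activation_offset,
                        cfg$inference_steps_per_cycle, cfg$cycles_per_frame,
                        record = TRUE, record_area = as.integer(area),
                        record_error = population == "EN")
  steps <- cfg$inference_steps_per_cycle
  structure(list(z = out$record, population = population, area = area,
                 block = steps,
                 T = n_frames(sequence) * cfg$cycles_per_frame * steps),
            class = "pcnet_trace")
}

#' @export
print.pcnet_trace <- function(x, ...) {
  cat("pcnet activity trace: ", x$population, " area ", x$area, ", ",
      nrow(x$z), " blocks of ", x$block, " steps x ", ncol(x$z),
      " neurons\n", sep = "")
  invisible(x)
}

#' Un-centred activity autocorrelation
#'
#' `R(z, lag) = 1/(N (T - lag)) * sum_t z(t) . z(t + lag)`, the average
#' per-neuron dot product between the activity vector and its lagged
#' copy, with no mean subtraction. High values indicate similar,
#' non-zero activity across the lag and thus high temporal stability.
#'
#' @param trace A `pcnet_trace`, or a plain matrix (time x neurons).
#' @param lag For a `pcnet_trace`: lag in inference steps (a multiple of
#'   the block size). For a matrix: lag in rows.
#' @return The autocorrelation value at that lag.
#' @examples
#' autocorrelation(matrix(c(1, 2, 3), ncol = 1), 1)  # (1*2 + 2*3)/2
#' @export
autocorrelation <- function(trace, lag) {
  if (inherits(trace, "pcnet_trace")) {
    if (lag %% trace$block != 0)
      stop("lag must be a multiple of the block size (",
           trace$block, " steps)", call. = FALSE)
    z <- trace$z
    ls <- lag / trace$block
  } else {
    z <- as.matrix(trace)
    ls <- lag
  }
  Ts <- nrow(z)
  if (ls < 0 || ls >= Ts)
    stop("lag must satisfy 0 <= lag < T", call. = FALSE)
  N <- ncol(z)
  idx <- seq_len(Ts - ls)
  sum(z[idx, , drop = FALSE] * z[idx + ls, , drop = FALSE]) / (N * (Ts - ls))
}

#' Full autocorrelation curve of a trace
#'
#' @param trace A `pcnet_trace` or matrix (time x neurons).
#' @return A numeric vector `R` over all available lags (0, block,
#'   2*block, ... in inference steps), with the lags as an attribute.
#' @export
autocorrelation_curve <- function(trace) {
  z <- if (inherits(trace, "pcnet_trace")) trace$z else as.matrix(trace)
  block <- if (inherits(trace, "pcnet_trace")) trace$block else 1L
  Ts <- nrow(z)
  R <- vapply(seq_len(Ts) - 1L, function(ls) autocorrelation(z, ls), 0)
  attr(R, "lags") <- (seq_len(Ts) - 1L) * block
  R
}

#' Decay constant of an autocorrelation curve
#'
#' The intrinsic-timescale proxy: the lag at which `R` first decays to
#' `1/e` of its zero-lag value, linearly interpolated between lag
#' samples. If the curve never reaches `1/e` within the sequence, a
#' linear continuation through the first and last samples is solved for
#' the crossing; if that line does not decay (slope >= 0), the estimate
#' is censored at `cap`.
#'
#' @param R_curve Autocorrelation values over equally spaced lags
#'   starting at 0 (as from [autocorrelation_curve()]); `R_curve[1]` must
#'   be positive.
#' @param block Lag spacing in inference steps (taken from the curve's
#'   `lags` attribute when present).
#' @param cap Value assigned to censored estimates (default `10 * T`).
#' @return A list with `tau` (inference steps) and `censored`.
#' @export
decay_constant <- function(R_curve, block = NULL, cap = NULL) {
  lags <- attr(R_curve, "lags")
  if (is.null(lags)) {
    if (is.null(block)) block <- 1
    lags <- (seq_along(R_curve) - 1) * block
  }
  R0 <- R_curve[1]
  if (!is.finite(R0) || R0 <= 0)
    stop("R(0) must be positive", call. = FALSE)
  Tlast <- lags[length(lags)]
  if (is.null(cap)) cap <- 10 * Tlast
  target <- R0 / exp(1)
  ratio <- R_curve / R0
  below <- which(ratio <= exp(-1))
  if (length(below)) {
    i <- below[1]
    if (i == 1) return(list(tau = 0, censored = FALSE))
    # linear interpolation between the bracketing lag samples
    tau <- lags[i - 1] + (lags[i] - lags[i - 1]) *
      (R_curve[i - 1] - target) / (R_curve[i - 1] - R_curve[i])
    return(list(tau = tau, censored = FALSE))
  }
  slope <- (R_curve[length(R_curve)] - R0) / Tlast
  if (slope >= 0) return(list(tau = cap, censored = TRUE))
  list(tau = (target - R0) / slope, censored = FALSE)
}

#' Timescale hierarchy experiment
#'
#' For every fitted network (seed), stimulus speed, and subpopulation
#' (representation neurons of areas 1..L, error neurons of areas
#' 0..L-1), runs every sequence of the dataset continuously, averages
#' the autocorrelation curves across sequences, and extracts the decay
#' constant. Speed `s` divides the number of inference cycles per frame
#' by `s`.
#'
#' @param fits A `pcnet` fit or a list of fits (one per seed).
#' @param dataset A `pcnet_dataset` (rotation sequences in the standard
#'   experiment).
#' @param speeds Numeric vector of stimulus speeds.
#' @return A data frame with columns `population`, `area`, `speed`,
#'   `seed`, `tau`, `censored`.
#' @export
timescale_experiment <- function(fits, dataset, speeds = c(1, 2, 4)) {
  if (inherits(fits, "pcnet")) fits <- list(fits)
  L <- length(fits[[1]]$config$area_sizes) - 1L
  combos <- rbind(data.frame(population = "RN", area = seq_len(L)),
                  data.frame(population = "EN", area = seq_len(L) - 1L))
  out <- list()
  for (fit in fits) {
    for (sp in speeds) {
      cfg <- set_speed(fit$config, sp)
      for (i in seq_len(nrow(combos))) {
        curves <- lapply(dataset$sequences, function(sq) {
          tr <- record_activity(fit$weights, sq,
                                population = combos$population[i],
                                area = combos$area[i], config = cfg)
          autocorrelation_curve(tr)
        })
        Rbar <- Reduce(`+`, curves) / length(curves)
        attr(Rbar, "lags") <- attr(curves[[1]], "lags")
        dc <- decay_constant(Rbar)
        out[[length(out) + 1L]] <- data.frame(
          population = combos$population[i], area = combos$area[i],
          speed = sp, seed = fit$seed, tau = dc$tau, censored = dc$censored)
      }
    }
  }
  do.call(rbind, out)
}

#' Welch ANOVA and Games-Howell comparison of decay constants
#'
#' Tests whether the six (population, area) groups differ in their decay
#' constants with a Welch ANOVA (no equal-variance assumption), followed
#' by pairwise Games-Howell post-hoc tests (the unequal-variance
#' extension of Tukey's test: Welch standard errors, Satterthwaite
#' degrees of freedom, studentized-range reference distribution).
#'
#' @param taus Data frame as returned by [timescale_experiment()].
#' @param speed Which stimulus speed to analyse (default 1).
#' @param drop_censored Exclude censored estimates (default `TRUE`)?
#' @return A list with `anova` (F statistic, df, p value) and `pairwise`
#'   (one row per group pair: mean difference, SE, df, p value).
#' @export
timescale_stats <- function(taus, speed = 1, drop_censored = TRUE) {
  d <- taus[taus$speed == speed, ]
  if (drop_censored) d <- d[!d$censored, ]
  d$group <- paste0(d$population, d$area)
  tab <- table(d$group)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  aov_w <- oneway.test(tau ~ group, data = d, var.equal = FALSE)
  groups <- names(tab)
  k <- length(groups)
  stats <- lapply(groups, function(g) {
    v <- d$tau[d$group == g]
    list(m = mean(v), s2 = stats::var(v), n = length(v))
  })
  names(stats) <- groups
  pairs <- utils::combn(groups, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- stats[[pairs[1, j]]]; b <- stats[[pairs[2, j]]]
    se2 <- a$s2 / a$n + b$s2 / b$n
    se <- sqrt(se2)
    df <- se2^2 / ((a$s2 / a$n)^2 / (a$n - 1) + (b$s2 / b$n)^2 / (b$n - 1))
    diff <- a$m - b$m
    tstat <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p <- if (is.infinite(tstat)) 0 else
      suppressWarnings(ptukey(tstat * sqrt(2), nmeans = k, df = df,
                              lower.tail = FALSE))
    if (is.nan(p)) p <- NA_real_   # studentized range undefined at tiny df
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               diff = diff, se = se, df = df, p = p)
  }))
  list(anova = list(statistic = unname(aov_w$statistic),
                    df = unname(aov_w$parameter),
                    p = unname(aov_w$p.value)),
       pairwise = pw)
}
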