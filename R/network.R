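#' Initialize the symmetric weight set
#'
#' Draws every entry of each inter-area matrix from a zero-mean Gaussian
#' with standard deviation 0.5, clips at zero to prevent negative weights,
#' and divides by the number of neurons in the next (higher) area. The
#' same matrix `W_l` generates the top-down prediction `W_l %*% y_{l+1}`
#' and routes bottom-up errors through its transpose, so feedforward and
#' feedback weights are symmetric by construction.
#'
#' @param config A [pcnet_config()].
#' @param seed Integer seed; identical seeds give identical weights.
#' @return An object of class `pcnet_weights`: a list of L matrices, the
#'   l-th of dimension `area_sizes[l] x area_sizes[l+1]`.
#' @examples
#' W <- init_weights(pcnet_config(area_sizes = c(4, 3)), seed = 1)
#' dim(W[[1]]); all(W[[1]] >= 0)
#' @export
init_weights <- function(config, seed = config$seed) {
  validate_config(config)
  s <- config$area_sizes
  L <- length(s) - 1L
  W <- with_seed(seed, lapply(seq_len(L), function(l) {
    g <- matrix(rnorm(s[l] * s[l + 1], mean = 0, sd = 0.5), s[l], s[l + 1])
    pmax(g, 0) / s[l + 1]  # note: pmax(g, 0), not pmax(0, g) -- keeps dim
  }))
  structure(W, class = "pcnet_weights", seed = as.integer(seed))
}

#' @export
print.pcnet_weights <- function(x, ...) {
  dims <- vapply(x, function(w) paste(dim(w), collapse = "x"), "")
  cat("pcnet weight set:", paste(dims, collapse = ", "),
      " (init seed", attr(x, "seed"), ")\n")
  invisible(x)
}

#' Reset network activity to a uniform low value
#'
#' Installs the uniform low rate `reset_rate` in every area, with the
#' activations set to the unique pre-activation consistent with the rate
#' equation, `x = logit(reset_rate) - activation_offset`, and all error
#' populations at zero. This is the most information-neutral state and is
#' applied at the start of each sequence during training.
#'
#' @param config A [pcnet_config()].
#' @return An object of class `pcnet_state` with fields `x`, `y` (lists of
#'   vectors per area, input area first) and `beta` (one error vector per
#'   predicted area, i.e. all areas but the top one).
#' @examples
#' st <- reset_state(pcnet_config(area_sizes = c(4, 3), reset_rate = 0.5,
#'                                activation_offset = 0))
#' st$x[[2]]  # logit(0.5) - 0 = 0
#' @export
reset_state <- function(config) {
  validate_config(config)
  s <- config$area_sizes
  L <- length(s) - 1L
  x0 <- qlogis(config$reset_rate) - config$activation_offset
  structure(list(
    x = lapply(s, function(n) rep(x0, n)),
    y = lapply(s, function(n) rep(config$reset_rate, n)),
    beta = lapply(s[seq_len(L)], function(n) rep(0, n))
  ), class = "pcnet_state")
}

#' @export
print.pcnet_state <- function(x, ...) {
  cat("pcnet state over", length(x$y), "areas; mean rates:",
      paste(signif(vapply(x$y, mean, 0), 3), collapse = ", "), "\n")
  invisible(x)
}

flatten_frame <- function(frame, n0) {
  v <- as.numeric(frame)
  if (length(v) != n0)
    stop("frame has ", length(v), " pixels; the input area expects ", n0,
         call. = FALSE)
  if (any(v < 0 | v > 1))
    stop("frame values must lie in [0, 1]", call. = FALSE)
  v
}

#' Clamp a stimulus frame to the input area
#'
#' The input-area representation neurons linearly reflect the pixel-wise
#' intensity of the frame: `y_0` is set equal to the flattened frame, with
#' no sigmoid and no rescaling. All other areas are untouched.
#'
#' @param state A `pcnet_state`.
#' @param frame A matrix (or vector) of pixel intensities in \[0, 1\] whose
#'   length equals the input-area size.
#' @return The state with `y[[1]]` replaced.
#' @export
clamp_input <- function(state, frame) {
  stopifnot(inherits(state, "pcnet_state"))
  state$y[[1]] <- flatten_frame(frame, length(state$y[[1]]))
  state
}

#' Compute prediction errors
#'
#' Every predicted area's error population takes the difference between
#' the area's current rates and the top-down prediction from the area
#' above: `beta_l = y_l - W_l %*% y_{l+1}`.
#'
#' @param state A `pcnet_state`.
#' @param weights A `pcnet_weights`.
#' @return The state with all `beta` vectors updated.
#' @export
compute_errors <- function(state, weights) {
  stopifnot(inherits(state, "pcnet_state"))
  L <- length(weights)
  for (l in seq_len(L)) {
    state$beta[[l]] <- state$y[[l]] - drop(weights[[l]] %*% state$y[[l + 1]])
  }
  state
}

#' Update neural activations from freshly computed errors
#'
#' One synchronous inference step: every hidden area moves its activation
#' up the weighted bottom-up errors and down its own error,
#' `x_l <- x_l + eps_inf * (t(W_{l-1}) %*% beta_{l-1} - beta_l)`; the top
#' area has no error population of its own and receives only the
#' bottom-up term. Rates then follow `y_l = sigmoid(x_l + offset)`, so
#' every hidden rate stays strictly inside (0, 1). The input area remains
#' clamped.
#'
#' @param state A `pcnet_state` whose errors were just computed with
#'   [compute_errors()].
#' @param weights A `pcnet_weights`.
#' @param config A [pcnet_config()].
#' @return The updated state.
#' @export
update_activations <- function(state, weights, config) {
  stopifnot(inherits(state, "pcnet_state"))
  L <- length(weights)
  eps <- config$inference_rate
  for (l in seq_len(L) + 1L) {          # R index: areas 1..L (0-based)
    drive <- drop(crossprod(weights[[l - 1]], state$beta[[l - 1]]))
    if (l <= L) drive <- drive - state$beta[[l]]
    state$x[[l]] <- state$x[[l]] + eps * drive
    state$y[[l]] <- sigmoid(state$x[[l]] + config$activation_offset)
  }
  state
}

#' Hebbian weight update
#'
#' Strengthens the synapses between active error neurons in each area and
#' simultaneously active representation neurons in the area above:
#' `W_l <- W_l + eps_learn * beta_l %*% t(y_{l+1})`. No clipping, decay,
#' normalization or gating is applied; a negative error reduces the weight
#' mediating the too-large prediction. This outer-product rule is the
#' exact negative gradient of half the summed squared prediction errors
#' with respect to the weights.
#'
#' @param weights A `pcnet_weights`.
#' @param state A `pcnet_state` with current errors and rates.
#' @param config A [pcnet_config()]; `learning_rate` scales the update.
#' @return The updated weight set.
#' @export
hebbian_update <- function(weights, state, config) {
  stopifnot(inherits(weights, "pcnet_weights"), inherits(state, "pcnet_state"))
  for (l in seq_along(weights)) {
    weights[[l]] <- weights[[l]] +
      config$learning_rate * tcrossprod(state$beta[[l]], state$y[[l + 1]])
  }
  weights
}

# Rewrap raw C++ output into classed containers
as_weights <- function(W, seed = NA_integer_) {
  structure(W, class = "pcnet_weights", seed = as.integer(seed))
}
as_state <- function(st) {
  # the C++ core returns states as n x 1 matrices; store plain vectors
  structure(list(x = lapply(st$x, as.numeric),
                 y = lapply(st$y, as.numeric),
                 beta = lapply(st$beta, as.numeric)),
            class = "pcnet_state")
}

#' Run one or more inference cycles on a clamped frame
#'
#' Clamps the frame to the input area and runs `steps` synchronous
#' error-computation/activation-update iterations. No learning takes
#' place.
#'
#' @param state A `pcnet_state`.
#' @param weights A `pcnet_weights`.
#' @param frame Stimulus frame (matrix or vector in \[0, 1\]).
#' @param config A [pcnet_config()].
#' @param steps Number of inference steps; defaults to one cycle's worth.
#'   `steps = 0` only clamps the input.
#' @return The updated state.
#' @export
inference_cycle <- function(state, weights, frame, config,
                            steps = config$inference_steps_per_cycle) {
  state <- clamp_input(state, frame)
  if (steps == 0) return(state)
  out <- cpp_run_frames(unclass(weights), state$x, state$y,
                        matrix(state$y[[1]], ncol = 1),
                        config$inference_rate, 0, config$activation_offset,
                        as.integer(steps), 1L)
  as_state(out$state)
}

#' Run inference on a frame until the prediction errors settle
#'
#' Repeats inference cycles on the clamped frame until the relative change
#' of the total squared prediction error between consecutive cycles falls
#' below `config$convergence_tol`, or `config$max_convergence_steps`
#' cycles have run. An infinite tolerance returns after a single cycle.
#'
#' @inheritParams inference_cycle
#' @return A list with elements `state` (the converged `pcnet_state`),
#'   `converged` (logical flag), `cycles` (cycles actually run) and
#'   `err_trace` (total squared error after each cycle).
#' @export
run_to_convergence <- function(state, weights, frame, config) {
  state <- clamp_input(state, frame)
  out <- cpp_run_to_convergence(unclass(weights), state$x, state$y,
                                state$y[[1]],
                                config$inference_rate,
                                config$activation_offset,
                                config$inference_steps_per_cycle,
                                config$convergence_tol,
                                config$max_convergence_steps)
  list(state = as_state(out$state), converged = out$converged,
       cycles = out$cycles, err_trace = drop(out$err_trace))
}

total_squared_error <- function(state) {
  sum(vapply(state$beta, function(b) sum(b^2), 0))
}

#' Save / load a fitted network or weight set
#'
#' Writes the weight matrices as a single compressed archive with a JSON
#' sidecar (`<path>.json`) describing the configuration and seed.
#'
#' @param object A `pcnet` fit or `pcnet_weights`.
#' @param path File path for the archive.
#' @param config Configuration to record when `object` is a bare weight
#'   set.
#' @return `write_weights` returns `path` invisibly; `read_weights`
#'   returns a list with elements `weights` and `config`.
#' @export
write_weights <- function(object, path, config = NULL) {
  if (inherits(object, "pcnet")) {
    config <- object$config
    object <- object$weights
  }
  stopifnot(inherits(object, "pcnet_weights"))
  saveRDS(lapply(object, identity), path, compress = "gzip")
  side <- list(seed = attr(object, "seed"),
               config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  W <- as_weights(readRDS(path))
  side_path <- paste0(path, ".json")
  cfg <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(W, "seed") <- side$seed
    if (!is.null(side$config))
      cfg <- do.call(pcnet_config, side$config[names(formals(pcnet_config))[
        names(formals(pcnet_config)) %in% names(side$config)]])
  }
  list(weights = W, config = cfg)
}
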