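#' Network configuration
#'
#' Collects all architectural and numeric hyperparameters of a
#' predictive-coding network. Area 0 is the input area; the network has
#' `length(area_sizes) - 1` hidden areas above it. The defaults follow the
#' reference architecture (28x28 input, areas of 2000, 500 and 30 neurons).
#'
#' @param area_sizes Integer vector of length L+1 (>= 2 entries, all >= 1);
#'   entry 1 is the input area size (number of pixels).
#' @param inference_rate Positive step size of the activity update
#'   (membrane dynamics), applied identically in every area.
#' @param learning_rate Positive step size of the Hebbian weight update.
#' @param activation_offset Constant lateral offset of the firing threshold:
#'   rates are `sigmoid(x + activation_offset)`. Negative values keep
#'   resting rates low.
#' @param inference_steps_per_cycle Number of inference steps between two
#'   Hebbian updates (one "cycle"); also the block length used when
#'   recording block-averaged activity.
#' @param cycles_per_frame Number of inference-learning cycles run on each
#'   stimulus frame during training.
#' @param repetitions Number of times each sequence is repeated within an
#'   epoch before switching to the next sequence.
#' @param reset_rate Uniform low firing rate, strictly in (0, 1), installed
#'   in all areas when activity is reset.
#' @param seed Default integer seed for weight initialization.
#' @param convergence_tol Relative change of the total squared prediction
#'   error between consecutive cycles below which inference on a clamped
#'   frame counts as converged.
#' @param max_convergence_steps Cap on the number of cycles of a
#'   convergence run.
#' @param reset_between_repetitions If `TRUE`, continuous training resets
#'   activity before every repetition of a sequence rather than once per
#'   sequence block.
#' @param decoder_decay Weight-decay regularization of the multinomial
#'   logistic decoder used by [decode_linear()].
#' @param reconstruct_through_phi If `TRUE`, top-down reconstruction passes
#'   intermediate installed activities through the sigmoid; the default
#'   installs the raw linear predictions.
#' @param normalize_occlusion_predictions If `TRUE`, predictions scored in
#'   [occlusion_experiment()] are min-max normalized to \[0, 1\] before the
#'   masked MSE is taken. The default (`FALSE`) scores the raw top-down
#'   prediction; min-max normalization is applied for display only.
#'
#' @return An object of class `pcnet_config` (a validated list).
#' @examples
#' cfg <- pcnet_config(area_sizes = c(64, 20, 10), cycles_per_frame = 5)
#' cfg
#' @export
pcnet_config <- function(area_sizes = c(784, 2000, 500, 30),
                         inference_rate = 0.05,
                         learning_rate = 0.01,
                         activation_offset = -2,
                         inference_steps_per_cycle = 10,
                         cycles_per_frame = 100,
                         repetitions = 10,
                         reset_rate = 0.1,
                         seed = 1L,
                         convergence_tol = 1e-4,
                         max_convergence_steps = 5000,
                         reset_between_repetitions = FALSE,
                         decoder_decay = 1e-4,
                         reconstruct_through_phi = FALSE,
                         normalize_occlusion_predictions = FALSE) {
  cfg <- structure(list(
    area_sizes = as.integer(area_sizes),
    inference_rate = inference_rate,
    learning_rate = learning_rate,
    activation_offset = activation_offset,
    inference_steps_per_cycle = as.integer(inference_steps_per_cycle),
    cycles_per_frame = as.integer(cycles_per_frame),
    repetitions = as.integer(repetitions),
    reset_rate = reset_rate,
    seed = as.integer(seed),
    convergence_tol = convergence_tol,
    max_convergence_steps = as.integer(max_convergence_steps),
    reset_between_repetitions = isTRUE(reset_between_repetitions),
    decoder_decay = decoder_decay,
    reconstruct_through_phi = isTRUE(reconstruct_through_phi),
    normalize_occlusion_predictions = isTRUE(normalize_occlusion_predictions)
  ), class = "pcnet_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  stopifnot(inherits(config, "pcnet_config"))
  s <- config$area_sizes
  if (length(s) < 2 || any(s < 1))
    stop("area_sizes must have >= 2 entries, all >= 1", call. = FALSE)
  if (!is.numeric(config$inference_rate) || config$inference_rate <= 0)
    stop("inference_rate must be > 0", call. = FALSE)
  if (!is.numeric(config$learning_rate) || config$learning_rate < 0)
    stop("learning_rate must be >= 0", call. = FALSE)
  if (!is.numeric(config$reset_rate) ||
      config$reset_rate <= 0 || config$reset_rate >= 1)
    stop("reset_rate must lie strictly in (0, 1)", call. = FALSE)
  if (config$inference_steps_per_cycle < 1 || config$cycles_per_frame < 1 ||
      config$repetitions < 1 || config$max_convergence_steps < 1)
    stop("step, cycle and repetition counts must be positive integers",
         call. = FALSE)
  if (!is.numeric(config$convergence_tol) || config$convergence_tol <= 0)
    stop("convergence_tol must be > 0", call. = FALSE)
  invisible(config)
}

#' @export
print.pcnet_config <- function(x, ...) {
  cat("Predictive-coding network configuration\n")
  cat("  areas (input ->", length(x$area_sizes) - 1L, "hidden):",
      paste(x$area_sizes, collapse = " - "), "\n")
  cat("  inference rate:", x$inference_rate,
      " learning rate:", x$learning_rate,
      " activation offset:", x$activation_offset, "\n")
  cat("  steps/cycle:", x$inference_steps_per_cycle,
      " cycles/frame:", x$cycles_per_frame,
      " repetitions:", x$repetitions, "\n")
  cat("  reset rate:", x$reset_rate,
      " convergence tol:", x$convergence_tol,
      " (cap", x$max_convergence_steps, "cycles)\n")
  invisible(x)
}

#' Adjust the stimulus timescale of a configuration
#'
#' Varies the stimulus timescale by dividing the number of inference
#' cycles spent on each frame by the transformation speed, so that a
#' speed-2 stimulus receives half as many inference steps per frame.
#'
#' @param config A [pcnet_config()].
#' @param speed Positive speed factor (>= 1 in the experiments).
#' @return The configuration with `cycles_per_frame` divided by `speed`
#'   (rounded, floor 1).
#' @examples
#' set_speed(pcnet_config(area_sizes = c(4, 2)), 2)$cycles_per_frame
#' @export
set_speed <- function(config, speed) {
  validate_config(config)
  if (!is.numeric(speed) || length(speed) != 1 || speed <= 0)
    stop("speed must be a positive number", call. = FALSE)
  config$cycles_per_frame <-
    max(1L, as.integer(round(config$cycles_per_frame / speed)))
  config
}
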