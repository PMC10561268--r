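#' Train a network on continuous transformation sequences
#'
#' The continuous paradigm: per epoch, each sequence is visited in turn;
#' activity is reset to the uniform low state once at the start of the
#' sequence's repetition block (optionally before every repetition), the
#' sequence is then repeated `config$repetitions` times, and within each
#' pass every frame receives `cycles_per_frame` inference-learning cycles
#' (`inference_steps_per_cycle` inference steps followed by one Hebbian
#' update). Activity carries over between frames and repetitions, so the
#' previous representation acts as a temporal prior for the next frame.
#'
#' @param dataset A `pcnet_dataset` (or list with a `sequences` field).
#' @param config A [pcnet_config()].
#' @param epochs Number of epochs (one epoch = one iteration through all
#'   sequences).
#' @param seed Integer seed for the weight initialization.
#' @param weights Optional `pcnet_weights` to continue training from; when
#'   supplied, `seed` is ignored.
#' @return A list with `weights` (the trained `pcnet_weights`) and
#'   `history` (a data frame with one row per epoch: total squared
#'   prediction error summed over all cycles of the epoch, per-area error
#'   sums, Hebbian update count and reset count).
#' @seealso [pcnet()] for the user-facing fit interface.
#' @export
train_continuous <- function(dataset, config, epochs = 10,
                             seed = config$seed, weights = NULL) {
  train_loop(dataset, config, epochs, seed, weights, static = FALSE)
}

#' Train a network on the static frames of the sequences
#'
#' Identical loop structure to [train_continuous()], but activity is
#' reset before every frame, removing all temporal carry-over. This is
#' the control paradigm: the same images are seen the same number of
#' times, but no temporal continuity links them.
#'
#' @inheritParams train_continuous
#' @return As [train_continuous()].
#' @export
train_static <- function(dataset, config, epochs = 10,
                         seed = config$seed, weights = NULL) {
  train_loop(dataset, config, epochs, seed, weights, static = TRUE)
}

train_loop <- function(dataset, config, epochs, seed, weights, static) {
  validate_config(config)
  seqs <- dataset$sequences
  if (length(seqs) == 0) stop("dataset is empty", call. = FALSE)
  if (is.null(weights)) weights <- init_weights(config, seed)
  W <- unclass(weights)
  L <- length(W)
  eps_i <- config$inference_rate
  eps_l <- config$learning_rate
  dx <- config$activation_offset
  steps <- config$inference_steps_per_cycle
  cycles <- config$cycles_per_frame
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    err_sum <- 0; err_area <- numeric(L); n_upd <- 0L; n_resets <- 0L
    for (sq in seqs) {
      frames <- sequence_matrix(sq)
      st <- reset_state(config); n_resets <- n_resets + 1L
      for (rep in seq_len(config$repetitions)) {
        if (rep > 1L && !static && config$reset_between_repetitions) {
          st <- reset_state(config); n_resets <- n_resets + 1L
        }
        if (static) {
          for (f in seq_len(ncol(frames))) {
            if (!(rep == 1L && f == 1L)) {          # first reset already done
              st <- reset_state(config); n_resets <- n_resets + 1L
            }
            out <- cpp_run_frames(W, st$x, st$y, frames[, f, drop = FALSE],
                                  eps_i, eps_l, dx, steps, cycles)
            W <- out$weights; st$x <- out$state$x; st$y <- out$state$y
            err_sum <- err_sum + out$err_sum
            err_area <- err_area + drop(out$err_area)
            n_upd <- n_upd + out$n_updates
          }
        } else {
          out <- cpp_run_frames(W, st$x, st$y, frames,
                                eps_i, eps_l, dx, steps, cycles)
          W <- out$weights; st$x <- out$state$x; st$y <- out$state$y
          err_sum <- err_sum + out$err_sum
          err_area <- err_area + drop(out$err_area)
          n_upd <- n_upd + out$n_updates
        }
      }
    }
    row <- data.frame(epoch = ep, total_sq_error = err_sum,
                      n_updates = n_upd, n_resets = n_resets)
    for (l in seq_len(L)) row[[paste0("err_area", l - 1L)]] <- err_area[l]
    hist[[ep]] <- row
  }
  list(weights = as_weights(W, seed), history = do.call(rbind, hist))
}

#' Fit a predictive-coding network to a stimulus dataset
#'
#' The main fitting function. Initializes the symmetric weight set from
#' `seed`, trains it on the dataset under the continuous or static
#' paradigm, and returns a classed fit object for use with the analysis
#' functions and standard methods (`print`, `summary`, `coef`, `plot`,
#' `predict`, `residuals`, `simulate`).
#'
#' Learning is active only during this call; every analysis run on the
#' returned object uses frozen weights.
#'
#' @param dataset A `pcnet_dataset` from [make_dataset()] (or assembled
#'   manually from `pcnet_sequence` objects).
#' @param config A [pcnet_config()]; its `area_sizes[1]` must equal the
#'   number of pixels per frame.
#' @param paradigm `"continuous"` (activity carried across frames) or
#'   `"static"` (reset before every frame).
#' @param epochs Number of training epochs.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `pcnet` with components `weights`, `config`,
#'   `history`, `paradigm`, `epochs`, `seed`, `n_classes`, `image_shape`
#'   and `call`.
#' @examples
#' ds <- make_dataset(2, "translate", shape = c(16, 16))
#' cfg <- pcnet_config(area_sizes = c(256, 40, 10), cycles_per_frame = 2,
#'                     repetitions = 2)
#' fit <- pcnet(ds, cfg, epochs = 1)
#' fit
#' @export
pcnet <- function(dataset, config = pcnet_config(),
                  paradigm = c("continuous", "static"),
                  epochs = 10, seed = config$seed) {
  paradigm <- match.arg(paradigm)
  d <- dim(dataset$sequences[[1]]$frames)
  if (prod(d[1:2]) != config$area_sizes[1])
    stop("config expects ", config$area_sizes[1], " input pixels but frames have ",
         prod(d[1:2]), call. = FALSE)
  res <- if (paradigm == "continuous")
    train_continuous(dataset, config, epochs, seed)
  else train_static(dataset, config, epochs, seed)
  structure(list(weights = res$weights, config = config,
                 history = res$history, paradigm = paradigm,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 n_classes = dataset$n_classes,
                 image_shape = dataset$image_shape %||% d[1:2],
                 transform = dataset$sequences[[1]]$transform,
                 call = match.call()),
            class = "pcnet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
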