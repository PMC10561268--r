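#' @export
print.pcnet <- function(x, ...) {
  cat("Predictive-coding network fit (", x$paradigm, " paradigm)\n", sep = "")
  cat("  areas:", paste(x$config$area_sizes, collapse = " - "),
      "  epochs:", x$epochs, "  seed:", x$seed, "\n")
  n <- nrow(x$history)
  cat("  total squared prediction error: ",
      signif(x$history$total_sq_error[1], 4), " (epoch 1) -> ",
      signif(x$history$total_sq_error[n], 4), " (epoch ", n, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.pcnet <- function(object, ...) {
  h <- object$history
  s <- list(paradigm = object$paradigm,
            area_sizes = object$config$area_sizes,
            epochs = object$epochs,
            seed = object$seed,
            n_classes = object$n_classes,
            transform = object$transform,
            error_first = h$total_sq_error[1],
            error_last = h$total_sq_error[nrow(h)],
            n_updates_per_epoch = h$n_updates[1],
            weight_range = range(unlist(lapply(object$weights, range))))
  class(s) <- "summary.pcnet"
  s
}

#' @export
print.summary.pcnet <- function(x, ...) {
  cat("Predictive-coding network (", x$paradigm, " paradigm)\n", sep = "")
  cat("  areas:", paste(x$area_sizes, collapse = " - "), "\n")
  cat("  trained", x$epochs, "epochs on", x$n_classes,
      x$transform, "sequences (seed", paste0(x$seed, ")\n"))
  cat("  Hebbian updates per epoch:", x$n_updates_per_epoch, "\n")
  cat("  total squared error: ", signif(x$error_first, 4), " -> ",
      signif(x$error_last, 4),
      sprintf(" (%.1f%% of initial)\n", 100 * x$error_last / x$error_first),
      sep = "")
  cat("  weight range:", paste(signif(x$weight_range, 3), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
coef.pcnet <- function(object, ...) object$weights

#' Training-error curve of a fitted network
#'
#' Plots the implicit objective - the total squared prediction error
#' accumulated over each epoch - against the epoch number.
#'
#' @param x A `pcnet` fit.
#' @param log Plot the error on a log scale? (default `TRUE`)
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pcnet <- function(x, log = TRUE, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$total_sq_error, type = "b", pch = 16,
                 log = if (log) "y" else "",
                 xlab = "epoch", ylab = "total squared prediction error",
                 main = paste0("pcnet training (", x$paradigm, ")"), ...)
  invisible(x)
}

#' Converged representations or reconstructions for new stimuli
#'
#' With `type = "representation"` (default), runs inference to
#' convergence on every frame of `newdata` from the reset state and
#' returns the rate vectors of the chosen area (a representation matrix,
#' as used for RDMs and decoding). With `type = "reconstruction"`,
#' additionally propagates each converged representation back down to the
#' input area through the top-down weights and returns the reconstructed
#' images.
#'
#' @param object A `pcnet` fit.
#' @param newdata A `pcnet_dataset` or `pcnet_sequence`.
#' @param area Area index (0 = input, default the top area).
#' @param type `"representation"` or `"reconstruction"`.
#' @param ... Unused.
#' @return A `pcnet_reps` object, or for reconstructions a list of image
#'   matrices with per-frame MSE attribute.
#' @export
predict.pcnet <- function(object, newdata, area = NULL,
                          type = c("representation", "reconstruction"), ...) {
  type <- match.arg(type)
  L <- length(object$config$area_sizes) - 1L
  if (is.null(area)) area <- L
  if (inherits(newdata, "pcnet_sequence"))
    newdata <- structure(list(sequences = list(newdata),
                              n_classes = 1L,
                              image_shape = dim(newdata$frames)[1:2]),
                         class = "pcnet_dataset")
  reps <- infer_representations(object, newdata, area = area)
  if (type == "representation") return(reps)
  imgs <- lapply(seq_len(nrow(reps$reps)), function(i)
    topdown_reconstruct(object, reps$reps[i, ], source_area = area)$image)
  imgs
}

#' Input-level prediction errors of a fitted network
#'
#' Runs inference to convergence on every frame of the dataset and
#' returns the remaining input-area prediction errors
#' `y_0 - W_0 %*% y_1`, one row per frame. These residuals are what the
#' Hebbian rule could not explain away with the learned generative model.
#'
#' @param object A `pcnet` fit.
#' @param dataset A `pcnet_dataset`; frames are presented individually.
#' @param ... Unused.
#' @return A matrix (frames x input pixels) of converged errors.
#' @export
residuals.pcnet <- function(object, dataset, ...) {
  cfg <- object$config
  out <- lapply(dataset$sequences, function(sq) {
    frames <- sequence_matrix(sq)
    t(vapply(seq_len(ncol(frames)), function(f) {
      conv <- run_to_convergence(reset_state(cfg), object$weights,
                                 frames[, f], cfg)
      conv$state$beta[[1]]
    }, numeric(cfg$area_sizes[1])))
  })
  do.call(rbind, out)
}

#' Sample images from the learned generative model
#'
#' Draws random top-area rate vectors (uniform in (0, 1)) and propagates
#' each through the top-down pathway to the input area, giving one
#' generated image per draw.
#'
#' @param object A `pcnet` fit.
#' @param nsim Number of images to generate.
#' @param seed Optional seed for the draws.
#' @param ... Unused.
#' @return A list of `nsim` image matrices (min-max normalized).
#' @export
simulate.pcnet <- function(object, nsim = 1, seed = NULL, ...) {
  s <- object$config$area_sizes
  n_top <- s[length(s)]
  draw <- function() {
    y_top <- runif(n_top)
    topdown_reconstruct(object, y_top,
                        source_area = length(s) - 1L)$normalized
  }
  if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
}
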