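#' Top-down reconstruction from a representation
#'
#' Propagates a representation from a source area back down to the input
#' area through the top-down weights: area by area, the rates of the
#' area below are installed by the descending prediction
#' `y_l <- W_l %*% y_{l+1}` (raw linear predictions by default; with
#' `reconstruct_through_phi` in the configuration the intermediate
#' installed activities pass through the sigmoid). The cascade is linear
#' in the source representation in the default mode.
#'
#' @param object A `pcnet` fit or `pcnet_weights`.
#' @param representation Rate vector of length `area_sizes[source_area]`.
#' @param source_area Area the representation lives in (1..L).
#' @param config Configuration when `object` is a bare weight set.
#' @param shape Optional `c(H, W)` to reshape the output (taken from a
#'   fit automatically).
#' @return A list with `image` (raw prediction, reshaped when the shape
#'   is known) and `normalized` (min-max normalized copy for display).
#' @export
topdown_reconstruct <- function(object, representation, source_area,
                                config = NULL, shape = NULL) {
  rw <- resolve_weights(object, config)
  cfg <- rw$config
  L <- length(cfg$area_sizes) - 1L
  if (source_area < 1 || source_area > L)
    stop("source_area must be in 1..", L, call. = FALSE)
  if (length(representation) != cfg$area_sizes[source_area + 1L])
    stop("representation length ", length(representation),
         " does not match area ", source_area, " size ",
         cfg$area_sizes[source_area + 1L], call. = FALSE)
  if (is.null(shape) && inherits(object, "pcnet")) shape <- object$image_shape
  y <- as.numeric(representation)
  for (l in seq(source_area - 1L, 0L)) {
    y <- drop(rw$weights[[l + 1L]] %*% y)
    if (cfg$reconstruct_through_phi && l > 0)
      y <- sigmoid(y + cfg$activation_offset)
  }
  img <- if (!is.null(shape)) matrix(y, shape[1], shape[2]) else y
  norm <- if (!is.null(shape)) matrix(minmax_normalize(y), shape[1], shape[2])
          else minmax_normalize(y)
  list(image = img, normalized = norm)
}

#' Reconstruct an input after blanking it out
#'
#' Presents a static frame until network activity converges, blanks the
#' input, and regenerates it from the converged representation of a
#' selected area through the top-down pathway. The MSE against the
#' original frame is computed on the raw (unnormalized) pixel scale.
#'
#' @param object A `pcnet` fit or `pcnet_weights`.
#' @param frame Stimulus frame (matrix in \[0, 1\]).
#' @param source_area Area to reconstruct from (1..L).
#' @param config Configuration when `object` is a bare weight set.
#' @return An object of class `pcnet_reconstruction`: list with
#'   `reconstruction` (raw), `normalized`, `mse`, `source_area` and
#'   `converged`.
#' @export
reconstruct_after_blanking <- function(object, frame, source_area,
                                       config = NULL) {
  rw <- resolve_weights(object, config)
  cfg <- rw$config
  conv <- run_to_convergence(reset_state(cfg), rw$weights, frame, cfg)
  rep_vec <- conv$state$y[[source_area + 1L]]
  shape <- if (is.matrix(frame)) dim(frame)
           else if (inherits(object, "pcnet")) object$image_shape
  rec <- topdown_reconstruct(rw$weights, rep_vec, source_area,
                             config = cfg, shape = shape)
  structure(list(reconstruction = rec$image, normalized = rec$normalized,
                 mse = mean((as.numeric(rec$image) - as.numeric(frame))^2),
                 source_area = source_area, converged = conv$converged),
            class = "pcnet_reconstruction")
}

#' @export
print.pcnet_reconstruction <- function(x, ...) {
  cat("top-down reconstruction from area ", x$source_area,
      ": MSE ", signif(x$mse, 4),
      if (!x$converged) " (inference not converged)", "\n", sep = "")
  invisible(x)
}

#' Occlusion filling-in experiment
#'
#' Runs continuous inference through each occluded sequence (one reset at
#' the start, activity carried across frames, frozen weights). After each
#' frame's inference, the prediction sent down to the input area,
#' `W_0 %*% y_1`, is recorded (min-max normalized to \[0, 1\] by default)
#' and scored by its MSE against the unoccluded ground truth restricted
#' to the occluded pixels. Frames whose mask is empty score 0.
#'
#' @param object A `pcnet` fit or `pcnet_weights`.
#' @param occluded_dataset A `pcnet_dataset` whose sequences carry
#'   `occluder_mask` and `ground_truth` (see [apply_occluder()]).
#' @param config Configuration when `object` is a bare weight set.
#' @return An object of class `pcnet_occlusion`: list with
#'   `mse_per_frame` (averaged across sequences), `mse_matrix`
#'   (sequences x frames), `predictions` (reconstructed images of the
#'   first sequence) and `normalized` (flag).
#' @export
occlusion_experiment <- function(object, occluded_dataset, config = NULL) {
  rw <- resolve_weights(object, config)
  cfg <- rw$config
  seqs <- occluded_dataset$sequences
  if (any(vapply(seqs, function(sq)
    is.null(sq$occluder_mask) || is.null(sq$ground_truth), TRUE)))
    stop("sequences must carry occluder_mask and ground_truth", call. = FALSE)
  nf <- n_frames(seqs[[1]])
  mse <- matrix(NA_real_, length(seqs), nf)
  preds <- NULL
  for (s in seq_along(seqs)) {
    sq <- seqs[[s]]
    frames <- sequence_matrix(sq)
    st <- reset_state(cfg)
    W <- unclass(rw$weights)
    if (s == 1) preds <- array(0, dim(sq$frames))
    for (f in seq_len(nf)) {
      out <- cpp_run_frames(W, st$x, st$y, frames[, f, drop = FALSE],
                            cfg$inference_rate, 0, cfg$activation_offset,
                            cfg$inference_steps_per_cycle,
                            cfg$cycles_per_frame)
      st$x <- out$state$x; st$y <- out$state$y
      pred <- drop(W[[1]] %*% out$state$y[[2]])
      if (cfg$normalize_occlusion_predictions) pred <- minmax_normalize(pred)
      mask <- as.vector(sq$occluder_mask[, , f])
      gt <- as.vector(sq$ground_truth[, , f])
      mse[s, f] <- if (!any(mask)) 0 else mean((pred[mask] - gt[mask])^2)
      if (s == 1) preds[, , f] <- matrix(pred, dim(sq$frames)[1])
    }
  }
  structure(list(mse_per_frame = colMeans(mse), mse_matrix = mse,
                 predictions = preds,
                 normalized = cfg$normalize_occlusion_predictions),
            class = "pcnet_occlusion")
}

#' @export
print.pcnet_occlusion <- function(x, ...) {
  cat("occlusion experiment over", nrow(x$mse_matrix), "sequences\n")
  cat("  occluded-region MSE per frame:",
      paste(signif(x$mse_per_frame, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Feedforward occlusion baseline
#'
#' A purely feedforward network performs no top-down reconstruction: its
#' "reconstruction" of an occluded frame is the occluded input itself,
#' which is zero inside the occluder. Its occluded-region MSE therefore
#' equals the mean squared ground-truth intensity inside the mask.
#'
#' @param occluded_dataset A `pcnet_dataset` with masks and ground truth.
#' @return A list with `mse_per_frame` (mean across sequences) and
#'   `mse_matrix` (sequences x frames).
#' @export
feedforward_baseline <- function(occluded_dataset) {
  seqs <- occluded_dataset$sequences
  if (any(vapply(seqs, function(sq)
    is.null(sq$occluder_mask) || is.null(sq$ground_truth), TRUE)))
    stop("sequences must carry occluder_mask and ground_truth", call. = FALSE)
  nf <- n_frames(seqs[[1]])
  mse <- t(vapply(seqs, function(sq) {
    vapply(seq_len(nf), function(f) {
      mask <- sq$occluder_mask[, , f]
      if (!any(mask)) 0 else mean(sq$ground_truth[, , f][mask]^2)
    }, 0)
  }, numeric(nf)))
  list(mse_per_frame = colMeans(mse), mse_matrix = mse)
}

#' Compare occlusion reconstruction errors across conditions
#'
#' Per-frame two-sample Welch t-tests of the predictive-coding network's
#' occluded-region MSE against each baseline, across seeds.
#'
#' @param pc Matrix of MSEs (seeds x frames), or a list of
#'   `pcnet_occlusion` objects (one per seed).
#' @param baselines Named list of matrices of the same shape (a
#'   deterministic baseline may be a single row, which is recycled
#'   across seeds).
#' @return A data frame with one row per (frame, baseline): means,
#'   difference, t statistic and p value.
#' @export
compare_occlusion <- function(pc, baselines) {
  as_mat <- function(x, nseeds = NULL) {
    if (is.list(x) && !is.data.frame(x) && !is.matrix(x))
      x <- do.call(rbind, lapply(x, function(o)
        if (inherits(o, "pcnet_occlusion")) o$mse_per_frame else o))
    x <- rbind(x)
    if (!is.null(nseeds) && nrow(x) == 1) x <- x[rep(1, nseeds), , drop = FALSE]
    x
  }
  pc <- as_mat(pc)
  if (nrow(pc) < 2)
    stop("need >= 2 seeds per condition for the t-test", call. = FALSE)
  out <- list()
  for (nm in names(baselines)) {
    b <- as_mat(baselines[[nm]], nseeds = nrow(pc))
    for (f in seq_len(ncol(pc))) {
      x <- pc[, f]; y <- b[, f]
      if (sd(x) == 0 && sd(y) == 0) {
        tt <- list(statistic = if (mean(x) == mean(y)) 0 else Inf,
                   p.value = if (mean(x) == mean(y)) 1 else 0)
      } else tt <- t.test(x, y)
      out[[length(out) + 1L]] <- data.frame(
        frame = f, baseline = nm, mean_pc = mean(x), mean_baseline = mean(y),
        diff = mean(x) - mean(y),
        statistic = unname(tt$statistic), p = tt$p.value)
    }
  }
  do.call(rbind, out)
}
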