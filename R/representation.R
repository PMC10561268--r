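resolve_weights <- function(object, config = NULL) {
  if (inherits(object, "pcnet"))
    list(weights = object$weights, config = object$config)
  else if (inherits(object, "pcnet_weights")) {
    if (is.null(config))
      stop("a pcnet_config is required alongside a bare weight set",
           call. = FALSE)
    list(weights = object, config = config)
  } else stop("expected a pcnet fit or pcnet_weights", call. = FALSE)
}

#' Converged representations for every frame of a dataset
#'
#' For every frame of every sequence (sequence-major order: rows 1..6 are
#' the six transformation states of the first object, and so on), resets
#' the network, clamps the still frame, runs inference to convergence
#' with frozen weights, and records the rate vector of the chosen area.
#'
#' @param object A `pcnet` fit or a `pcnet_weights` set (then `config` is
#'   required).
#' @param dataset A `pcnet_dataset`.
#' @param area Area index, 0 = input .. L = top (default top).
#' @param config Configuration when `object` is a bare weight set.
#' @return An object of class `pcnet_reps`: list with `reps` (matrix,
#'   one row per frame), `labels`, `sequence`, `frame`, `area` and
#'   `converged` (logical per row).
#' @export
infer_representations <- function(object, dataset, area = NULL, config = NULL) {
  rw <- resolve_weights(object, config)
  cfg <- rw$config
  L <- length(cfg$area_sizes) - 1L
  if (is.null(area)) area <- L
  if (area < 0 || area > L) stop("area out of range 0..", L, call. = FALSE)
  rows <- list(); labels <- integer(); seq_id <- integer(); fr_id <- integer()
  conv_flags <- logical()
  for (s in seq_along(dataset$sequences)) {
    sq <- dataset$sequences[[s]]
    frames <- sequence_matrix(sq)
    for (f in seq_len(ncol(frames))) {
      conv <- run_to_convergence(reset_state(cfg), rw$weights, frames[, f], cfg)
      rows[[length(rows) + 1L]] <- conv$state$y[[area + 1L]]
      labels <- c(labels, sq$label)
      seq_id <- c(seq_id, s); fr_id <- c(fr_id, f)
      conv_flags <- c(conv_flags, conv$converged)
    }
  }
  structure(list(reps = do.call(rbind, rows), labels = labels,
                 sequence = seq_id, frame = fr_id, area = area,
                 converged = conv_flags),
            class = "pcnet_reps")
}

#' @export
print.pcnet_reps <- function(x, ...) {
  cat("pcnet representations: ", nrow(x$reps), " frames x ", ncol(x$reps),
      " neurons (area ", x$area, "), ",
      length(unique(x$labels)), " classes\n", sep = "")
  invisible(x)
}

#' Cosine dissimilarity between two representations
#'
#' `d(r1, r2) = 1 - (r1 . r2) / (||r1|| ||r2||)`. Zero for identical
#' directions, 1 for orthogonal vectors; bounded by 1 when all activities
#' are non-negative.
#'
#' @param r1,r2 Non-zero numeric vectors of equal length.
#' @return A single dissimilarity value.
#' @examples
#' cosine_dissimilarity(c(1, 1), c(1, 0))  # 1 - 1/sqrt(2)
#' @export
cosine_dissimilarity <- function(r1, r2) {
  n1 <- sqrt(sum(r1^2)); n2 <- sqrt(sum(r2^2))
  if (n1 == 0 || n2 == 0)
    stop("cosine dissimilarity is undefined for zero vectors", call. = FALSE)
  1 - sum(r1 * r2) / (n1 * n2)
}

#' Representational dissimilarity matrix
#'
#' Full pairwise cosine-dissimilarity matrix over the rows of a
#' representation matrix, preserving the sequence-major row ordering.
#' The result is symmetric with a zero diagonal; tiny negative values
#' from floating-point cancellation are clipped at zero.
#'
#' @param reps A `pcnet_reps` object or a plain numeric matrix (rows =
#'   representations).
#' @return An object of class `pcnet_rdm`: list with `d` (the matrix) and
#'   `labels` (if available).
#' @export
compute_rdm <- function(reps) {
  m <- if (inherits(reps, "pcnet_reps")) reps$reps else as.matrix(reps)
  if (nrow(m) < 2) stop("need at least 2 representations", call. = FALSE)
  nrm <- sqrt(rowSums(m^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("representation row ", zero[1], " is a zero vector", call. = FALSE)
  d <- 1 - tcrossprod(m / nrm)
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  structure(list(d = d,
                 labels = if (inherits(reps, "pcnet_reps")) reps$labels),
            class = "pcnet_rdm")
}

#' @export
print.pcnet_rdm <- function(x, ...) {
  cat("pcnet RDM: ", nrow(x$d), " x ", ncol(x$d),
      ", range ", paste(signif(range(x$d), 3), collapse = " .. "), "\n",
      sep = "")
  invisible(x)
}

#' Heatmap of a representational dissimilarity matrix
#'
#' @param x A `pcnet_rdm`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.pcnet_rdm <- function(x, ...) {
  n <- nrow(x$d)
  graphics::image(seq_len(n), seq_len(n), t(x$d[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "stimulus", ylab = "stimulus",
                  main = "cosine dissimilarity", ...)
  invisible(x)
}

#' Within- versus across-sequence dissimilarity
#'
#' Summarizes the block-diagonal structure of an RDM whose rows are
#' ordered sequence-major with `n_frames` frames per sequence: the mean
#' dissimilarity over within-sequence (off-diagonal) pairs and over
#' across-sequence pairs. Invariant representations give a low
#' within-sequence and a high across-sequence mean.
#'
#' @param rdm A `pcnet_rdm` or plain square matrix.
#' @param n_frames Frames per sequence; must divide the row count.
#' @return A list with `within_mean` and `across_mean`.
#' @export
block_structure_score <- function(rdm, n_frames) {
  d <- if (inherits(rdm, "pcnet_rdm")) rdm$d else as.matrix(rdm)
  n <- nrow(d)
  if (n %% n_frames != 0)
    stop("row count ", n, " is not divisible by n_frames ", n_frames,
         call. = FALSE)
  block <- rep(seq_len(n / n_frames), each = n_frames)
  same <- outer(block, block, "==")
  offdiag <- !diag(TRUE, n)
  list(within_mean = mean(d[same & offdiag]),
       across_mean = mean(d[!same]))
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt into folds 1..k round-robin.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("class ", cl, " has fewer than k = ", k, " samples",
             call. = FALSE)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

new_decoding <- function(acc, method) {
  structure(list(accuracy = acc, mean = mean(acc), sd = sd(acc),
                 method = method),
            class = "pcnet_decoding")
}

#' @export
print.pcnet_decoding <- function(x, ...) {
  cat("decoding [", x$method, "]: accuracy ",
      sprintf("%.3f +/- %.3f", x$mean, if (is.na(x$sd)) 0 else x$sd),
      " over ", length(x$accuracy), " folds\n", sep = "")
  invisible(x)
}

#' Linear decoding of object identity
#'
#' Maps representations through a single fully connected layer to one
#' output neuron per class - a multinomial logistic regression - fitted
#' on k-1 folds and evaluated on the held-out fold of a stratified
#' k-fold split (default k = 3: fit on 2/3, evaluate on 1/3). Accuracy
#' on held-out representations measures how well the learned code
#' generalizes across views.
#'
#' @param reps A `pcnet_reps` object or a numeric matrix (rows =
#'   samples).
#' @param labels Class labels per row (taken from `reps` if absent).
#' @param k Number of stratified folds.
#' @param seed Seed for the fold assignment.
#' @param decay Weight-decay regularization of the decoder.
#' @param method Tag recorded in the result.
#' @return A `pcnet_decoding` object with per-fold accuracies.
#' @export
decode_linear <- function(reps, labels = NULL, k = 3, seed = 1,
                          decay = 1e-4, method = "pc_area") {
  m <- if (inherits(reps, "pcnet_reps")) reps$reps else as.matrix(reps)
  if (is.null(labels) && inherits(reps, "pcnet_reps")) labels <- reps$labels
  stopifnot(length(labels) == nrow(m))
  folds <- stratified_folds(labels, k, seed)
  y <- factor(labels)
  acc <- vapply(seq_len(k), function(fold) {
    tr <- folds != fold
    df_tr <- data.frame(.cl = y[tr], m[tr, , drop = FALSE])
    df_te <- data.frame(m[!tr, , drop = FALSE])
    fit <- with_seed(seed + fold,
      nnet::multinom(.cl ~ ., data = df_tr, decay = decay,
                     maxit = 200, MaxNWts = 50000, trace = FALSE))
    pred <- predict(fit, newdata = df_te)
    mean(as.character(pred) == as.character(y[!tr]))
  }, 0)
  new_decoding(acc, method)
}

#' k-means clustering baseline
#'
#' Clusters the raw input vectors with k-means (k = number of classes)
#' on the training folds, labels each cluster by majority vote of the
#' training labels it captured, and scores held-out samples by their
#' nearest cluster's label. Uses the same stratified folds as
#' [decode_linear()] for a given seed.
#'
#' @param inputs Matrix of flattened frames (rows = samples).
#' @param labels Class labels per row.
#' @param n_classes Number of clusters.
#' @param seed Seed for folds and k-means starts.
#' @param k Number of folds.
#' @return A `pcnet_decoding` object (method `"kmeans"`).
#' @export
kmeans_baseline <- function(inputs, labels, n_classes, seed = 1, k = 3) {
  inputs <- as.matrix(inputs)
  folds <- stratified_folds(labels, k, seed)
  acc <- vapply(seq_len(k), function(fold) {
    tr <- folds != fold
    km <- with_seed(seed + fold,
                    kmeans(inputs[tr, , drop = FALSE], centers = n_classes,
                           nstart = 10, iter.max = 50))
    # majority-vote mapping cluster -> label on the training split
    map <- vapply(seq_len(n_classes), function(cl) {
      lab <- labels[tr][km$cluster == cl]
      if (length(lab) == 0) return(NA_integer_)
      as.integer(names(sort(table(lab), decreasing = TRUE))[1])
    }, 0L)
    te <- inputs[!tr, , drop = FALSE]
    d2 <- outer(rowSums(te^2), rowSums(km$centers^2), "+") -
      2 * tcrossprod(te, km$centers)
    pred <- map[max.col(-d2)]
    mean(pred == labels[!tr], na.rm = FALSE)
  }, 0)
  new_decoding(acc, "kmeans")
}

#' Linear slow feature analysis baseline
#'
#' Linear SFA on the whitened raw pixels: inputs are centred and
#' whitened, the covariance of the within-sequence temporal differences
#' is eigendecomposed, and the eigenvectors with the smallest
#' eigenvalues (delta values) are the slowest features. The slowest
#' `n_components` features are then passed to [decode_linear()].
#'
#' @param dataset A `pcnet_dataset` (sequence order provides the
#'   temporal structure).
#' @param n_components Number of slow features kept (default 10).
#' @param seed Seed passed to the decoder folds.
#' @param k Folds for decoding.
#' @return A list with `decoding` (a `pcnet_decoding`, method `"sfa"`),
#'   `delta` (delta values of all features, ascending), `features`
#'   (the slow-feature values) and `labels`.
#' @export
sfa_baseline <- function(dataset, n_components = 10, seed = 1, k = 3) {
  X <- do.call(rbind, lapply(dataset$sequences, function(sq)
    t(sequence_matrix(sq))))
  labels <- unlist(lapply(dataset$sequences, function(sq)
    rep(sq$label, n_frames(sq))))
  seq_id <- unlist(lapply(seq_along(dataset$sequences), function(s)
    rep(s, n_frames(dataset$sequences[[s]]))))
  sfa <- linear_sfa(X, seq_id)
  nc <- min(n_components, ncol(sfa$features))
  feats <- sfa$features[, seq_len(nc), drop = FALSE]
  list(decoding = decode_linear(feats, labels, k = k, seed = seed,
                                method = "sfa"),
       delta = sfa$delta, features = feats, labels = labels)
}

# Whitening + smallest-eigenvalue problem on temporal differences.
linear_sfa <- function(X, seq_id) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  if (!all(keep)) {
    # degenerate directions dropped; if everything is degenerate,
    # regularize with a small ridge
    if (!any(keep)) {
      warning("degenerate input covariance; applying a small ridge")
      C <- C + diag(1e-8, ncol(C))
      eg <- eigen(C, symmetric = TRUE)
      keep <- rep(TRUE, ncol(C))
    }
  }
  Wh <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), sum(keep))
  Z <- Xc %*% Wh
  dz <- do.call(rbind, lapply(unique(seq_id), function(s) {
    rows <- which(seq_id == s)
    if (length(rows) < 2) return(NULL)
    Z[rows[-1], , drop = FALSE] - Z[rows[-length(rows)], , drop = FALSE]
  }))
  B <- crossprod(dz) / nrow(dz)
  eb <- eigen(B, symmetric = TRUE)
  ord <- order(eb$values)
  V <- eb$vectors[, ord, drop = FALSE]
  list(features = Z %*% V, delta = eb$values[ord],
       projection = Wh %*% V, center = attr(Xc, "scaled:center"))
}
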