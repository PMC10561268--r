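#' Synthetic glyph stimuli
#'
#' Renders a small family of connected stroke-based shapes (ring, bars,
#' cross, X, L, T, triangle, U, Z for classes 0..9; seeded random
#' polylines beyond that) centred on the canvas with soft anti-aliased
#' edges. Glyphs are deterministic per `(class_id, seed)` and mutually
#' distinct, and stand in for handwritten-digit images so that the
#' package is self-contained.
#'
#' @param class_id Non-negative integer class identity.
#' @param shape Canvas size `c(H, W)`; both must be >= 16.
#' @param seed Integer seed controlling small shape jitter.
#' @return An `H x W` matrix with values in \[0, 1\].
#' @examples
#' g <- make_glyph(0, shape = c(16, 16))
#' range(g)
#' @export
make_glyph <- function(class_id, shape = c(28, 28), seed = 1) {
  H <- shape[1]; W <- shape[2]
  if (H < 16 || W < 16)
    stop("canvas too small: glyphs need at least 16x16 pixels", call. = FALSE)
  segs <- glyph_strokes(class_id, seed)
  render_strokes(segs, H, W)
}

# Stroke list in unit-square coordinates (u = across, v = down), jittered
# deterministically per (class_id, seed).
glyph_strokes <- function(class_id, seed) {
  base <- switch(as.character(class_id %% 10L),
    "0" = list(ring = c(0.5, 0.5, 0.20)),
    "1" = list(s = c(0.50, 0.26, 0.50, 0.74)),
    "2" = list(s = c(0.26, 0.50, 0.74, 0.50)),
    "3" = list(s = c(0.50, 0.26, 0.50, 0.74), s2 = c(0.26, 0.50, 0.74, 0.50)),
    "4" = list(s = c(0.28, 0.28, 0.72, 0.72), s2 = c(0.28, 0.72, 0.72, 0.28)),
    "5" = list(s = c(0.34, 0.26, 0.34, 0.72), s2 = c(0.34, 0.72, 0.72, 0.72)),
    "6" = list(s = c(0.27, 0.30, 0.73, 0.30), s2 = c(0.50, 0.30, 0.50, 0.74)),
    "7" = list(s = c(0.50, 0.26, 0.73, 0.71), s2 = c(0.73, 0.71, 0.27, 0.71),
               s3 = c(0.27, 0.71, 0.50, 0.26)),
    "8" = list(s = c(0.31, 0.28, 0.31, 0.68), s2 = c(0.69, 0.28, 0.69, 0.68),
               s3 = c(0.31, 0.68, 0.69, 0.68)),
    "9" = list(s = c(0.29, 0.30, 0.71, 0.30), s2 = c(0.71, 0.30, 0.29, 0.70),
               s3 = c(0.29, 0.70, 0.71, 0.70)))
  if (class_id > 9) {
    base <- with_seed(seed * 131L + as.integer(class_id), {
      pts <- cbind(runif(4, 0.30, 0.70), runif(4, 0.30, 0.70))
      lapply(seq_len(3), function(i)
        c(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2]))
    })
    names(base) <- paste0("s", seq_along(base))
    return(base)
  }
  jit <- with_seed(seed * 977L + as.integer(class_id) * 7L + 3L,
                   runif(8 * length(base), -0.02, 0.02))
  k <- 0
  for (i in seq_along(base)) {
    n <- length(base[[i]])
    base[[i]] <- base[[i]] + jit[k + seq_len(n)] * c(1, 1, 1, 1)[seq_len(n)]
    k <- k + n
  }
  base
}

render_strokes <- function(segs, H, W, halfwidth = 0.055, edge = 0.045) {
  sc <- min(H, W)
  u <- (col(matrix(0, H, W)) - 0.5) / sc
  v <- (row(matrix(0, H, W)) - 0.5) / sc
  img <- matrix(0, H, W)
  for (nm in names(segs)) {
    p <- segs[[nm]]
    if (startsWith(nm, "ring")) {
      d <- abs(sqrt((u - p[1])^2 + (v - p[2])^2) - p[3])
    } else {
      d <- dist_to_segment(u, v, p[1], p[2], p[3], p[4])
    }
    val <- pmin(1, pmax(0, (halfwidth + edge - d) / edge))
    img <- pmax(img, val)
  }
  img
}

dist_to_segment <- function(u, v, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((u - x1) * dx + (v - y1) * dy) / len2))
  sqrt((u - (x1 + t * dx))^2 + (v - (y1 + t * dy))^2)
}

# Integer-pixel shift with zero fill; dx > 0 moves right, dy > 0 moves down.
shift_image <- function(img, dx = 0, dy = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  sr <- seq_len(H) - dy; sc <- seq_len(W) - dx
  okr <- sr >= 1 & sr <= H; okc <- sc >= 1 & sc <= W
  out[okr, okc] <- img[sr[okr], sc[okc]]
  out
}

# Bilinear affine warp about the image centre: rotation (degrees,
# counterclockwise in matrix row/col coordinates) and isotropic scaling.
# Out-of-canvas samples are zero.
warp_image <- function(img, angle = 0, scale = 1) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  r <- as.vector(row(img)); c <- as.vector(col(img))
  dy <- r - cy; dx <- c - cx
  # inverse map: rotate destination offsets by -angle, then unscale
  sx <- (co * dx + si * dy) / scale + cx
  sy <- (-si * dx + co * dy) / scale + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  gv <- function(rr, cc) {
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    out <- numeric(length(rr))
    out[ok] <- img[cbind(rr[ok], cc[ok])]
    out
  }
  val <- (1 - fx) * (1 - fy) * gv(y0, x0) +
         fx * (1 - fy) * gv(y0, x0 + 1) +
         (1 - fx) * fy * gv(y0 + 1, x0) +
         fx * fy * gv(y0 + 1, x0 + 1)
  matrix(pmin(1, pmax(0, val)), H, W)
}

new_sequence <- function(frames, label = NA_integer_, transform = "none",
                         speed = NA_real_, noise = FALSE,
                         occluder_mask = NULL, ground_truth = NULL) {
  structure(list(frames = frames, label = label, transform = transform,
                 speed = speed, noise = noise,
                 occluder_mask = occluder_mask, ground_truth = ground_truth),
            class = "pcnet_sequence")
}

#' @export
print.pcnet_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat("pcnet sequence:", d[3], "frames of", d[1], "x", d[2],
      " transform:", x$transform,
      if (!is.null(x$occluder_mask)) " (occluded)", "\n")
  invisible(x)
}

n_frames <- function(sequence) dim(sequence$frames)[3]

#' Moving-bar sequence
#'
#' A full-length bar of unit intensity translated across a zero
#' background by an integer number of pixels per frame. A horizontal bar
#' moves downward; a vertical bar moves rightward; the two are each
#' other's transpose.
#'
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param shape Canvas `c(H, W)`.
#' @param n_frames Number of frames (default 6).
#' @param step_px Integer pixels moved per frame.
#' @param bar_width Bar thickness in pixels.
#' @return A `pcnet_sequence`.
#' @export
make_bar_sequence <- function(orientation = c("vertical", "horizontal"),
                              shape = c(28, 28), n_frames = 6, step_px = 2,
                              bar_width = 2) {
  orientation <- match.arg(orientation)
  H <- shape[1]; W <- shape[2]
  travel <- (n_frames - 1) * step_px + bar_width
  if (travel > (if (orientation == "vertical") W else H))
    stop("bar does not fit the canvas over ", n_frames, " frames",
         call. = FALSE)
  base <- matrix(0, H, W)
  if (orientation == "vertical") base[, seq_len(bar_width)] <- 1  # left edge
  else base[seq_len(bar_width), ] <- 1                            # top edge
  frames <- array(0, c(H, W, n_frames))
  for (i in seq_len(n_frames)) {
    sh <- (i - 1L) * step_px
    frames[, , i] <- if (orientation == "vertical")
      shift_image(base, dx = sh) else shift_image(base, dy = sh)
  }
  new_sequence(frames, transform = "translate", speed = step_px)
}

#' Transformation sequence from a base image
#'
#' Applies a gradually increasing transformation to a base image: frame i
#' (0-based) is the base translated by `i * step` pixels, rotated by
#' `i * step` degrees, or scaled by factor `1 + i * step`. Rotation and
#' scaling use bilinear interpolation about the canvas centre;
#' translation uses integer-pixel shifts. Optionally a fresh uniform
#' noise pattern (amplitude 0.2) is added to the background - pixels not
#' covered by the object - of every frame.
#'
#' @param base Base image matrix in \[0, 1\].
#' @param transform One of `"translate"`, `"rotate"`, `"scale"`.
#' @param n_frames Number of frames.
#' @param step Per-frame increment (pixels, degrees, or scale-factor
#'   increment); must be > 0.
#' @param noise Add background noise?
#' @param seed Seed for the noise patterns.
#' @param noise_amplitude Upper bound of the uniform background noise.
#' @return A `pcnet_sequence`.
#' @examples
#' sq <- make_sequence(make_glyph(0, c(16, 16)), "rotate", step = 15)
#' dim(sq$frames)
#' @export
make_sequence <- function(base, transform = c("translate", "rotate", "scale"),
                          n_frames = 6, step = 1, noise = FALSE, seed = 1,
                          noise_amplitude = 0.2) {
  if (length(transform) != 1 || !transform %in% c("translate", "rotate", "scale"))
    stop("unknown transform: ", paste(transform, collapse = "/"), call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  H <- nrow(base); W <- ncol(base)
  frames <- array(0, c(H, W, n_frames))
  for (i in seq_len(n_frames)) {
    k <- i - 1L
    frames[, , i] <- switch(transform,
      translate = shift_image(base, dx = round(k * step)),
      rotate = warp_image(base, angle = k * step),
      scale = warp_image(base, scale = 1 + k * step))
  }
  if (noise) {
    for (i in seq_len(n_frames)) {
      f <- frames[, , i]
      bg <- f < 0.05
      f[bg] <- f[bg] + with_seed(seed * 613L + i,
                                 runif(sum(bg), 0, noise_amplitude))
      frames[, , i] <- pmin(1, f)
    }
  }
  new_sequence(frames, transform = transform, speed = step, noise = noise)
}

default_steps <- c(translate = 1, rotate = 15, scale = 0.08)

#' Synthetic transformation dataset
#'
#' One transformation sequence per object class, built from the glyph
#' family. The per-frame step is the transform's base step multiplied by
#' `speed`; the fast condition (`speed = 2`) doubles the step and thereby
#' halves the overlap between consecutive frames. Translating glyphs are
#' pre-shifted so the motion is centred on the canvas.
#'
#' @param n_classes Number of object classes (sequences).
#' @param transform `"translate"`, `"rotate"` or `"scale"`.
#' @param speed Speed factor (1 = slow, 2 = fast).
#' @param noise Add background noise to every frame?
#' @param shape Canvas `c(H, W)`.
#' @param seed Seed for glyph jitter and noise.
#' @param n_frames Frames per sequence (default 6).
#' @return An object of class `pcnet_dataset`: a list with `sequences`,
#'   `n_classes` and `image_shape`. Labels run from 0 to
#'   `n_classes - 1`.
#' @examples
#' ds <- make_dataset(3, "translate", shape = c(16, 16))
#' length(ds$sequences)
#' @export
make_dataset <- function(n_classes = 10,
                         transform = c("translate", "rotate", "scale"),
                         speed = 1, noise = FALSE, shape = c(28, 28),
                         seed = 1, n_frames = 6) {
  transform <- match.arg(transform)
  step <- default_steps[[transform]] * speed
  seqs <- lapply(seq_len(n_classes) - 1L, function(cl) {
    base <- make_glyph(cl, shape, seed)
    if (transform == "translate")
      base <- shift_image(base, dx = -floor((n_frames - 1) * step / 2))
    sq <- make_sequence(base, transform, n_frames, step,
                        noise = noise, seed = seed + cl * 101L)
    sq$label <- cl
    sq$speed <- speed
    sq
  })
  structure(list(sequences = seqs, n_classes = as.integer(n_classes),
                 image_shape = as.integer(shape)),
            class = "pcnet_dataset")
}

#' @export
print.pcnet_dataset <- function(x, ...) {
  cat("pcnet dataset:", length(x$sequences), "sequences,",
      x$n_classes, "classes,", paste(x$image_shape, collapse = "x"),
      "pixels,", n_frames(x$sequences[[1]]), "frames each\n")
  invisible(x)
}

#' Occlude a sequence with a static rectangle
#'
#' Zeroes all pixels inside an axis-aligned rectangle in every frame,
#' storing the original frames as ground truth and the rectangle as a
#' per-frame occluder mask. With a translating object entering the
#' region, the number of occluded object pixels grows across the
#' sequence.
#'
#' @param sequence A `pcnet_sequence`.
#' @param region Integer vector `c(row1, row2, col1, col2)` (inclusive
#'   bounds). An empty region (`row2 < row1` or `col2 < col1`, or `NULL`)
#'   leaves the sequence unchanged with an all-false mask.
#' @return The occluded `pcnet_sequence` with `occluder_mask` and
#'   `ground_truth` populated.
#' @export
apply_occluder <- function(sequence, region) {
  stopifnot(inherits(sequence, "pcnet_sequence"))
  d <- dim(sequence$frames)
  mask <- array(FALSE, d)
  gt <- sequence$frames
  empty <- is.null(region) || region[2] < region[1] || region[4] < region[3]
  if (!empty) {
    if (region[1] < 1 || region[2] > d[1] || region[3] < 1 || region[4] > d[2])
      stop("occluder region exceeds the canvas", call. = FALSE)
    rows <- region[1]:region[2]; cols <- region[3]:region[4]
    mask[rows, cols, ] <- TRUE
    sequence$frames[rows, cols, ] <- 0
  }
  sequence$occluder_mask <- mask
  sequence$ground_truth <- gt
  sequence
}

#' Shuffle the frame order of a sequence
#'
#' Permutes the frames (and any masks/ground truth) with a seeded
#' permutation. Temporal continuity in the training loop is preserved;
#' only the spatial ordering of the transformation is broken.
#'
#' @param sequence A `pcnet_sequence`.
#' @param seed Integer seed for the permutation.
#' @return The permuted `pcnet_sequence`.
#' @export
shuffle_frame_order <- function(sequence, seed = 1) {
  stopifnot(inherits(sequence, "pcnet_sequence"))
  nf <- n_frames(sequence)
  perm <- with_seed(seed, sample.int(nf))
  sequence$frames <- sequence$frames[, , perm, drop = FALSE]
  if (!is.null(sequence$occluder_mask))
    sequence$occluder_mask <- sequence$occluder_mask[, , perm, drop = FALSE]
  if (!is.null(sequence$ground_truth))
    sequence$ground_truth <- sequence$ground_truth[, , perm, drop = FALSE]
  sequence
}

# n_pixels x n_frames matrix for the C++ core
sequence_matrix <- function(sequence) {
  d <- dim(sequence$frames)
  matrix(sequence$frames, d[1] * d[2], d[3])
}

# Mean pixelwise product of consecutive frames (overlap measure)
sequence_overlap <- function(sequence) {
  nf <- n_frames(sequence)
  mean(vapply(seq_len(nf - 1), function(i)
    mean(sequence$frames[, , i] * sequence$frames[, , i + 1]), 0))
}

#' Export the frames of a sequence as PNG images
#'
#' Writes one grayscale PNG per frame (`frame-01.png`, ...) for visual
#' inspection of generated stimuli.
#'
#' @param sequence A `pcnet_sequence`.
#' @param dir Output directory (created if missing).
#' @return The written file paths, invisibly.
#' @export
write_sequence_png <- function(sequence, dir) {
  stopifnot(inherits(sequence, "pcnet_sequence"))
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nf <- n_frames(sequence)
  paths <- vapply(seq_len(nf), function(i) {
    p <- file.path(dir, sprintf("frame-%02d.png", i))
    png::writePNG(sequence$frames[, , i], p)
    p
  }, "")
  invisible(paths)
}
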