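test_that("glyphs are deterministic, bounded and mutually distinct", {
  for (shape in list(c(16, 16), c(28, 28))) {
    glyphs <- lapply(0:9, make_glyph, shape = shape, seed = 1)
    for (g in glyphs) {
      expect_gte(min(g), 0)
      expect_lte(max(g), 1)
      expect_gt(sum(g), 0)
    }
    # pairwise distinctness
    for (a in 1:9) for (b in (a + 1):10) {
      if (b > 10) next
      expect_gt(cosine_dissimilarity(as.numeric(glyphs[[a]]),
                                     as.numeric(glyphs[[b]])), 0.05)
    }
  }
  expect_identical(make_glyph(3, c(20, 20), seed = 7),
                   make_glyph(3, c(20, 20), seed = 7))
  expect_false(identical(make_glyph(3, c(20, 20), seed = 7),
                         make_glyph(3, c(20, 20), seed = 8)))
  # beyond the parametric family: seeded polylines
  expect_identical(make_glyph(12, c(20, 20), seed = 2),
                   make_glyph(12, c(20, 20), seed = 2))
  expect_error(make_glyph(0, c(8, 8)), "too small")
})

test_that("bar sequences translate by whole pixels", {
  sq <- make_bar_sequence("vertical", c(20, 20), n_frames = 6, step_px = 2)
  expect_identical(dim(sq$frames), c(20L, 20L, 6L))
  # frame i equals frame 0 shifted 2*i pixels (manual index shift)
  for (i in 2:6) {
    shifted <- matrix(0, 20, 20)
    shifted[, (2 * (i - 1) + 1):20] <- sq$frames[, 1:(20 - 2 * (i - 1)), 1]
    expect_equal(sq$frames[, , i], shifted)
  }
  sq0 <- make_bar_sequence("vertical", c(20, 20), n_frames = 4, step_px = 0)
  for (i in 2:4) expect_equal(sq0$frames[, , i], sq0$frames[, , 1])
  h <- make_bar_sequence("horizontal", c(20, 20), n_frames = 3, step_px = 2)
  v <- make_bar_sequence("vertical", c(20, 20), n_frames = 3, step_px = 2)
  for (i in 1:3) expect_equal(h$frames[, , i], t(v$frames[, , i]))
  expect_error(make_bar_sequence("vertical", c(10, 10), n_frames = 6,
                                 step_px = 2), "fit")
})

test_that("translation sequences move the centroid at the stated speed", {
  g <- make_glyph(0, c(28, 28))
  base <- pcnet:::shift_image(g, dx = -5)
  sq <- make_sequence(base, "translate", n_frames = 6, step = 2)
  centroids <- vapply(1:6, function(i) {
    f <- sq$frames[, , i]
    sum(col(f) * f) / sum(f)
  }, 0)
  expect_equal(diff(centroids), rep(2, 5), tolerance = 0.05)
  expect_error(make_sequence(base, "swirl"), "unknown transform")
  expect_error(make_sequence(base, "translate", step = 0), "step")
})

test_that("rotation frames match an independent bilinear rotation oracle", {
  skip_if_not_installed("EBImage")
  base <- make_glyph(7, c(28, 28))
  sq <- make_sequence(base, "rotate", n_frames = 6, step = 60)
  # frame 6 is the base rotated by 300 degrees; EBImage rotates the
  # transposed raster in the opposite sense, hence the sign flip
  oracle <- as.matrix(EBImage::rotate(base, -300, filter = "bilinear",
                                      output.dim = c(28, 28), bg.col = 0))
  expect_lt(mean((sq$frames[, , 6] - oracle)^2), 0.01)
  oracle2 <- as.matrix(EBImage::rotate(base, -60, filter = "bilinear",
                                       output.dim = c(28, 28), bg.col = 0))
  expect_lt(mean((sq$frames[, , 2] - oracle2)^2), 0.01)
})

test_that("scaling sequences grow the object monotonically", {
  base <- make_glyph(0, c(28, 28))
  sq <- make_sequence(base, "scale", n_frames = 6, step = 0.1)
  bbox_area <- vapply(1:6, function(i) {
    f <- sq$frames[, , i] > 0.1
    if (!any(f)) return(0)
    rr <- range(row(f)[f]); cc <- range(col(f)[f])
    (rr[2] - rr[1] + 1) * (cc[2] - cc[1] + 1)
  }, 0)
  expect_true(all(diff(bbox_area) >= 0))
  expect_gt(bbox_area[6], bbox_area[1])
})

test_that("background noise spares the object and respects its amplitude", {
  base <- make_glyph(1, c(20, 20))
  sq <- make_sequence(base, "rotate", n_frames = 3, step = 10, noise = TRUE,
                      seed = 5)
  clean <- make_sequence(base, "rotate", n_frames = 3, step = 10)
  for (i in 1:3) {
    f <- sq$frames[, , i]; f0 <- clean$frames[, , i]
    obj <- f0 >= 0.05
    expect_equal(f[obj], f0[obj])                 # object pixels untouched
    expect_true(all(f[!obj] - f0[!obj] <= 0.2 + 1e-12))
    expect_true(all(f >= 0 & f <= 1))
    expect_gt(mean(f[!obj]), mean(f0[!obj]))      # noise actually added
  }
  # regenerated per frame: background patterns differ across frames
  expect_false(isTRUE(all.equal(sq$frames[, , 1][base < 0.05],
                                sq$frames[, , 2][base < 0.05])))
})

test_that("datasets are reproducible and the fast condition lowers overlap", {
  ds1 <- make_dataset(10, "translate", speed = 1, shape = c(28, 28), seed = 3)
  ds2 <- make_dataset(10, "translate", speed = 2, shape = c(28, 28), seed = 3)
  expect_length(ds1$sequences, 10)
  expect_identical(vapply(ds1$sequences, function(s) dim(s$frames)[3], 0L),
                   rep(6L, 10))
  expect_identical(vapply(ds1$sequences, `[[`, 0L, "label"), 0:9)
  for (i in 1:10) {
    expect_gt(pcnet:::sequence_overlap(ds1$sequences[[i]]),
              pcnet:::sequence_overlap(ds2$sequences[[i]]))
  }
  expect_identical(make_dataset(3, "rotate", seed = 11),
                   make_dataset(3, "rotate", seed = 11))
})

test_that("the occluder zeroes its region and tracks the object's entry", {
  ds <- make_dataset(1, "translate", shape = c(16, 16), seed = 2)
  sq <- ds$sequences[[1]]
  occ <- apply_occluder(sq, c(1, 16, 12, 16))
  expect_true(all(occ$frames[, 12:16, ] == 0))
  out_mask <- !occ$occluder_mask
  expect_equal(occ$frames[out_mask], occ$ground_truth[out_mask])
  # occluded object pixels are non-decreasing as the object translates in
  occluded_obj <- vapply(1:6, function(i)
    sum(occ$ground_truth[, , i][occ$occluder_mask[, , i]] > 0.1), 0)
  expect_true(all(diff(occluded_obj) >= 0))
  # empty and full regions
  same <- apply_occluder(sq, NULL)
  expect_equal(same$frames, sq$frames)
  expect_false(any(same$occluder_mask))
  full <- apply_occluder(sq, c(1, 16, 1, 16))
  expect_true(all(full$frames == 0))
  expect_true(all(full$occluder_mask))
  expect_error(apply_occluder(sq, c(1, 20, 1, 16)), "canvas")
})

test_that("frame shuffling permutes without loss and reproducibly", {
  ds <- make_dataset(1, "rotate", shape = c(16, 16), seed = 4)
  sq <- ds$sequences[[1]]
  sh <- shuffle_frame_order(sq, seed = 3)
  expect_identical(shuffle_frame_order(sq, seed = 3)$frames, sh$frames)
  # multiset of frames preserved
  key <- function(fr) sort(apply(fr, 3, function(m) sum(m * seq_along(m))))
  expect_equal(key(sh$frames), key(sq$frames))
  # single-frame sequence cannot change
  one <- sq; one$frames <- sq$frames[, , 1, drop = FALSE]
  expect_equal(shuffle_frame_order(one, seed = 9)$frames, one$frames)
})

test_that("sequences export to one PNG per frame", {
  skip_if_not_installed("png")
  sq <- make_bar_sequence("vertical", c(16, 16), n_frames = 3, step_px = 2)
  td <- file.path(tempdir(), "pcnet-png")
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  write_sequence_png(sq, td)
  files <- list.files(td, pattern = "frame-\\d+\\.png")
  expect_length(files, 3)
  back <- png::readPNG(file.path(td, "frame-01.png"))
  expect_equal(back, sq$frames[, , 1], tolerance = 1e-2)
})
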