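# Standard glyph fixture shared by the acceptance-property tests: 10 glyph
# classes on a 16x16 canvas, 6 frames, 4 weight-initialization seeds,
# continuous and static training on translation plus continuous training on
# rotation. Built once per test run on first use.

.fixture <- new.env(parent = emptyenv())

std_fixture <- function() {
  if (!is.null(.fixture$fx)) return(.fixture$fx)
  cfg <- study_config()
  seeds <- 1:4
  shape <- c(16, 16)
  ds_tr <- make_dataset(10, "translate", shape = shape, seed = 42)
  ds_rot <- make_dataset(10, "rotate", shape = shape, seed = 42)
  occ_region <- c(1, 16, 12, 16)
  ds_occ <- ds_tr
  ds_occ$sequences <- lapply(ds_occ$sequences, apply_occluder,
                             region = occ_region)
  fits_cont <- lapply(seeds, function(s)
    pcnet(ds_tr, cfg, "continuous", epochs = 10, seed = s))
  fits_stat <- lapply(seeds, function(s)
    pcnet(ds_tr, cfg, "static", epochs = 10, seed = s))
  fits_rot <- lapply(seeds, function(s)
    pcnet(ds_rot, cfg, "continuous", epochs = 10, seed = s))
  reps_cont <- lapply(fits_cont, infer_representations, dataset = ds_tr,
                      area = 3)
  reps_stat <- lapply(fits_stat, infer_representations, dataset = ds_tr,
                      area = 3)
  reps_untr <- lapply(seeds, function(s)
    infer_representations(init_weights(cfg, s), ds_tr, area = 3,
                          config = cfg))
  .fixture$fx <- list(cfg = cfg, seeds = seeds, shape = shape,
                      ds_tr = ds_tr, ds_rot = ds_rot, ds_occ = ds_occ,
                      fits_cont = fits_cont, fits_stat = fits_stat,
                      fits_rot = fits_rot,
                      reps_cont = reps_cont, reps_stat = reps_stat,
                      reps_untr = reps_untr)
  .fixture$fx
}

fixture_inputs <- function(fx) {
  X <- do.call(rbind, lapply(fx$ds_tr$sequences, function(sq)
    t(matrix(sq$frames, prod(fx$shape), dim(sq$frames)[3]))))
  labels <- rep(vapply(fx$ds_tr$sequences, `[[`, 0L, "label"), each = 6)
  list(X = X, labels = labels)
}
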