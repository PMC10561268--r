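#' Standard study configuration
#'
#' The scaled network configuration used by [run_reproduction()], the
#' package examples and the test suite: a 16x16 canvas feeding areas of
#' 200, 80 and 30 neurons, with 20 inference-learning cycles per frame.
#' The architecture, rates and loop structure are those of
#' [pcnet_config()]; only the problem size is reduced so that the full
#' set of experiments (4 seeds, 3 training paradigms, all analyses) runs
#' in minutes on a single CPU. See the methods vignette for the
#' rationale.
#'
#' @param image_shape Canvas size `c(H, W)`.
#' @param ... Overrides passed on to [pcnet_config()].
#' @return A [pcnet_config()].
#' @export
study_config <- function(image_shape = c(16, 16), ...) {
  args <- list(...)
  defaults <- list(area_sizes = c(prod(image_shape), 200, 80, 30),
                   cycles_per_frame = 20,
                   learning_rate = 0.01)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(pcnet_config, args)
}

#' End-to-end reproduction driver
#'
#' Chains the full experimental pipeline on the standard glyph fixture:
#' stimulus generation, continuous and static training across seeds, the
#' RDM and decoding analyses with k-means / input-decoding / SFA
#' baselines, the timescale hierarchy on rotation sequences, top-down
#' reconstruction MSEs per source area, and the occlusion experiment
#' with its feedforward baseline. Writes tabular results as CSV files, a
#' JSON manifest, and a pass/fail summary of the ordinal properties the
#' model is expected to show.
#'
#' @param out_dir Output directory (created if missing).
#' @param seeds Integer vector of weight-initialization seeds.
#' @param n_classes Number of glyph classes.
#' @param epochs Training epochs.
#' @param config Network configuration; defaults to [study_config()].
#' @param speeds Stimulus speeds for the timescale experiment.
#' @param dry_run If `TRUE`, lists the planned stages without running or
#'   writing anything.
#' @param verbose Print per-stage progress?
#' @return A run manifest (list) with config snapshot, seeds, artifact
#'   paths, per-stage status and the ordinal-property summary, invisibly
#'   (visibly for dry runs).
#' @export
run_reproduction <- function(out_dir, seeds = 1:4, n_classes = 10,
                             epochs = 10, config = NULL,
                             speeds = c(1, 2, 4), dry_run = FALSE,
                             verbose = TRUE) {
  stages <- c("generate", "train", "rdm", "decode", "timescales",
              "reconstruct", "occlude", "summary")
  if (dry_run)
    return(list(stages = stages, seeds = seeds, planned_out = out_dir,
                dry_run = TRUE))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message("[pcnet] ", ...)
  if (is.null(config)) config <- study_config()
  shape <- c(NA, NA)
  shape <- sqrt(config$area_sizes[1]); shape <- c(shape, shape)
  manifest <- list(config = unclass(config), seeds = seeds,
                   n_classes = n_classes, epochs = epochs,
                   stages = list(), artifacts = character())
  art <- function(name) {
    p <- file.path(out_dir, name)
    manifest$artifacts <<- c(manifest$artifacts, p)
    p
  }
  status <- function(stage, ok) manifest$stages[[stage]] <<- ok

  say("generating stimuli")
  ds_tr <- make_dataset(n_classes, "translate", shape = shape, seed = 42)
  ds_rot <- make_dataset(n_classes, "rotate", shape = shape, seed = 42)
  occ_region <- c(1, shape[1], shape[2] - 4, shape[2])
  ds_occ <- ds_tr
  ds_occ$sequences <- lapply(ds_occ$sequences, apply_occluder,
                             region = occ_region)
  status("generate", TRUE)

  say("training ", length(seeds), " seeds x {continuous, static, rotation}")
  fits_cont <- lapply(seeds, function(s)
    pcnet(ds_tr, config, "continuous", epochs, seed = s))
  fits_stat <- lapply(seeds, function(s)
    pcnet(ds_tr, config, "static", epochs, seed = s))
  fits_rot <- lapply(seeds, function(s)
    pcnet(ds_rot, config, "continuous", epochs, seed = s))
  hist <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    h <- fits_cont[[i]]$history; h$seed <- seeds[i]; h$paradigm <- "continuous"
    h2 <- fits_stat[[i]]$history; h2$seed <- seeds[i]; h2$paradigm <- "static"
    rbind(h, h2)
  }))
  write.csv(hist, art("training_history.csv"), row.names = FALSE)
  status("train", TRUE)

  say("RDM analysis")
  L <- length(config$area_sizes) - 1L
  reps_cont <- lapply(fits_cont, function(f)
    infer_representations(f, ds_tr, area = L))
  reps_stat <- lapply(fits_stat, function(f)
    infer_representations(f, ds_tr, area = L))
  reps_untr <- lapply(seeds, function(s)
    infer_representations(init_weights(config, s), ds_tr, area = L,
                          config = config))
  nf <- n_frames(ds_tr$sequences[[1]])
  gap <- function(reps) {
    bs <- block_structure_score(compute_rdm(reps), nf)
    c(within = bs$within_mean, across = bs$across_mean,
      gap = bs$across_mean - bs$within_mean)
  }
  rdm_tab <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    rbind(data.frame(seed = seeds[i], network = "continuous",
                     t(gap(reps_cont[[i]]))),
          data.frame(seed = seeds[i], network = "static",
                     t(gap(reps_stat[[i]]))),
          data.frame(seed = seeds[i], network = "untrained",
                     t(gap(reps_untr[[i]]))))
  }))
  write.csv(rdm_tab, art("rdm_block_structure.csv"), row.names = FALSE)
  rdm1 <- compute_rdm(reps_cont[[1]])
  write.csv(rdm1$d, art("rdm_continuous_seed1.csv"), row.names = FALSE)
  status("rdm", TRUE)

  say("decoding analysis with baselines")
  inputs <- do.call(rbind, lapply(ds_tr$sequences, function(sq)
    t(sequence_matrix(sq))))
  in_labels <- unlist(lapply(ds_tr$sequences, function(sq)
    rep(sq$label, nf)))
  dec_tab <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    s <- seeds[i]
    rbind(
      data.frame(seed = s, method = "pc_continuous",
                 accuracy = decode_linear(reps_cont[[i]], seed = s)$mean),
      data.frame(seed = s, method = "pc_static",
                 accuracy = decode_linear(reps_stat[[i]], seed = s)$mean),
      data.frame(seed = s, method = "input_ld",
                 accuracy = decode_linear(inputs, in_labels, seed = s)$mean),
      data.frame(seed = s, method = "kmeans",
                 accuracy = kmeans_baseline(inputs, in_labels, n_classes,
                                            seed = s)$mean),
      data.frame(seed = s, method = "sfa",
                 accuracy = sfa_baseline(ds_tr, seed = s)$decoding$mean))
  }))
  write.csv(dec_tab, art("decoding.csv"), row.names = FALSE)
  status("decode", TRUE)

  say("timescale analysis")
  taus <- timescale_experiment(fits_rot, ds_rot, speeds = speeds)
  write.csv(taus, art("decay_constants.csv"), row.names = FALSE)
  ts_stats <- tryCatch(timescale_stats(taus, speed = 1),
                       error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(ts_stats, art("timescale_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  status("timescales", TRUE)

  say("top-down reconstruction")
  rec_tab <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    fit <- fits_cont[[i]]
    do.call(rbind, lapply(seq_len(L), function(a) {
      mses <- vapply(ds_tr$sequences, function(sq)
        reconstruct_after_blanking(fit, sq$frames[, , 1],
                                   source_area = a)$mse, 0)
      data.frame(seed = seeds[i], source_area = a, mse = mean(mses))
    }))
  }))
  write.csv(rec_tab, art("reconstruction_mse.csv"), row.names = FALSE)
  status("reconstruct", TRUE)

  say("occlusion experiment")
  occ_pc <- lapply(fits_cont, occlusion_experiment,
                   occluded_dataset = ds_occ)
  occ_st <- lapply(fits_stat, occlusion_experiment,
                   occluded_dataset = ds_occ)
  ff <- feedforward_baseline(ds_occ)
  occ_cmp <- compare_occlusion(occ_pc,
                               list(feedforward = ff$mse_per_frame,
                                    pc_static = occ_st))
  write.csv(occ_cmp, art("occlusion_comparison.csv"), row.names = FALSE)
  status("occlude", TRUE)

  say("summarizing ordinal properties")
  acc <- function(m) dec_tab$accuracy[dec_tab$method == m]
  mean_rec <- function(a) mean(rec_tab$mse[rec_tab$source_area == a])
  pc_mse <- colMeans(do.call(rbind, lapply(occ_pc, `[[`, "mse_per_frame")))
  occluded <- ff$mse_per_frame > 0
  tau_at <- function(pop, a) mean(taus$tau[taus$population == pop &
                                             taus$area == a & taus$speed == 1])
  rho <- stats::cor(taus$speed, taus$tau, method = "spearman")
  summary <- list(
    invariance_within_lt_across =
      all(rdm_tab$gap[rdm_tab$network == "continuous"] > 0),
    invariance_gap_exceeds_controls =
      mean(rdm_tab$gap[rdm_tab$network == "continuous"]) >
        max(mean(rdm_tab$gap[rdm_tab$network == "untrained"]),
            mean(rdm_tab$gap[rdm_tab$network == "static"])),
    decoding_beats_baselines_majority =
      sum(acc("pc_continuous") > pmax(acc("pc_static"), acc("input_ld"),
                                      acc("kmeans"), 1 / n_classes)) >=
        ceiling(length(seeds) * 3 / 4),
    timescale_hierarchy =
      tau_at("RN", 3) > tau_at("RN", 2) && tau_at("RN", 2) > tau_at("RN", 1),
    en_faster_than_rn = tau_at("EN", 2) < tau_at("RN", 2),
    tau_grows_with_stimulus_timescale = rho < 0,
    reconstruction_ordering =
      mean_rec(1) < mean_rec(2) && mean_rec(2) < mean_rec(3),
    occlusion_beats_feedforward =
      all(pc_mse[occluded] < ff$mse_per_frame[occluded]))
  manifest$summary <- summary
  status("summary", TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
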