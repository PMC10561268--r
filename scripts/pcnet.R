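#!/usr/bin/env Rscript
# Thin command-line wrapper over the pcnet package.
#
#   Rscript scripts/pcnet.R generate --transform translate --classes 10 \
#       --speed 1 --shape 16 --seed 1 --out data.rds
#   Rscript scripts/pcnet.R train --data data.rds --paradigm continuous \
#       --epochs 10 --seed 1 --out fit.rds
#   Rscript scripts/pcnet.R reproduce --out results/ --seeds 1,2,3,4

suppressMessages(library(pcnet))
suppressMessages(library(optparse))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1)
  stop("usage: pcnet.R <generate|train|reproduce> [options]", call. = FALSE)
cmd <- argv[1]
rest <- argv[-1]

if (cmd == "generate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--transform", default = "translate"),
    make_option("--classes", type = "integer", default = 10L),
    make_option("--speed", type = "double", default = 1),
    make_option("--noise", action = "store_true", default = FALSE),
    make_option("--occlude", action = "store_true", default = FALSE),
    make_option("--shape", type = "integer", default = 16L),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", default = "dataset.rds"))), args = rest)
  ds <- make_dataset(opts$classes, opts$transform, speed = opts$speed,
                     noise = opts$noise, shape = c(opts$shape, opts$shape),
                     seed = opts$seed)
  if (opts$occlude) {
    region <- c(1, opts$shape, opts$shape - 4, opts$shape)
    ds$sequences <- lapply(ds$sequences, apply_occluder, region = region)
  }
  saveRDS(ds, opts$out)
  message("wrote ", opts$out)
} else if (cmd == "train") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--data", default = "dataset.rds"),
    make_option("--paradigm", default = "continuous"),
    make_option("--epochs", type = "integer", default = 10L),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", default = "fit.rds"))), args = rest)
  ds <- readRDS(opts$data)
  cfg <- study_config(image_shape = ds$image_shape)
  fit <- pcnet(ds, cfg, opts$paradigm, epochs = opts$epochs,
               seed = opts$seed)
  saveRDS(fit, opts$out)
  write.csv(fit$history, paste0(opts$out, ".history.csv"),
            row.names = FALSE)
  print(summary(fit))
  message("wrote ", opts$out)
} else if (cmd == "reproduce") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--out", default = "results"),
    make_option("--seeds", default = "1,2,3,4"),
    make_option("--classes", type = "integer", default = 10L),
    make_option("--epochs", type = "integer", default = 10L),
    make_option("--dry-run", dest = "dry_run", action = "store_true",
                default = FALSE))), args = rest)
  m <- run_reproduction(opts$out,
                        seeds = as.integer(strsplit(opts$seeds, ",")[[1]]),
                        n_classes = opts$classes, epochs = opts$epochs,
                        dry_run = opts$dry_run)
  if (opts$dry_run) print(m) else str(m$summary)
} else {
  stop("unknown command: ", cmd, call. = FALSE)
}
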