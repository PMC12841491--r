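#!/usr/bin/env Rscript
# Thin shell entry point over the package functions: either simulates a
# synthetic study into --data-dir, or loads an existing bundle from it, then
# runs the full pipeline and writes the report files to --out-dir.
#
# Usage:
#   Rscript scripts/run_pipeline.R --simulate --seed 7 \
#       --data-dir data/sim --out-dir results/run
#   Rscript scripts/run_pipeline.R --data-dir data/sim --cohort-size 180 \
#       --threshold 0.1 --n-iter 1000 --seed 7 --out-dir results/run

suppressMessages(library(cnvmask))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (!is.na(i) && i < length(args)) args[i + 1L] else default
}
has_flag <- function(flag) flag %in% args

seed <- as.integer(get_arg("--seed", "1"))
data_dir <- get_arg("--data-dir", "simdata")
out_dir <- get_arg("--out-dir", "results")
threshold <- as.numeric(get_arg("--threshold", "0.10"))
n_iter <- as.integer(get_arg("--n-iter", "1000"))
cohort_size <- get_arg("--cohort-size")

if (has_flag("--simulate")) {
  message("simulating cohort (seed ", seed, ") into ", data_dir)
  bundle <- simulate_cohort(sim_config(seed = seed))
  write_bundle(bundle, data_dir)
  if (is.null(cohort_size)) cohort_size <- bundle$config$n_samples
} else {
  message("loading bundle from ", data_dir)
  raw <- read_bundle(data_dir)
  bundle <- raw
}
if (is.null(cohort_size))
  cohort_size <- length(unique(bundle$calls$sample))

run <- run_pipeline(bundle, cohort_size = as.integer(cohort_size),
                    mask_threshold = threshold, n_iter = n_iter,
                    seed = seed, out_dir = out_dir)
print(run)
message("report written to ", out_dir)
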