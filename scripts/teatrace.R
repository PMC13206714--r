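#!/usr/bin/env Rscript
# Thin command-line wrapper over the teatrace package.
#
#   Rscript scripts/teatrace.R run <config.yaml> [--seed N] [--out DIR]
#   Rscript scripts/teatrace.R run --default    [--seed N] [--out DIR]
#
# `run` executes the full pipeline (simulate/ingest -> zone ATLD ->
# calibrate -> quantify -> summarize -> classify) from a YAML configuration
# whose keys mirror the arguments of teatrace::pipeline_config().

suppressPackageStartupMessages(library(teatrace))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0 || args[1] != "run") {
  cat("usage: Rscript scripts/teatrace.R run <config.yaml>|--default",
      "[--seed N] [--out DIR]\n")
  quit(status = if (length(args) == 0) 1 else 2)
}
args <- args[-1]

cfg <- NULL
seed <- NULL
out <- NULL
i <- 1
while (i <= length(args)) {
  if (args[i] == "--seed") { seed <- as.integer(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--out") { out <- args[i + 1]; i <- i + 2 }
  else if (args[i] == "--default") { cfg <- pipeline_config(); i <- i + 1 }
  else if (is.null(cfg)) { cfg <- read_pipeline_config(args[i]); i <- i + 1 }
  else stop("unknown argument: ", args[i])
}
if (is.null(cfg)) cfg <- pipeline_config()
if (!is.null(seed)) cfg$seed <- seed
if (!is.null(out)) cfg$out_dir <- out

res <- run_pipeline(cfg)
cat("pipeline complete;", length(res$artifacts), "artifacts in",
    cfg$out_dir, "\n")
for (f in res$artifacts) cat("  ", f, "\n")
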