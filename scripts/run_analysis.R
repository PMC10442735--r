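#!/usr/bin/env Rscript
# Thin command-line front-end over diabudget::run_full_analysis().
#
# Usage: Rscript scripts/run_analysis.R [--config <file>] --out <dir>
#          [--seed <int>] [--variance <frac>] [--no-cohort]

suppressPackageStartupMessages(library(diabudget))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(config = NULL, out = NULL, seed = 1L, variance = 0.10,
            cohort = TRUE)
i <- 1L
while (i <= length(args)) {
  a <- args[i]
  if (a == "--config") { opt$config <- args[i + 1L]; i <- i + 2L }
  else if (a == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
  else if (a == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (a == "--variance") {
    opt$variance <- as.numeric(args[i + 1L]); i <- i + 2L
  }
  else if (a == "--no-cohort") { opt$cohort <- FALSE; i <- i + 1L }
  else stop("unknown argument: ", a)
}
if (is.null(opt$out)) stop("--out <dir> is required")

manifest <- run_full_analysis(
  config = opt$config, out_dir = opt$out, seed = opt$seed,
  cohort = if (opt$cohort) cohort_spec() else NULL,
  variance = opt$variance)
cat("wrote", length(manifest$files), "files to", opt$out, "\n")
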