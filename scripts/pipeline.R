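#!/usr/bin/env Rscript
# Thin command-line wrapper over specdiv::run_pipeline() / report().
#
# Usage:
#   Rscript scripts/pipeline.R run    --seed 1 --out runs/demo [--resume]
#   Rscript scripts/pipeline.R report --out runs/demo
#
# The synthetic generator is configured through --rows/--cols/--regions;
# everything else uses the package defaults (see ?run_config).

suppressPackageStartupMessages({
  library(optparse)
  library(specdiv)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("run", "report")) {
  stop("usage: pipeline.R <run|report> [options]", call. = FALSE)
}
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "runs/out"),
  make_option("--rows", type = "integer", default = 96L),
  make_option("--cols", type = "integer", default = 96L),
  make_option("--regions", type = "integer", default = 21L),
  make_option("--alpha", type = "character", default = "adaptive",
              help = "adaptive, convex, or a fixed numeric alpha"),
  make_option("--resume", action = "store_true", default = FALSE)
)), args = args[-1])

if (cmd == "run") {
  alpha <- suppressWarnings(as.numeric(opts$alpha))
  if (is.na(alpha)) alpha <- opts$alpha
  cfg <- run_config(
    generator = landscape_config(rows = opts$rows, cols = opts$cols,
                                 n_regions = opts$regions),
    alpha = alpha)
  manifest <- run_pipeline(cfg, seed = opts$seed, out_dir = opts$out,
                           resume = opts$resume)
  cat("stages completed:", paste(names(manifest$stages), collapse = ", "), "\n")
} else {
  rep <- report(opts$out)
  cat(sprintf("report written to %s\n", file.path(opts$out, "report.json")))
  cat(sprintf("mean resistance %.1f%%, recovery %.1f%%, resilience %.1f%%\n",
              rep$response$resistance_pct$mean, rep$response$recovery_pct$mean,
              rep$response$resilience_pct$mean))
}
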