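#!/usr/bin/env Rscript
# Thin command-line wrapper over pairephys::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R [--config <yaml>] [--seed <int>]
#                                  [--out <dir>]
#
# The optional YAML config may override any default_config() argument
# (n_cells_per_class, n_connections, n_sweeps_per_epoch, n_intrinsic,
# leak_scale, alpha, scenarios).

suppressPackageStartupMessages(library(pairephys))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}

seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "pipeline_out")
cfg_file <- get_arg("--config")

overrides <- if (!is.null(cfg_file)) yaml::read_yaml(cfg_file) else list()
overrides$seed <- seed
cfg <- do.call(default_config,
               overrides[intersect(names(overrides),
                                   names(formals(default_config)))])

res <- run_pipeline(cfg, out_dir = out)
print(res)
message("report bundle written to ", out)
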