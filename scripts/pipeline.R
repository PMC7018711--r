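#!/usr/bin/env Rscript
# Thin command-line wrapper over burstlab::run_pipeline().
#
#   Rscript scripts/pipeline.R config.yaml
#
# The config file holds the flat keys of burstlab::run_config(); see
# ?run_config for the full list. Outputs (CSV/Newick, manifest, failure
# report) land in the configured output_dir.

suppressPackageStartupMessages(library(burstlab))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1) {
  cat("usage: Rscript scripts/pipeline.R <config.yaml>\n")
  quit(status = 2)
}
res <- run_pipeline(args[1])
if (nrow(res$failures)) {
  cat("stages with failures:\n")
  print(res$failures)
  quit(status = 1)
}
cat("pipeline complete;", nrow(res$manifest), "files written\n")
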