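#!/usr/bin/env Rscript

# Thin command-line wrapper over popgenpipe::run_pipeline(): reads a panel,
# applies a YAML configuration (defaults when omitted) and writes stage
# artifacts plus a manifest to the output directory.
#
# Usage: Rscript scripts/run_pipeline.R --panel <path> --format vcf \
#          [--config <yaml>] --out <dir> [--seed <int>]

suppressPackageStartupMessages({
  library(optparse)
  library(popgenpipe)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--panel", type = "character"),
  make_option("--format", type = "character", default = "vcf"),
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = 1)
)))

if (is.null(opt$panel)) {
  message("--panel is required")
  quit(status = 2)
}

cfg <- tryCatch({
  if (is.null(opt$config)) default_pipeline_config(seed = opt$seed)
  else read_pipeline_config(opt$config)
}, error = function(e) {
  message("configuration error: ", conditionMessage(e)); quit(status = 2)
})
if (!is.null(opt$config)) cfg$seed <- opt$seed

panel <- tryCatch(read_panel(opt$panel, opt$format), error = function(e) {
  message("input error: ", conditionMessage(e)); quit(status = 2)
})

res <- tryCatch(run_pipeline(panel, cfg, out_dir = opt$out),
                error = function(e) {
  message("pipeline failure: ", conditionMessage(e)); quit(status = 3)
})
print(res$manifest)
quit(status = 0)
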