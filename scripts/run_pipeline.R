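#!/usr/bin/env Rscript
# Thin shell wrapper over dispersalSSF::run_pipeline().
#
#   Rscript scripts/run_pipeline.R --config path/to/config.yml
#   Rscript scripts/run_pipeline.R --out pipeline_out --seed 1

suppressMessages({
  library(optparse)
  library(dispersalSSF)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML pipeline config; omit to use defaults"),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = 1L)
)))

cfg <- if (!is.null(opts$config)) {
  read_pipeline_config(opts$config)
} else {
  pipeline_config(out_dir = opts$out, rng_seed = opts$seed)
}
if (!is.null(opts$config)) {
  cfg$out_dir <- opts$out
  cfg$rng_seed <- opts$seed
}
res <- run_pipeline(cfg)
message("outputs written to ", res$out_dir)
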