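#!/usr/bin/env Rscript

## Thin shell entry point over idpensemble::run_pipeline().
## Usage:
##   Rscript scripts/pipeline.R [--config cfg.yaml] [--seed 1] [--out dir]

suppressMessages({
  library(optparse)
  library(idpensemble)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration (default: package demo config)"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the configuration seed"),
  make_option("--out", type = "character", default = NULL,
              help = "override the output directory")
)))

config <- if (!is.null(opts$config)) load_run_config(opts$config) else
  default_run_config()
if (!is.null(opts$seed)) config$seed <- opts$seed
if (!is.null(opts$out)) config$out_dir <- opts$out

res <- run_pipeline(config)
print(utils::head(res$ranking, 10))
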