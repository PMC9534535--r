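#!/usr/bin/env Rscript

# Thin shell entry point over numspike::run_experiment().
# Usage:
#   Rscript scripts/run_experiment.R [--config cfg.yaml] [--seed INT]
#     [--dataset numerosity|mnist|digit-fixture] [--out DIR] [--figures]

suppressPackageStartupMessages({
  library(optparse)
  library(numspike)
})

opt_list <- list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML experiment configuration"),
  make_option("--seed", type = "integer", default = NULL,
              help = "master seed (overrides the config)"),
  make_option("--dataset", type = "character", default = NULL,
              help = "numerosity, mnist or digit-fixture"),
  make_option("--out", type = "character", default = NULL,
              help = "output directory"),
  make_option("--figures", action = "store_true", default = FALSE,
              help = "render PNG figures from the report CSVs"))
opts <- parse_args(OptionParser(option_list = opt_list))

raw <- if (is.null(opts$config)) list() else yaml::read_yaml(opts$config)
if (!is.null(opts$seed)) raw$master_seed <- opts$seed
if (!is.null(opts$dataset)) raw$dataset <- opts$dataset
if (!is.null(opts$out)) raw$output_dir <- opts$out
if (opts$figures) raw$emit_figures <- TRUE

report <- run_experiment(validate_config(raw), verbose = TRUE)
print(report)
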