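#!/usr/bin/env Rscript
# Thin command-line wrapper over climpen::run_pipeline().
#
#   Rscript scripts/run_pipeline.R --scenario flat --seed 1 --out out/run
#
# Optional: --config path to a YAML/one-per-line "key: value" file with
# any validate_config() key; flags override file values.

suppressMessages(library(climpen))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

raw <- list()
cfg_path <- get_arg("--config")
if (!is.null(cfg_path)) {
  raw <- yaml::read_yaml(cfg_path)
}
if (!is.null(get_arg("--scenario"))) raw$scenario <- get_arg("--scenario")
if (!is.null(get_arg("--seed"))) raw$seed <- as.integer(get_arg("--seed"))
if (!is.null(get_arg("--out"))) raw$out_dir <- get_arg("--out")
if (!is.null(get_arg("--grid"))) {
  dims <- as.integer(strsplit(get_arg("--grid"), "x")[[1]])
  raw$n_lat <- dims[1]; raw$n_lon <- dims[2]
}

cfg <- tryCatch(validate_config(raw), error = function(e) {
  message("configuration error: ", conditionMessage(e)); quit(status = 1)
})
run <- tryCatch(run_pipeline(cfg), error = function(e) {
  message("pipeline failure: ", conditionMessage(e)); quit(status = 2)
})
print(run)
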