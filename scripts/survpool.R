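#!/usr/bin/env Rscript

# Thin command-line wrapper over the survpool package.
#
#   Rscript scripts/survpool.R simulate  --config cfg.yaml --out cohort.csv [--seed N]
#   Rscript scripts/survpool.R fit       --data cohort.csv --out fits.csv [--methods TDCM,PLR_AD]
#   Rscript scripts/survpool.R run-grid  --config cfg.yaml --out outdir [--reps N] [--methods ...]
#
# Exit codes: 0 success, 2 configuration error, 3 data-validation error,
# 4 estimation error, 1 other failure.

suppressPackageStartupMessages({
  library(survpool)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  message("usage: survpool.R <simulate|fit|run-grid> [options]")
  quit(status = 1)
}
cmd <- args[1]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--data", type = "character", default = NULL),
  make_option("--out", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--reps", type = "integer", default = NULL),
  make_option("--methods", type = "character", default = NULL),
  make_option("--quiet", action = "store_true", default = FALSE)
))
opt <- parse_args(parser, args = args[-1])
methods <- if (is.null(opt$methods)) NULL else strsplit(opt$methods, ",")[[1]]

status <- tryCatch({
  switch(cmd,
    "simulate" = {
      if (is.null(opt$out)) stop("--out is required")
      cmd_simulate(opt$config, opt$out, seed = opt$seed)
      if (!opt$quiet) message("wrote ", opt$out)
    },
    "fit" = {
      if (is.null(opt$data) || is.null(opt$out))
        stop("--data and --out are required")
      m <- if (is.null(methods)) METHODS else methods
      cmd_fit(opt$data, methods = m, out_path = opt$out)
      if (!opt$quiet) message("wrote ", opt$out)
    },
    "run-grid" = {
      if (is.null(opt$out)) stop("--out is required")
      cmd_run_grid(opt$config, opt$out, n_replicates = opt$reps,
                   methods = methods,
                   progress = if (opt$quiet) 0 else 50)
      if (!opt$quiet) message("wrote tables under ", opt$out)
    },
    stop("unknown command: ", cmd)
  )
  0L
},
survpool_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
survpool_data_error = function(e) { message("data error: ", conditionMessage(e)); 3L },
survpool_estimation_error = function(e) { message("estimation error: ", conditionMessage(e)); 4L },
error = function(e) { message("error: ", conditionMessage(e)); 1L })

quit(status = status)
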