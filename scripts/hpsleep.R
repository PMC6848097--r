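#!/usr/bin/env Rscript

# Thin shell entry point over the exported package functions.
#
#   Rscript scripts/hpsleep.R run        --out <dir> [--config <yaml>] [--seed N]
#                                        [--replicates N] [--k auto|3] [--folds N]
#   Rscript scripts/hpsleep.R simulate   --out <dir> [--config <yaml>] [--seed N]
#   Rscript scripts/hpsleep.R summarize  --nights <file> --out <file> [--min-nights 5]
#   Rscript scripts/hpsleep.R score      --items <file> --psqi <file> --out <dir>
#   Rscript scripts/hpsleep.R factors    --items <file> --out <dir> [--k auto|3] [--seed N]
#
# `run` executes the full pipeline; the other subcommands expose single
# stages for use on externally supplied tables.

suppressPackageStartupMessages(library(hpsleep))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("usage: hpsleep.R <subcommand> [--flag value ...]")
cmd <- args[1]
flags <- list()
i <- 2L
while (i <= length(args)) {
  if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
  flags[[substring(args[i], 3)]] <- args[i + 1L]
  i <- i + 2L
}
flag <- function(name, default = NULL) {
  if (!is.null(flags[[name]])) flags[[name]] else default
}

load_cohort_cfg <- function() {
  cfg <- if (!is.null(flag("config"))) read_config(flag("config")) else
    cohort_config()
  if (!is.null(flag("seed"))) cfg$seed <- as.integer(flag("seed"))
  cfg
}

switch(cmd,
  run = {
    cfg <- pipeline_config(
      out_dir = flag("out", "hpsleep_out"),
      cohort = load_cohort_cfg(),
      n_replicates = as.integer(flag("replicates", 10000)),
      k_factors = {
        k <- flag("k", "auto"); if (k == "auto") "auto" else as.integer(k)
      },
      folds = as.integer(flag("folds", 10)),
      min_nights = as.integer(flag("min-nights", 5)),
      seed = as.integer(flag("seed", 20260101))
    )
    run_pipeline(cfg)
  },
  simulate = {
    write_cohort(generate_cohort(load_cohort_cfg()), flag("out", "hpsleep_out"))
  },
  summarize = {
    nights <- read_table_csv(flag("nights"))
    write_table_csv(
      summarize_sleep(nights, min_nights = as.integer(flag("min-nights", 5))),
      flag("out", "sleep_summary.csv"))
  },
  score = {
    items <- read_table_csv(flag("items"))
    resp <- as.matrix(items[, -1]); rownames(resp) <- items$subject_id
    dir.create(flag("out", "."), showWarnings = FALSE, recursive = TRUE)
    key <- default_scoring_key()
    write_table_csv(merge(score_hps_total(resp, key),
                          score_hps_subscales_sum(resp, key),
                          by = "subject_id"),
                    file.path(flag("out", "."), "hps_scores.csv"))
    write_table_csv(score_psqi(read_table_csv(flag("psqi"))),
                    file.path(flag("out", "."), "psqi_scores.csv"))
  },
  factors = {
    items <- read_table_csv(flag("items"))
    resp <- as.matrix(items[, -1]); rownames(resp) <- items$subject_id
    k <- flag("k", "auto"); if (k != "auto") k <- as.integer(k)
    fit <- fit_hps_factors(resp, k = k, seed = as.integer(flag("seed", 1)))
    dir.create(flag("out", "."), showWarnings = FALSE, recursive = TRUE)
    write_table_csv(data.frame(item = rownames(fit$solution$pattern),
                               fit$solution$pattern,
                               communality = fit$solution$communalities),
                    file.path(flag("out", "."), "loadings.csv"))
    write_table_csv(as.data.frame(fit$solution$factor_corr),
                    file.path(flag("out", "."), "factor_corr.csv"))
    write_table_csv(fit$scores, file.path(flag("out", "."), "factor_scores.csv"))
    print(fit)
  },
  stop("unknown subcommand: ", cmd)
)
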