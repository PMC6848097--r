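# End-to-end pipeline --------------------------------------------------------

#' Build a pipeline configuration
#'
#' Paths, stage toggles, seeds and analysis options for [run_pipeline()].
#'
#' @param out_dir output directory.
#' @param cohort a [cohort_config()] (used by the simulate stage).
#' @param stages named logical vector switching stages on/off; a stage that
#'   is off leaves previously written outputs in place for downstream
#'   stages.
#' @param min_nights actigraphy inclusion threshold (default 5).
#' @param decile extreme-group tail fraction (default 0.1).
#' @param adjust_method multiple-test correction (default "BH").
#' @param n_replicates permutation replicates for the QQ envelope
#'   (default 10000; raise towards 1e6 for publication-grade envelopes).
#' @param folds cross-validation folds (default 10).
#' @param k_factors `"auto"` (parallel analysis) or fixed integer.
#' @param seed global seed for the analysis stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_config(),
                            stages = c(simulate = TRUE, summarize = TRUE,
                                       score = TRUE, factors = TRUE,
                                       associate = TRUE, permutation = TRUE,
                                       extremes = TRUE, cv = TRUE),
                            min_nights = 5L, decile = 0.1,
                            adjust_method = "BH", n_replicates = 10000L,
                            folds = 10L, k_factors = "auto", seed = 20260101L) {
  structure(list(out_dir = out_dir, cohort = cohort, stages = stages,
                 min_nights = min_nights, decile = decile,
                 adjust_method = adjust_method, n_replicates = n_replicates,
                 folds = folds, k_factors = k_factors, seed = as.integer(seed)),
            class = "pipeline_config")
}

# assemble the 21-column sleep panel (14 actigraphy + 7 PSQI variables)
# over the union of subjects; NA where an instrument is absent
.sleep_panel <- function(sleep_summary, psqi_scores) {
  ids <- union(sleep_summary$subject_id, psqi_scores$subject_id)
  panel <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (v in actigraphy_variables())
    panel[[v]] <- sleep_summary[[v]][match(ids, sleep_summary$subject_id)]
  for (v in psqi_variables())
    panel[[v]] <- psqi_scores[[v]][match(ids, psqi_scores$subject_id)]
  panel
}

#' Run the full analysis pipeline
#'
#' simulate -> summarize -> score -> factors -> associate -> permutation QQ
#' -> extreme groups -> cross-validated prediction, writing every stage's
#' table, the figures, and a run manifest into `config$out_dir`. Any stage
#' failure aborts with a stage-tagged error; outputs of completed stages
#' are retained.
#'
#' @param config a [pipeline_config()].
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  log_file <- out("run.log")
  on_stage <- function(name, expr) {
    hp_log("stage ", name, " ...", file = log_file)
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    hp_log("stage ", name, " done in ",
           round(as.numeric(Sys.time() - t0, units = "secs"), 2), " s",
           file = log_file)
    res
  }
  st <- config$stages

  if (isTRUE(st[["simulate"]])) on_stage("simulate", {
    write_cohort(generate_cohort(config$cohort), config$out_dir)
  })

  if (isTRUE(st[["summarize"]])) on_stage("summarize", {
    nights <- read_table_csv(out("nights.csv"))
    write_table_csv(summarize_sleep(nights, config$min_nights),
                    out("sleep_summary.csv"))
  })

  if (isTRUE(st[["score"]])) on_stage("score", {
    items <- read_table_csv(out("hps_items.csv"))
    resp <- as.matrix(items[, -1]); rownames(resp) <- items$subject_id
    key <- default_scoring_key(config$cohort$item_table)
    hps <- merge(score_hps_total(resp, key),
                 score_hps_subscales_sum(resp, key), by = "subject_id")
    write_table_csv(hps, out("hps_scores.csv"))
    write_table_csv(score_psqi(read_table_csv(out("psqi_items.csv"))),
                    out("psqi_scores.csv"))
  })

  if (isTRUE(st[["factors"]])) on_stage("factors", {
    items <- read_table_csv(out("hps_items.csv"))
    resp <- as.matrix(items[, -1]); rownames(resp) <- items$subject_id
    fit <- fit_hps_factors(resp, k = config$k_factors,
                           markers = split(config$cohort$item_table$item,
                                           config$cohort$item_table$factor),
                           seed = child_seed(config$seed, "factors"))
    write_table_csv(data.frame(item = rownames(fit$solution$pattern),
                               fit$solution$pattern,
                               communality = fit$solution$communalities),
                    out("loadings.csv"))
    write_table_csv(as.data.frame(fit$solution$factor_corr), out("factor_corr.csv"))
    write_table_csv(fit$scores, out("factor_scores.csv"))
  })

  scores <- NULL; panel <- NULL; covars <- NULL
  load_assoc_inputs <- function() {
    hps <- read_table_csv(out("hps_scores.csv"))
    fs <- read_table_csv(out("factor_scores.csv"))
    scores <<- merge(hps[, c("subject_id", "hps_total")], fs, by = "subject_id")
    panel <<- .sleep_panel(read_table_csv(out("sleep_summary.csv")),
                           read_table_csv(out("psqi_scores.csv")))
    subj <- read_table_csv(out("subjects.csv"))
    covars <<- subj[, c("subject_id", "age", "sex")]
    invisible(NULL)
  }

  if (isTRUE(st[["associate"]])) on_stage("associate", {
    load_assoc_inputs()
    assoc <- correlate_grid(scores, panel, covars,
                            adjust_method = config$adjust_method)
    write_table_csv(assoc, out("associations.csv"))
  })

  if (isTRUE(st[["permutation"]])) on_stage("permutation-qq", {
    if (is.null(scores)) load_assoc_inputs()
    ids <- scores$subject_id
    P <- as.matrix(scores[, -1])
    S <- as.matrix(panel[match(ids, panel$subject_id), -1])
    C <- as.matrix(covars[match(ids, covars$subject_id), -1])
    pm <- permute_and_score(P, S, C, n_replicates = config$n_replicates,
                            seed = child_seed(config$seed, "permutation"))
    env <- build_envelope(pm)
    write_table_csv(env, out("envelope.csv"))
    assoc <- read_table_csv(out("associations.csv"))
    pts <- qq_points(assoc$p, env)
    write_table_csv(pts, out("qq_observed.csv"))
    plot_qq(pts, out("qq_plot.png"))
  })

  if (isTRUE(st[["extremes"]])) on_stage("extremes", {
    if (is.null(scores)) load_assoc_inputs()
    ext <- extreme_group_tests(scores, "hps_total", panel, config$decile)
    write_table_csv(ext, out("extremes.csv"))
    g <- extreme_deciles(scores$hps_total, config$decile)
    v <- panel$isd_waso[match(scores$subject_id, panel$subject_id)]
    keep <- g != "excluded" & is.finite(v)
    boxplot_extremes(v[keep], droplevels(g[keep]), out("extremes_isd_waso.png"),
                     seed = child_seed(config$seed, "plots"),
                     ylab = "ISD of WASO (min)")
  })

  if (isTRUE(st[["cv"]])) on_stage("cv-predict", {
    if (is.null(scores)) load_assoc_inputs()
    subj <- read_table_csv(out("subjects.csv"))
    cov_cv <- subj[, c("subject_id", "age", "sex", "ses")]
    cv <- cv_predict_scores(scores, panel, cov_cv, k = config$folds,
                            seed = child_seed(config$seed, "cv"))
    write_table_csv(cv, out("cv_results.csv"))
  })

  on_stage("manifest", write_manifest(config))
  files <- list.files(config$out_dir, full.names = TRUE)
  invisible(stats::setNames(files, basename(files)))
}

# manifest: versions, seeds, and md5 of every numeric output, so a re-run
# with the same config and seeds is verifiably identical
write_manifest <- function(config) {
  csvs <- sort(list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE))
  manifest <- list(
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("hpsleep")),
    seed = config$seed,
    cohort_seed = config$cohort$seed,
    options = list(min_nights = config$min_nights, decile = config$decile,
                   adjust_method = config$adjust_method,
                   n_replicates = config$n_replicates, folds = config$folds),
    outputs = as.list(stats::setNames(unname(tools::md5sum(csvs)),
                                      basename(csvs)))
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  file.path(config$out_dir, "manifest.yaml")
}

#' Jittered extreme-group boxplot
#'
#' Boxes span the interquartile range with the median line; whiskers extend
#' to the furthest observation within 1.5 IQR of the quartiles; individual
#' observations are overdrawn with seeded horizontal jitter.
#'
#' @param values numeric vector.
#' @param groups factor with two levels.
#' @param out_path output figure path (`.png` or `.svg`).
#' @param seed jitter seed.
#' @param ylab y-axis label.
#' @return `out_path`, invisibly.
#' @export
boxplot_extremes <- function(values, groups, out_path, seed = 1L,
                             ylab = "value") {
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0L)) stop("empty group")
  open_dev(out_path, width = 5, height = 5)
  on.exit(grDevices::dev.off())
  graphics::boxplot(values ~ groups, range = 1.5, outline = FALSE,
                    col = "gray92", ylab = ylab, xlab = "")
  set.seed(seed)
  x <- as.integer(groups) + stats::runif(length(values), -0.18, 0.18)
  graphics::points(x, values, pch = 16, col = grDevices::adjustcolor("black", 0.4))
  invisible(out_path)
}
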