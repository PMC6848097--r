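# shared fixtures, all generated in code

small_config <- function(n = 300, seed = 11, ...) {
  cohort_config(n_subjects = n, n_actigraphy = n, seed = seed, ...)
}

# multiply every trait coefficient by `mult` (strong-effect cohorts for
# qualitative direction checks)
scale_effects <- function(config, mult) {
  tr <- c("core", "vitality", "ordinariness")
  for (f in c("level_effects", "variability_effects", "psqi_effects"))
    config[[f]][, tr] <- config[[f]][, tr] * mult
  config
}

# full per-subject analysis tables (scores incl. factor scores, 21-variable
# sleep panel, covariates) for one cohort config; k fixed to 3 to keep
# replicate loops affordable
cohort_tables <- function(cfg, k = 3) {
  co <- generate_cohort(cfg)
  ss <- summarize_sleep(co$nights)
  key <- default_scoring_key(cfg$item_table)
  fit <- fit_hps_factors(co$items, k = k,
                         markers = split(cfg$item_table$item, cfg$item_table$factor))
  scores <- merge(score_hps_total(co$items, key), fit$scores, by = "subject_id")
  panel <- hpsleep:::.sleep_panel(ss, score_psqi(co$psqi))
  list(cohort = co, scores = scores, panel = panel,
       covars = co$subjects[, c("subject_id", "age", "sex")], fit = fit)
}

# aligned matrices for the permutation machinery
qq_blocks <- function(tb) {
  ids <- tb$scores$subject_id
  list(P = as.matrix(tb$scores[, -1]),
       S = as.matrix(tb$panel[match(ids, tb$panel$subject_id), -1]),
       C = as.matrix(tb$covars[match(ids, tb$covars$subject_id), -1]))
}

# hand-rolled nights for exact-arithmetic checks
make_nights <- function(subject_id, onset, offset, latency, nwak, waso, duration) {
  data.frame(subject_id = subject_id, night_index = seq_along(onset),
             sleep_onset_time = onset, sleep_offset_time = offset,
             sleep_onset_latency = latency, nwak = nwak, waso = waso,
             sleep_duration = duration, stringsAsFactors = FALSE)
}
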