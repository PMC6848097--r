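# Cohort configuration ------------------------------------------------------
#
# The generator emulates a population cohort of older adults (ages 60-82)
# who completed a 44-item true/false hypomanic-personality questionnaire and
# contributed either ~7 nights of actigraphy, a PSQI assessment, or both.
# Three correlated latent factors (hypomanic core, social vitality,
# ordinariness) drive item endorsement through a probit threshold model and,
# via configurable coefficients, both the person-level mean and the
# night-to-night variability of the sleep parameters.

.sleep_params <- c("latency", "onset", "duration", "nwak", "waso")
.trait_names <- c("core", "vitality", "ordinariness")
.effect_cols <- c(.trait_names, "age", "sex")

.effect_row <- function(core = 0, vitality = 0, ordinariness = 0, age = 0, sex = 0) {
  c(core = core, vitality = vitality, ordinariness = ordinariness,
    age = age, sex = sex)
}

.effect_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

#' Default item table for the 44-item hypomanic personality instrument
#'
#' Each item is assigned to exactly one latent factor with a loading in
#' `[0, 1)` and a probit threshold. Items on the ordinariness factor are
#' keyed negatively with respect to the hypomanic pole (endorsing them
#' indicates *less* hypomanic tendency), mirroring how reverse-keyed items
#' behave in the real instrument.
#'
#' @return data.frame with columns `item`, `factor`, `loading`, `threshold`,
#'   `key` (+1 / -1 relative to the hypomanic pole).
#' @export
default_item_table <- function() {
  n_core <- 16L; n_vit <- 15L; n_ord <- 13L
  fac <- rep(c("core", "vitality", "ordinariness"), c(n_core, n_vit, n_ord))
  # deterministic spread of loadings/thresholds; chosen to resemble a real
  # well-constructed scale (moderate-to-strong loadings, mixed difficulty)
  load_cycle <- c(0.75, 0.55, 0.65, 0.50, 0.70, 0.60, 0.45, 0.68)
  thr_cycle <- c(0.5, -0.3, 0.1, 0.8, -0.6, 0.3, 0.0, -0.2, 0.6, -0.4)
  n <- n_core + n_vit + n_ord
  data.frame(
    item = sprintf("i%02d", seq_len(n)),
    factor = fac,
    loading = rep_len(load_cycle, n),
    threshold = rep_len(thr_cycle, n),
    key = ifelse(fac == "ordinariness", -1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Build a cohort configuration
#'
#' Returns the full set of generator parameters with defaults that encode
#' the study conditions: ages 60-82, roughly balanced sex, 5-7 actigraphy
#' nights averaging 6.9, a three-correlated-factor item model, and small
#' cross-domain effects of the personality factors on sleep level and
#' night-to-night variability (signs follow the hypomanic-vulnerability
#' literature: higher core, worse and more variable sleep; ordinariness the
#' opposite). Any element can be overridden via `...`.
#'
#' @param n_subjects number of subjects (default 1766, the PSQI subsample
#'   size; actigraphy is recorded for a random `n_actigraphy` of them).
#' @param n_actigraphy number of subjects with an actigraphy recording
#'   (default 771). Use `n_actigraphy = n_subjects` for full overlap.
#' @param seed global RNG seed; per-stage child seeds are derived from it
#'   via [child_seed()].
#' @param ... named overrides of any default component.
#' @return object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_subjects = 200, n_actigraphy = 200, seed = 1)
#' @export
cohort_config <- function(n_subjects = 1766L, n_actigraphy = 771L,
                          seed = 20260101L, ...) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_actigraphy = as.integer(min(n_actigraphy, n_subjects)),
    seed = as.integer(seed),
    age_range = c(60, 82),
    p_female = 0.48,
    # latent factor correlations (core, vitality, ordinariness): core and
    # vitality share hypomanic content; ordinariness opposes the core
    factor_corr = matrix(c(1, 0.40, -0.30,
                           0.40, 1, -0.10,
                           -0.30, -0.10, 1), 3, 3,
                         dimnames = list(.trait_names, .trait_names)),
    item_table = default_item_table(),
    # nights per subject: mean 6.9 (most wear the device the full week)
    nights_dist = c("5" = 0.02, "6" = 0.06, "7" = 0.92),
    # person-level baselines: mean, between-person SD of the mean,
    # log night-to-night SD baseline, between-person SD of that log-SD.
    # onset in minutes after noon (680 = 23:20); durations/latency/waso in
    # minutes; nwak as a Poisson log-rate.
    sleep_base = list(
      latency  = list(meanlog = log(14), sd_meanlog = 0.45,
                      log_sdlog = log(0.40), sd_log_sdlog = 0.25),
      onset    = list(mean = 680, sd_mean = 40,
                      log_sd = log(25), sd_log_sd = 0.30),
      duration = list(mean = 420, sd_mean = 35,
                      log_sd = log(28), sd_log_sd = 0.30),
      nwak     = list(lograte = log(2.2), sd_lograte = 0.35),
      waso     = list(mean = 40, sd_mean = 12,
                      log_sd = log(16), sd_log_sd = 0.30)
    ),
    # effects of (core, vitality, ordinariness, age - 70, sex[female=1])
    # on the person-level mean (level_effects) and on the log of the
    # person-level night SD (variability_effects). Units: minutes per unit
    # latent SD for linear parameters; log-scale for latency/nwak.
    level_effects = .effect_matrix(list(
      latency  = .effect_row(core = 0.04, vitality = 0.03, ordinariness = -0.03,
                             age = 0.005, sex = 0.05),
      onset    = .effect_row(age = -1.0, sex = -5),
      duration = .effect_row(core = -3, vitality = -2, ordinariness = 1,
                             age = -0.8, sex = 8),
      nwak     = .effect_row(core = 0.04, vitality = 0.03, ordinariness = -0.02,
                             age = 0.010, sex = -0.10),
      waso     = .effect_row(core = 1.2, vitality = 1.0, ordinariness = -1,
                             age = 0.40, sex = -2)
    )),
    variability_effects = .effect_matrix(list(
      latency  = .effect_row(vitality = 0.03, ordinariness = -0.01),
      onset    = .effect_row(core = 0.04, vitality = 0.04),
      duration = .effect_row(core = 0.04, vitality = 0.035, age = 0.005),
      nwak     = .effect_row(),   # awakenings are Poisson: variability follows the rate
      waso     = .effect_row(core = 0.042, vitality = 0.02, ordinariness = -0.03,
                             age = 0.005)
    )),
    # effects on the latent drivers of PSQI item responses; signs mirror the
    # pattern that core predicts worse, ordinariness better perceived sleep
    psqi_effects = .effect_matrix(list(
      latency_log  = .effect_row(core = 0.04, vitality = -0.035, ordinariness = -0.04,
                                 age = 0.004),
      duration_h   = .effect_row(core = -0.09, vitality = 0.03, ordinariness = 0.07,
                                 age = -0.01),
      quality      = .effect_row(core = 0.15, vitality = -0.06, ordinariness = -0.14),
      disturbance  = .effect_row(core = 0.10, vitality = 0.02, ordinariness = -0.08,
                                 age = 0.01),
      sleepiness   = .effect_row(core = 0.12, vitality = 0.07, ordinariness = -0.10),
      medication   = .effect_row(age = 0.015),
      bedtime      = .effect_row(age = -0.8, sex = -4),
      getup        = .effect_row(age = -0.5)
    )),
    # residual scales
    noise_scales = list(
      psqi_latent = 1.0,       # SD of each PSQI latent residual
      psqi_duration_h = 0.9,   # SD of reported duration (hours)
      psqi_bedtime = 45,       # SD of reported bedtime (minutes)
      psqi_getup = 40,
      ses = 1.0                # socioeconomic index residual SD
    ),
    # socioeconomic status: standardized index, positively related to
    # social vitality so that vitality is partly "explained" by SES in
    # incremental-prediction contrasts
    ses_effects = .effect_row(vitality = 0.45, age = -0.01),
    max_resample = 100L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

#' Switch off every cross-domain effect (null configuration)
#'
#' Zeroes all coefficients of the latent personality factors on sleep level,
#' sleep variability, and PSQI latents, leaving age/sex effects and all
#' within-domain structure intact. Used for type-I-error calibration.
#'
#' @param config a `cohort_config`.
#' @return modified `cohort_config`.
#' @export
null_config <- function(config) {
  for (f in c("level_effects", "variability_effects", "psqi_effects")) {
    config[[f]][, .trait_names] <- 0
  }
  config$ses_effects[.trait_names] <- 0
  validate_config(config)
  config
}

#' Validate a cohort configuration
#'
#' Checks symmetry and positive definiteness of the factor correlation
#' matrix, probability normalization, loading ranges, and positivity of all
#' scale parameters.
#'
#' @param config a `cohort_config`.
#' @return the config, invisibly; stops with a configuration error otherwise.
#' @export
validate_config <- function(config) {
  fc <- config$factor_corr
  if (!isTRUE(all.equal(fc, t(fc), tolerance = 1e-10)))
    stop("configuration error: factor_corr must be symmetric")
  ev <- eigen(fc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("configuration error: factor_corr must be positive definite")
  if (any(diag(fc) != 1))
    stop("configuration error: factor_corr must have unit diagonal")
  nd <- config$nights_dist
  if (abs(sum(nd) - 1) > 1e-8 || any(nd < 0))
    stop("configuration error: nights_dist must be a probability vector")
  it <- config$item_table
  if (nrow(it) != 44L) stop("configuration error: item_table must have 44 items")
  if (any(it$loading < 0 | it$loading >= 1))
    stop("configuration error: loadings must lie in [0, 1)")
  if (!all(it$factor %in% .trait_names))
    stop("configuration error: item factor assignments must be core/vitality/ordinariness")
  if (anyDuplicated(it$item)) stop("configuration error: duplicate item ids")
  if (config$p_female < 0 || config$p_female > 1)
    stop("configuration error: p_female must be a probability")
  sds <- c(
    vapply(config$sleep_base, function(b)
      min(unlist(b[grep("^sd_", names(b))])), numeric(1)),
    unlist(config$noise_scales)
  )
  if (any(sds <= 0)) stop("configuration error: all SDs must be > 0")
  invisible(config)
}

#' Read / write a cohort configuration as YAML
#'
#' Only fields that differ from the defaults need to be present in the file;
#' matrices are stored row-wise with their dimnames.
#'
#' @param path YAML file path.
#' @param config a `cohort_config` (for writing).
#' @return `read_config()`: a `cohort_config`; `write_config()`: `path`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  to_mat <- function(x) {
    m <- do.call(rbind, lapply(x, unlist))
    rownames(m) <- names(x)
    m[, .effect_cols, drop = FALSE]
  }
  args <- list()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    args[[nm]] <- switch(nm,
      factor_corr = {
        m <- do.call(rbind, lapply(v, unlist))
        dimnames(m) <- list(.trait_names, .trait_names)
        m
      },
      level_effects = , variability_effects = , psqi_effects = to_mat(v),
      item_table = as.data.frame(v, stringsAsFactors = FALSE),
      nights_dist = unlist(v),
      ses_effects = unlist(v)[.effect_cols],
      age_range = unlist(v),
      v
    )
  }
  do.call(cohort_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  ser <- unclass(config)
  mat_to_list <- function(m) {
    out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
    names(out) <- rownames(m)
    out
  }
  for (nm in c("factor_corr", "level_effects", "variability_effects", "psqi_effects"))
    ser[[nm]] <- mat_to_list(ser[[nm]])
  ser$item_table <- as.list(config$item_table)
  ser$nights_dist <- as.list(config$nights_dist)
  ser$ses_effects <- as.list(config$ses_effects)
  yaml::write_yaml(ser, path)
  path
}
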