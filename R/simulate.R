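# Synthetic cohort generation ----------------------------------------------

# covariate/effect design row for one subject: (core, vitality,
# ordinariness, age - 70, sex)
.effect_design <- function(subjects) {
  cbind(core = subjects$latent_core,
        vitality = subjects$latent_vitality,
        ordinariness = subjects$latent_ordinariness,
        age = subjects$age - 70,
        sex = subjects$sex)
}

#' Generate the subject-level table
#'
#' Ages are uniform on the configured range, sex Bernoulli
#' (0 = male, 1 = female), and the three latent personality factors are
#' drawn from the configured 3-variate normal correlation structure. A
#' standardized socioeconomic index (SES) is generated with a configurable
#' loading on social vitality. A seeded random subset of `n_actigraphy`
#' subjects is flagged as having an actigraphy recording.
#'
#' The latent factor columns are ground truth for recovery tests only; the
#' analysis stages never read them (see [write_cohort()], which splits them
#' into a separate truth file).
#'
#' @param config a [cohort_config()].
#' @return data.frame: `subject_id`, `age`, `sex`, `ses`, `actigraphy`
#'   (0/1), plus `latent_core`, `latent_vitality`, `latent_ordinariness`.
#' @export
generate_subjects <- function(config) {
  validate_config(config)
  set.seed(child_seed(config$seed, "subjects"))
  n <- config$n_subjects
  z <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(config$factor_corr)
  colnames(z) <- .trait_names
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1, config$p_female)
  x <- cbind(z, age = age - 70, sex = sex)
  ses <- drop(x %*% config$ses_effects) +
    stats::rnorm(n, 0, config$noise_scales$ses)
  acti <- integer(n)
  acti[sample.int(n, config$n_actigraphy)] <- 1L
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = round(age, 1),
    sex = sex,
    ses = round(ses, 4),
    actigraphy = acti,
    latent_core = z[, "core"],
    latent_vitality = z[, "vitality"],
    latent_ordinariness = z[, "ordinariness"],
    stringsAsFactors = FALSE
  )
}

#' Generate dichotomous questionnaire item responses
#'
#' Probit threshold model on a standardized item latent: for an item with
#' loading `a` on factor `F` and threshold `tau`, the latent response is
#' `y* = a*F + sqrt(1 - a^2)*e` with `e ~ N(0,1)`, and the item is endorsed
#' when `y* > tau`, i.e. `P(x = 1 | F) = pnorm((a*F - tau)/sqrt(1 - a^2))`.
#' Because `y*` is standard normal, the marginal endorsement rate is
#' `pnorm(-tau)` and the implied tetrachoric correlation between items
#' `i, j` is `a_i * a_j * corr(F_i, F_j)` — a closed form used as the
#' oracle for the factor-analysis machinery.
#'
#' @param subjects output of [generate_subjects()].
#' @param config a [cohort_config()].
#' @return integer matrix (subjects x 44 items) of 0/1 responses, with
#'   `rownames` = subject ids and `colnames` = item ids.
#' @export
generate_item_responses <- function(subjects, config) {
  validate_config(config)
  set.seed(child_seed(config$seed, "items"))
  it <- config$item_table
  fmat <- as.matrix(subjects[, paste0("latent_", it$factor)])
  n <- nrow(subjects)
  a <- matrix(it$loading, n, nrow(it), byrow = TRUE)
  tau <- matrix(it$threshold, n, nrow(it), byrow = TRUE)
  ystar <- a * fmat + sqrt(1 - a^2) * matrix(stats::rnorm(n * nrow(it)), n)
  x <- (ystar > tau) + 0L
  dimnames(x) <- list(subjects$subject_id, it$item)
  x
}

# draw with truncation by resampling (no point masses at the bounds);
# give up after config$max_resample attempts
.resample_trunc <- function(draw, lo, hi, max_resample) {
  x <- draw()
  bad <- which(x <= lo | x >= hi)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > max_resample)
      stop("truncation resampling failed after ", max_resample, " attempts")
    x[bad] <- draw()[bad]
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Generate the night-level actigraphy table
#'
#' Each subject flagged `actigraphy == 1` contributes 5-7 nights (drawn
#' from `nights_dist`). Per subject, the person-level mean of each sleep
#' parameter is linear — and the log of the person-level night-to-night SD
#' log-linear — in the latent traits, centered age, and sex, plus a normal
#' person-level random effect. Nightly draws: sleep-onset time normal
#' (minutes after noon), duration normal, latency lognormal, awakenings
#' (NWAK) Poisson with person-level rate, WASO gamma with person-level mean
#' and SD. Implausible draws are rejected and resampled (duration within
#' (120, 720) min, latency < 300 min, WASO < 400 min, NWAK < 30). The
#' sleep-offset clock time is onset + duration + WASO, so time in bed
#' (latency + duration + WASO) is internally consistent.
#'
#' @param subjects output of [generate_subjects()].
#' @param config a [cohort_config()].
#' @return data.frame of night records: `subject_id`, `night_index`,
#'   `sleep_onset_time` / `sleep_offset_time` ("HH:MM"), and
#'   `sleep_onset_latency`, `nwak`, `waso`, `sleep_duration` (minutes).
#' @export
generate_nights <- function(subjects, config) {
  validate_config(config)
  set.seed(child_seed(config$seed, "nights"))
  sub <- subjects[subjects$actigraphy == 1L, , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L) stop("no subjects flagged for actigraphy")
  x <- .effect_design(sub)
  le <- config$level_effects; ve <- config$variability_effects
  b <- config$sleep_base
  mx <- config$max_resample

  nn <- as.integer(names(config$nights_dist))[
    sample.int(length(config$nights_dist), n, replace = TRUE,
               prob = config$nights_dist)]
  idx <- rep(seq_len(n), nn)            # subject row per night
  m <- length(idx)

  person <- function(base, eff_row, sd_between) {
    base + drop(x %*% eff_row) + stats::rnorm(n, 0, sd_between)
  }
  # person-level parameters
  lat_mu <- person(b$latency$meanlog, le["latency", ], b$latency$sd_meanlog)
  lat_sd <- exp(person(b$latency$log_sdlog, ve["latency", ], b$latency$sd_log_sdlog))
  ons_mu <- person(b$onset$mean, le["onset", ], b$onset$sd_mean)
  ons_sd <- exp(person(b$onset$log_sd, ve["onset", ], b$onset$sd_log_sd))
  dur_mu <- person(b$duration$mean, le["duration", ], b$duration$sd_mean)
  dur_sd <- exp(person(b$duration$log_sd, ve["duration", ], b$duration$sd_log_sd))
  nwk_la <- exp(person(b$nwak$lograte, le["nwak", ], b$nwak$sd_lograte))
  was_mu <- pmax(person(b$waso$mean, le["waso", ], b$waso$sd_mean), 2)
  was_sd <- exp(person(b$waso$log_sd, ve["waso", ], b$waso$sd_log_sd))

  latency <- .resample_trunc(function() stats::rlnorm(m, lat_mu[idx], lat_sd[idx]),
                             0, 300, mx)
  onset <- .resample_trunc(function() stats::rnorm(m, ons_mu[idx], ons_sd[idx]),
                           480, 1020, mx)     # 20:00 .. 05:00 after noon
  duration <- .resample_trunc(function() stats::rnorm(m, dur_mu[idx], dur_sd[idx]),
                              120, 720, mx)
  nwak <- .resample_trunc(function() stats::rpois(m, nwk_la[idx]), -1, 30, mx)
  shape <- (was_mu / was_sd)^2
  rate <- was_mu / was_sd^2
  waso <- .resample_trunc(function() stats::rgamma(m, shape[idx], rate[idx]),
                          -1e-9, 400, mx)

  # joint plausibility: the final awakening must fall before the next noon,
  # otherwise the stored offset clock time would wrap past the linearization
  # reference; violating nights are redrawn as a whole
  bad <- which(onset + duration + waso >= 1410)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > mx) stop("truncation resampling failed after ", mx, " attempts")
    i <- idx[bad]
    onset[bad] <- stats::rnorm(length(bad), ons_mu[i], ons_sd[i])
    duration[bad] <- stats::rnorm(length(bad), dur_mu[i], dur_sd[i])
    waso[bad] <- stats::rgamma(length(bad), shape[i], rate[i])
    keep <- onset[bad] > 480 & onset[bad] < 1020 &
      duration[bad] > 120 & duration[bad] < 720 & waso[bad] < 400 &
      onset[bad] + duration[bad] + waso[bad] < 1410
    bad <- bad[!keep]
  }

  offset <- onset + duration + waso
  data.frame(
    subject_id = sub$subject_id[idx],
    night_index = sequence(nn),
    sleep_onset_time = format_clock_time(onset + 720),
    sleep_offset_time = format_clock_time(offset + 720),
    sleep_onset_latency = round(latency, 1),
    nwak = nwak,
    waso = round(waso, 1),
    sleep_duration = round(duration, 1),
    stringsAsFactors = FALSE
  )
}

# ordinal item from a latent value via increasing thresholds -> 0..length(thr)
.ordinalize <- function(latent, thr) {
  out <- integer(length(latent))
  for (t in thr) out <- out + (latent > t)
  out
}

#' Generate PSQI item responses
#'
#' Item-level self-report responses driven by latent components (reported
#' latency, reported duration, subjective quality, disturbances, daytime
#' sleepiness, medication use, bed and get-up times), each linear in the
#' personality factors, centered age, and sex per `config$psqi_effects`,
#' plus standard-normal residuals. Ordinal frequency items are obtained by
#' thresholding their latent component.
#'
#' @param subjects output of [generate_subjects()].
#' @param config a [cohort_config()].
#' @return data.frame with `subject_id`, reported `bedtime` and
#'   `getup_time` ("HH:MM"), `latency_min`, `latency_freq` (0-3),
#'   `duration_h`, `quality` (0-3), disturbance items `d1`..`d9` (0-3),
#'   `medication` (0-3), `sleepiness` (0-3), `enthusiasm` (0-3).
#' @export
generate_psqi <- function(subjects, config) {
  validate_config(config)
  set.seed(child_seed(config$seed, "psqi"))
  n <- nrow(subjects)
  x <- .effect_design(subjects)
  pe <- config$psqi_effects
  ns <- config$noise_scales
  lat_comp <- function(row, sd = ns$psqi_latent)
    drop(x %*% pe[row, ]) + stats::rnorm(n, 0, sd)

  lat <- lat_comp("latency_log", 0.45)
  latency_min <- pmax(round(exp(log(18) + lat)), 1)
  latency_freq <- .ordinalize(lat + stats::rnorm(n, 0, 0.6), c(0.2, 0.9, 1.6))
  duration_h <- round(pmin(pmax(
    7.2 + drop(x %*% pe["duration_h", ]) + stats::rnorm(n, 0, ns$psqi_duration_h),
    3), 11), 1)
  bedtime <- 650 + drop(x %*% pe["bedtime", ]) + stats::rnorm(n, 0, ns$psqi_bedtime)
  getup <- 1130 + drop(x %*% pe["getup", ]) + stats::rnorm(n, 0, ns$psqi_getup)
  getup <- pmax(getup, bedtime + 60 * duration_h + 15)  # time in bed > reported sleep
  qual <- lat_comp("quality")
  dist_l <- lat_comp("disturbance")
  dmat <- vapply(1:9, function(j)
    .ordinalize(dist_l + stats::rnorm(n, 0, 1.1), c(1.0, 2.2, 3.2)), integer(n))
  colnames(dmat) <- paste0("d", 1:9)
  med <- .ordinalize(lat_comp("medication"), c(1.5, 2.1, 2.6))
  sleepy <- .ordinalize(lat_comp("sleepiness"), c(0.8, 1.8, 2.7))
  enth <- .ordinalize(lat_comp("sleepiness"), c(1.1, 2.0, 2.9))

  data.frame(
    subject_id = subjects$subject_id,
    bedtime = format_clock_time(bedtime + 720),
    getup_time = format_clock_time(getup + 720),
    latency_min = latency_min,
    latency_freq = latency_freq,
    duration_h = duration_h,
    quality = .ordinalize(qual, c(0.3, 1.3, 2.2)),
    dmat,
    medication = med,
    sleepiness = sleepy,
    enthusiasm = enth,
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic cohort
#'
#' Runs all four generation stages from one configuration.
#'
#' @param config a [cohort_config()].
#' @return list with elements `subjects`, `items`, `nights`, `psqi`,
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  subjects <- generate_subjects(config)
  list(
    subjects = subjects,
    items = generate_item_responses(subjects, config),
    nights = generate_nights(subjects, config),
    psqi = generate_psqi(subjects, config),
    config = config
  )
}

#' Write a cohort to CSV files
#'
#' Writes `subjects.csv` (id, age, sex, ses, actigraphy flag),
#' `truth.csv` (id + latent factor columns; consumed only by recovery
#' tests, never by analysis stages), `nights.csv`, `hps_items.csv`, and
#' `psqi_items.csv` as RFC-4180 CSV with header row and '.' decimal
#' separator; clock times as HH:MM.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- cohort$subjects
  truth_cols <- grep("^latent_", names(s), value = TRUE)
  paths <- c(
    subjects = write_table_csv(s[, setdiff(names(s), truth_cols)],
                               file.path(dir, "subjects.csv")),
    truth = write_table_csv(s[, c("subject_id", truth_cols)],
                            file.path(dir, "truth.csv")),
    nights = write_table_csv(cohort$nights, file.path(dir, "nights.csv")),
    hps_items = write_table_csv(
      data.frame(subject_id = rownames(cohort$items), cohort$items,
                 stringsAsFactors = FALSE),
      file.path(dir, "hps_items.csv")),
    psqi_items = write_table_csv(cohort$psqi, file.path(dir, "psqi_items.csv"))
  )
  invisible(paths)
}
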