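# Questionnaire scoring ------------------------------------------------------

#' Build a scoring key for the 44-item instrument
#'
#' The key fixes, per item, the keyed direction relative to the hypomanic
#' pole (+1: endorsing indicates hypomanic tendency; -1: reverse-keyed) and
#' the subscale assignment (`core`, `vitality`, `ordinariness`, or `none`).
#' The direction is decided once (from the rotated loading signs or, as
#' here, from the generating item table) and frozen, so sum-scores cannot
#' flip sign across runs.
#'
#' @param item_table data.frame with columns `item`, `factor`, `key`
#'   (defaults to [default_item_table()]).
#' @return data.frame with columns `item`, `subscale`, `direction`.
#' @export
default_scoring_key <- function(item_table = default_item_table()) {
  data.frame(item = item_table$item,
             subscale = item_table$factor,
             direction = item_table$key,
             stringsAsFactors = FALSE)
}

.keyed <- function(responses, direction) {
  # keyed response toward the hypomanic pole: x for +, 1 - x for -
  sweep(responses * matrix(direction, nrow(responses), ncol(responses),
                           byrow = TRUE),
        2, (1 - direction) / 2, "+")
}

.check_key <- function(responses, key) {
  unknown <- setdiff(colnames(responses), key$item)
  if (length(unknown))
    stop("key mismatch: no key entry for item(s) ",
         paste(utils::head(unknown, 3), collapse = ", "))
  missing <- setdiff(key$item, colnames(responses))
  if (length(missing))
    stop("key mismatch: response matrix lacks item(s) ",
         paste(utils::head(missing, 3), collapse = ", "))
  bad <- responses[!is.na(responses)]
  if (!all(bad %in% c(0, 1))) stop("responses must be binary (0/1) or missing")
  key[match(colnames(responses), key$item), ]
}

#' HPS total sum-score
#'
#' Sum of the keyed item responses toward the hypomanic pole (reverse-keyed
#' items contribute `1 - x`). Subjects with any missing item are excluded
#' (complete-response policy; the exclusion count is logged).
#'
#' @param responses subjects x items binary matrix with item-id colnames and
#'   subject-id rownames.
#' @param key scoring key from [default_scoring_key()].
#' @return data.frame `subject_id`, `hps_total` (0-44 for 44 items).
#' @export
score_hps_total <- function(responses, key = default_scoring_key()) {
  k <- .check_key(responses, key)
  complete <- stats::complete.cases(responses)
  if (any(!complete))
    hp_log("score_hps_total: excluded ", sum(!complete),
           " subject(s) with incomplete responses")
  r <- responses[complete, , drop = FALSE]
  data.frame(subject_id = rownames(r),
             hps_total = rowSums(.keyed(r, k$direction)),
             stringsAsFactors = FALSE)
}

#' Unweighted subscale sum-scores
#'
#' Per-subscale keyed sums. With `pole = "native"` (default) the
#' ordinariness subscale is scored toward its own pole (endorsing
#' ordinariness content raises the score), i.e. reverse-keyed relative to
#' the hypomanic pole, which is how the subscale correlates in the
#' association tables. With `pole = "hypomanic"` every subscale is keyed
#' toward the hypomanic pole, so the three sums plus any unassigned items
#' add up to the total score exactly.
#'
#' @inheritParams score_hps_total
#' @param pole `"native"` or `"hypomanic"`.
#' @return data.frame `subject_id`, `sum_core`, `sum_vitality`,
#'   `sum_ordinariness`.
#' @export
score_hps_subscales_sum <- function(responses, key = default_scoring_key(),
                                    pole = c("native", "hypomanic")) {
  pole <- match.arg(pole)
  k <- .check_key(responses, key)
  complete <- stats::complete.cases(responses)
  r <- responses[complete, , drop = FALSE]
  keyed <- .keyed(r, k$direction)
  out <- data.frame(subject_id = rownames(r), stringsAsFactors = FALSE)
  for (sc in c("core", "vitality", "ordinariness")) {
    cols <- which(k$subscale == sc)
    s <- if (length(cols)) rowSums(keyed[, cols, drop = FALSE]) else
      rep(0, nrow(r))
    if (pole == "native" && sc == "ordinariness" && length(cols)) {
      # flip back to the ordinariness pole: n_items - hypomanic-keyed sum
      s <- length(cols) - s
    }
    out[[paste0("sum_", sc)]] <- s
  }
  out
}

#' Load the shipped PSQI component scoring table
#'
#' @param path YAML file of cut-points; defaults to the table shipped with
#'   the package, which follows the instrument's published manual.
#' @return nested list of cut-points.
#' @export
psqi_scoring_table <- function(path = system.file("extdata", "psqi_scoring.yaml",
                                                  package = "hpsleep")) {
  yaml::read_yaml(path)
}

.band_upper <- function(x, upper) {
  # number of upper bounds strictly exceeded: x <= upper[1] -> 0, ...
  out <- integer(length(x))
  for (u in upper) out <- out + (x > u)
  out
}

.band_lower <- function(x, lower) {
  # descending lower bounds: x > lower[1] -> 0, x >= lower[2] -> 1, ...
  out <- rep(length(lower), length(x))
  for (i in seq_along(lower)) {
    hit <- if (i == 1) x > lower[i] else x >= lower[i]
    out[hit & out == length(lower)] <- i - 1L
  }
  out
}

#' Score the PSQI
#'
#' Computes the seven components (each 0-3) from item responses via the
#' configured ordinal cut-points, their 0-21 total (higher = worse sleep
#' quality), and the single-item variables carried into the association
#' analyses: reported sleep-onset latency (minutes), bedtime and get-up
#' time (linearized to minutes after noon), reported sleep duration
#' (hours), reported sleep efficiency (fraction of time in bed), and the
#' daytime sleepiness item. Subjects missing any required item are excluded
#' with a log entry.
#'
#' @param psqi_items data.frame from [generate_psqi()] (or equivalently
#'   shaped real data).
#' @param scoring_table cut-point table from [psqi_scoring_table()].
#' @return data.frame: `subject_id`, `comp_quality`, `comp_latency`,
#'   `comp_duration`, `comp_efficiency`, `comp_disturbance`,
#'   `comp_medication`, `comp_daytime`, `psqi_total`, and extracted
#'   variables `psqi_latency`, `psqi_bedtime`, `psqi_getup`,
#'   `psqi_duration`, `psqi_efficiency`, `psqi_sleepiness`.
#' @export
score_psqi <- function(psqi_items, scoring_table = psqi_scoring_table()) {
  req <- c("subject_id", "bedtime", "getup_time", "latency_min", "latency_freq",
           "duration_h", "quality", paste0("d", 1:9), "medication",
           "sleepiness", "enthusiasm")
  missing <- setdiff(req, names(psqi_items))
  if (length(missing))
    stop("psqi items table missing column(s): ", paste(missing, collapse = ", "))
  complete <- stats::complete.cases(psqi_items[, req])
  if (any(!complete))
    hp_log("score_psqi: excluded ", sum(!complete),
           " subject(s) with missing PSQI items")
  d <- psqi_items[complete, , drop = FALSE]
  st <- scoring_table

  bed <- linearize_clock_time(d$bedtime)
  getup <- linearize_clock_time(d$getup_time)
  tib_min <- (getup - bed) %% 1440
  eff <- pmin(d$duration_h * 60 / tib_min, 1)

  comp <- data.frame(
    comp_quality = as.integer(d$quality),
    comp_latency = .band_upper(
      .band_upper(d$latency_min, st$latency$minutes_upper) + d$latency_freq,
      st$latency$sum_upper),
    comp_duration = .band_lower(d$duration_h, st$duration$hours_lower),
    comp_efficiency = .band_lower(100 * eff, st$efficiency$percent_lower),
    comp_disturbance = .band_upper(rowSums(d[, paste0("d", 1:9)]),
                                   st$disturbance$sum_upper),
    comp_medication = as.integer(d$medication),
    comp_daytime = .band_upper(d$sleepiness + d$enthusiasm, st$daytime$sum_upper)
  )
  if (any(as.matrix(comp) < 0 | as.matrix(comp) > 3))
    stop("PSQI component out of range 0-3; check the scoring table")
  data.frame(
    subject_id = d$subject_id,
    comp,
    psqi_total = rowSums(comp),
    psqi_latency = d$latency_min,
    psqi_bedtime = bed,
    psqi_getup = getup,
    psqi_duration = d$duration_h,
    psqi_efficiency = eff,
    psqi_sleepiness = as.integer(d$sleepiness),
    stringsAsFactors = FALSE
  )
}

#' The 7 PSQI panel variables in reporting order
#'
#' Reported latency, bedtime, get-up time, duration, efficiency, daytime
#' sleepiness, and the PSQI total score.
#' @return character vector of 7 column names.
#' @export
psqi_variables <- function() {
  c("psqi_latency", "psqi_bedtime", "psqi_getup", "psqi_duration",
    "psqi_efficiency", "psqi_sleepiness", "psqi_total")
}
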