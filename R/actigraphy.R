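# Actigraphy summaries ------------------------------------------------------
#
# Turns night-level records into the 14 per-subject variables used in the
# association analyses: the mean and the intraindividual standard deviation
# (ISD) of sleep-onset latency, sleep-onset time, sleep-offset time, sleep
# duration, number of awakenings (NWAK), wake after sleep onset (WASO), and
# sleep efficiency.

#' Per-night sleep efficiency
#'
#' The quotient of sleep duration and time in bed, where time in bed is
#' sleep-onset latency + sleep duration + WASO.
#'
#' @param sleep_duration minutes asleep.
#' @param sleep_onset_latency minutes from bedtime to sleep onset.
#' @param waso minutes awake after sleep onset.
#' @return efficiency in `(0, 1]`.
#' @examples
#' sleep_efficiency(420, 20, 40)  # 0.875
#' @export
sleep_efficiency <- function(sleep_duration, sleep_onset_latency, waso) {
  tib <- sleep_onset_latency + sleep_duration + waso
  if (any(tib <= 0)) stop("invalid night record: time in bed must be > 0")
  if (any(sleep_duration <= 0)) stop("invalid night record: sleep duration must be > 0")
  if (any(sleep_onset_latency < 0 | waso < 0))
    stop("invalid night record: latency and WASO must be >= 0")
  sleep_duration / tib
}

.validate_nights <- function(nights) {
  req <- c("subject_id", "night_index", "sleep_onset_time", "sleep_offset_time",
           "sleep_onset_latency", "nwak", "waso", "sleep_duration")
  missing <- setdiff(req, names(nights))
  if (length(missing))
    stop("nights table missing column(s): ", paste(missing, collapse = ", "))
  if (any(nights$sleep_duration <= 0)) stop("invalid night record: sleep_duration <= 0")
  if (any(nights$waso < 0) || any(nights$sleep_onset_latency < 0))
    stop("invalid night record: negative WASO or latency")
  if (any(nights$nwak < 0) || any(nights$nwak != round(nights$nwak)))
    stop("invalid night record: NWAK must be a non-negative integer")
  invisible(nights)
}

#' Summarize one subject's nights
#'
#' Computes the mean and ISD of the seven sleep variables across a single
#' subject's nights. Onset and offset clock times are linearized to minutes
#' after noon (see [linearize_clock_time()]) before aggregation, so evening
#' onsets and morning offsets each sit on a continuous axis; efficiency is
#' computed per night and then aggregated. Subjects with fewer than
#' `min_nights` nights yield `NULL` (excluded, matching the requirement of
#' an actigraphy recording of at least five nights).
#'
#' @param nights data.frame of night records for one subject.
#' @param min_nights minimum number of nights (default 5).
#' @param reference clock reference for linearization (default "12:00").
#' @return one-row data.frame (`subject_id`, `n_nights`, `mean_*`, `isd_*`
#'   for latency, onset, offset, duration, nwak, waso, efficiency), or
#'   `NULL` if the subject has fewer than `min_nights` nights.
#' @export
summarize_subject <- function(nights, min_nights = 5L, reference = "12:00") {
  .validate_nights(nights)
  if (length(unique(nights$subject_id)) != 1L)
    stop("summarize_subject() expects nights of exactly one subject")
  if (nrow(nights) < min_nights) return(NULL)
  vals <- list(
    latency = nights$sleep_onset_latency,
    onset = linearize_clock_time(nights$sleep_onset_time, reference),
    offset = linearize_clock_time(nights$sleep_offset_time, reference),
    duration = nights$sleep_duration,
    nwak = nights$nwak,
    waso = nights$waso,
    efficiency = sleep_efficiency(nights$sleep_duration,
                                  nights$sleep_onset_latency, nights$waso)
  )
  out <- data.frame(subject_id = nights$subject_id[1], n_nights = nrow(nights),
                    stringsAsFactors = FALSE)
  for (v in names(vals)) {
    out[[paste0("mean_", v)]] <- mean(vals[[v]])
    out[[paste0("isd_", v)]] <- isd(vals[[v]])
  }
  out
}

#' Summarize all subjects' nights
#'
#' Applies [summarize_subject()] per subject; subjects failing the
#' `min_nights` requirement are dropped (their count is logged).
#'
#' @param nights data.frame of night records (multiple subjects).
#' @param min_nights minimum number of nights per subject (default 5).
#' @param reference clock reference for linearization.
#' @return data.frame, one row per retained subject: `subject_id`,
#'   `n_nights`, then 14 summary columns (7 means, 7 ISDs).
#' @export
summarize_sleep <- function(nights, min_nights = 5L, reference = "12:00") {
  .validate_nights(nights)
  id <- factor(nights$subject_id)
  n_by <- tabulate(id, nlevels(id))
  keep_subj <- n_by >= min_nights
  dropped <- sum(!keep_subj)
  if (dropped > 0)
    hp_log("summarize_sleep: excluded ", dropped,
           " subject(s) with fewer than ", min_nights, " nights")
  rows <- keep_subj[as.integer(id)]
  nights <- nights[rows, , drop = FALSE]
  id <- droplevels(id[rows])
  n_by <- tabulate(id, nlevels(id))
  vals <- list(
    latency = nights$sleep_onset_latency,
    onset = linearize_clock_time(nights$sleep_onset_time, reference),
    offset = linearize_clock_time(nights$sleep_offset_time, reference),
    duration = nights$sleep_duration,
    nwak = as.numeric(nights$nwak),
    waso = nights$waso,
    efficiency = sleep_efficiency(nights$sleep_duration,
                                  nights$sleep_onset_latency, nights$waso)
  )
  out <- data.frame(subject_id = levels(id), n_nights = n_by,
                    stringsAsFactors = FALSE)
  for (v in names(vals)) {
    mu <- rowsum(vals[[v]], id)[, 1] / n_by
    # group sample SD via centered sums of squares (n - 1 denominator)
    dev2 <- rowsum((vals[[v]] - mu[as.integer(id)])^2, id)[, 1]
    out[[paste0("mean_", v)]] <- unname(mu)
    out[[paste0("isd_", v)]] <- unname(sqrt(dev2 / (n_by - 1)))
  }
  rownames(out) <- NULL
  out
}

#' The 14 actigraphy panel variables in reporting order
#'
#' Seven per-subject means followed by the seven night-to-night ISDs
#' (latency, onset, offset, duration, NWAK, WASO, efficiency).
#' @return character vector of 14 column names.
#' @export
actigraphy_variables <- function() {
  v <- c("latency", "onset", "offset", "duration", "nwak", "waso", "efficiency")
  c(paste0("mean_", v), paste0("isd_", v))
}
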