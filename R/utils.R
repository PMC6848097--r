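#' Parse a 24-h clock time to minutes after midnight
#'
#' @param x character vector of times in `"HH:MM"` format.
#' @return numeric vector of minutes after midnight in `[0, 1440)`.
#' @examples
#' parse_clock_time(c("23:30", "00:05"))
#' @export
parse_clock_time <- function(x) {
  if (!is.character(x)) stop("clock times must be character 'HH:MM'")
  ok <- grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", x) | is.na(x)
  if (!all(ok)) {
    stop("malformed clock time(s): ", paste(utils::head(x[!ok], 3), collapse = ", "))
  }
  h <- as.numeric(substr(x, 1, 2))
  m <- as.numeric(substr(x, 4, 5))
  h * 60 + m
}

#' Format minutes after midnight as "HH:MM"
#'
#' Values are wrapped into `[0, 1440)` and rounded to the nearest minute.
#' @param m numeric vector, minutes after midnight (any real; wrapped mod 1440).
#' @return character vector `"HH:MM"`.
#' @export
format_clock_time <- function(m) {
  m <- round(m) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

#' Linearize a clock time relative to a reference
#'
#' Clock times wrap at midnight; to aggregate sleep-onset and sleep-offset
#' times across nights they are mapped to minutes elapsed since a fixed
#' reference (noon by default), which places typical evening onsets and
#' morning offsets on a single continuous axis.
#'
#' @param t clock time(s): `"HH:MM"` strings or minutes after midnight.
#' @param reference reference clock time, same formats; default `"12:00"`.
#' @return minutes elapsed from `reference` to `t`, in `[0, 1440)`.
#' @examples
#' linearize_clock_time("23:30")        # 690
#' linearize_clock_time("00:30")        # 750 (wraps midnight)
#' @export
linearize_clock_time <- function(t, reference = "12:00") {
  tm <- if (is.character(t)) parse_clock_time(t) else as.numeric(t)
  rm <- if (is.character(reference)) parse_clock_time(reference) else as.numeric(reference)
  (tm - rm) %% 1440
}

# Derive a per-stage child seed from one global seed.  Fixed affine map
# modulo the Mersenne prime 2^31 - 1, with a documented stage index, so
# every stage is independently reproducible from the global seed.
.stage_index <- c(
  subjects = 1L, items = 2L, nights = 3L, psqi = 4L,
  factors = 5L, permutation = 6L, cv = 7L, plots = 8L
)

#' Derive a stage-specific child seed from a global seed
#'
#' `child = (seed * 69621 + 1013904223 * index) mod (2^31 - 1)`, a fixed
#' affine derivation so the synthetic-data stages can be re-run
#' independently yet reproducibly from one global seed.
#'
#' @param seed integer global seed.
#' @param stage one of `"subjects"`, `"items"`, `"nights"`, `"psqi"`,
#'   `"factors"`, `"permutation"`, `"cv"`, `"plots"`, or an integer index.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  idx <- if (is.character(stage)) {
    if (!stage %in% names(.stage_index)) stop("unknown stage: ", stage)
    .stage_index[[stage]]
  } else as.integer(stage)
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 69621 + 1013904223 * idx
  as.integer(s %% m) + 1L
}

# Sample standard deviation (n - 1 denominator) of one subject's nights.

#' Intraindividual standard deviation (ISD)
#'
#' Night-to-night variability of a sleep parameter, operationalized as the
#' sample standard deviation (denominator `n - 1`) across one subject's
#' nights.
#'
#' @param values numeric vector of per-night measurements (length >= 2).
#' @return scalar, same units as `values`.
#' @examples
#' isd(c(400, 420, 440))  # 20
#' @export
isd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("isd() needs at least two nights; got ", length(values))
  }
  stats::sd(values)
}

# Lightweight stage logging to stderr; every exclusion is accounted for.
hp_log <- function(..., file = NULL) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [hpsleep] ", ...)
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
  invisible(msg)
}

#' Read and write the pipeline's CSV tables
#'
#' RFC-4180 CSV with a header row, '.' decimal separator, and the empty
#' string for missing values; clock times are stored as HH:MM text. Every
#' writer's output is readable by the reader.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return `write_table_csv()`: `path`, invisibly; `read_table_csv()`:
#'   a data.frame.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
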