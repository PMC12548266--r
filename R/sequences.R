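# Daily location histories: detections -> calendar-day state sequences with
# last-observation-carried-forward imputation and explicit MISSING/VOID coding.

#' Construct a daily state sequence object
#'
#' @param fish_id Fish identifier.
#' @param start_date First calendar day of the sequence.
#' @param states Character vector of daily states (alphabet labels plus
#'   `"MISSING"` before the first observation and a contiguous `"VOID"`
#'   suffix after the last one).
#' @param level `"habitat"` or `"region"`.
#' @param alphabet Ordered state alphabet (excluding MISSING/VOID).
#' @return Object of class `daily_seq`.
#' @export
daily_seq <- function(fish_id, start_date, states, level, alphabet) {
  structure(
    list(fish_id = fish_id, start_date = as_utc_date(start_date),
         states = as.character(states), level = level,
         alphabet = as.character(alphabet)),
    class = "daily_seq"
  )
}

#' @export
print.daily_seq <- function(x, ...) {
  obs <- x$states[!x$states %in% c(.MISSING, .VOID)]
  cat(sprintf("<daily_seq> fish %s, %s level: %d days from %s (%d observed)\n",
              x$fish_id, x$level, length(x$states), format(x$start_date),
              length(obs)))
  rle_s <- rle(x$states)
  cat("  ", paste(sprintf("%s/%d", rle_s$values, rle_s$lengths), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.daily_seq <- function(x) length(x$states)

seq_dates <- function(x) x$start_date + seq_along(x$states) - 1L

#' Drop the VOID suffix of a sequence
#'
#' Right-missing days (after the fish's final detection) are excluded from
#' edit-distance computation; this returns the sequence without them.
#'
#' @param x A [daily_seq()].
#' @return A [daily_seq()] with no VOID states.
#' @export
strip_void <- function(x) {
  stopifnot(inherits(x, "daily_seq"))
  keep <- x$states != .VOID
  if (!any(keep)) {
    x$states <- character()
    return(x)
  }
  last <- max(which(keep))
  x$states <- x$states[seq_len(last)]
  x
}

#' Build a fish's daily location history from detections
#'
#' Converts one fish's detection events into a calendar-day state sequence at
#' habitat or region level:
#' \itemize{
#'   \item a day with detections takes the location of its \emph{first}
#'     detection;
#'   \item undetected days take the location of the \emph{last} detection on
#'     the most recent detection day (last observation carried forward);
#'   \item days before the first detection are `MISSING`;
#'   \item days after the final detection, when the timeframe extends beyond
#'     it, are `VOID`.
#' }
#'
#' @param events Detections of a single fish: data.frame with `fish_id`,
#'   `timestamp` (POSIXct or parseable, treated as UTC), `receiver_id`.
#' @param stations Receiver classification table (`receiver_id`, `habitat`,
#'   `region`).
#' @param timeframe Two dates `c(start, end)`; defaults to the fish's own
#'   detection span.
#' @param level `"habitat"` or `"region"`.
#' @param alphabet Optional explicit alphabet; defaults to the distinct
#'   habitat or region labels in `stations`.
#' @return A [daily_seq()].
#' @export
build_daily_sequence <- function(events, stations,
                                 timeframe = NULL,
                                 level = c("habitat", "region"),
                                 alphabet = NULL) {
  level <- match.arg(level)
  if (nrow(events) == 0L) stopf("no detections for sequence construction")
  fish <- unique(as.character(events$fish_id))
  if (length(fish) != 1L)
    stopf("build_daily_sequence expects events of a single fish, got %d", length(fish))
  loc <- classify_receiver(events$receiver_id, stations)[[level]]
  ts <- as_utc_time(events$timestamp)
  o <- order(ts)
  ts <- ts[o]; loc <- loc[o]
  day <- as_utc_date(ts)

  if (is.null(alphabet)) alphabet <- unique(stations[[level]])
  if (is.null(timeframe)) timeframe <- range(day)
  timeframe <- as_utc_date(timeframe)
  if (timeframe[1] > timeframe[2]) stopf("inverted timeframe")

  first_of_day <- tapply(loc, day, function(z) z[1L])
  last_of_day <- tapply(loc, day, function(z) z[length(z)])
  det_days <- as.Date(names(first_of_day))

  grid <- seq(timeframe[1], timeframe[2], by = "day")
  idx <- findInterval(grid, det_days)   # 0 before first detection day
  states <- rep(.MISSING, length(grid))
  has_prev <- idx > 0L
  states[has_prev] <- unname(last_of_day[idx[has_prev]])
  on_det_day <- !is.na(match(grid, det_days))
  states[on_det_day] <- unname(first_of_day[match(grid[on_det_day], det_days)])
  beyond <- grid > det_days[length(det_days)]
  states[beyond] <- .VOID

  daily_seq(fish, timeframe[1], states, level, alphabet)
}

#' Build daily sequences for every fish in a detection table
#'
#' @inheritParams build_daily_sequence
#' @param events Detection table covering multiple fish.
#' @param fish_ids Fish to include (default: all in `events`).
#' @return Named list of [daily_seq()], one per fish, all on the same
#'   timeframe (default: the span of all detections).
#' @export
build_cohort_sequences <- function(events, stations, timeframe = NULL,
                                   level = c("habitat", "region"),
                                   fish_ids = NULL, alphabet = NULL) {
  level <- match.arg(level)
  if (is.null(fish_ids)) fish_ids <- unique(as.character(events$fish_id))
  if (is.null(timeframe)) {
    d <- as_utc_date(as_utc_time(events$timestamp))
    timeframe <- range(d)
  }
  out <- lapply(fish_ids, function(f) {
    build_daily_sequence(events[events$fish_id == f, , drop = FALSE],
                         stations, timeframe, level, alphabet)
  })
  names(out) <- fish_ids
  out
}

#' Restrict a daily sequence to an analysis timeframe
#'
#' Days outside the window are dropped; when the window starts before the
#' sequence, the gap is coded `MISSING` (left-missing preserved, the sequence
#' is never re-anchored); when it ends after the sequence, the tail is coded
#' `VOID`.
#'
#' @param x A [daily_seq()].
#' @param window Two dates `c(start, end)`.
#' @return A [daily_seq()] spanning exactly `window`.
#' @export
truncate_to_timeframe <- function(x, window) {
  stopifnot(inherits(x, "daily_seq"))
  window <- as_utc_date(window)
  if (window[1] > window[2]) stopf("inverted window")
  seq_end <- x$start_date + length(x$states) - 1L
  if (window[2] < x$start_date || window[1] > seq_end)
    stopf("window does not overlap sequence")
  grid <- seq(window[1], window[2], by = "day")
  states <- rep(.MISSING, length(grid))
  inside <- grid >= x$start_date & grid <= seq_end
  states[inside] <- x$states[as.integer(grid[inside] - x$start_date) + 1L]
  states[grid > seq_end] <- .VOID
  daily_seq(x$fish_id, window[1], states, x$level, x$alphabet)
}
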