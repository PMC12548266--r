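# Detection- and fish-level filtering cascade applied before sequence
# analysis.  Order (asserted by filter_detections_and_fish): false detections
# -> tag life -> maturity -> history span -> spawning evidence -> timeframe
# coverage.

filter_report <- function(stage, unit, n_input, n_removed, removed = NULL) {
  structure(
    list(stage = stage, unit = unit, n_input = as.integer(n_input),
         n_removed = as.integer(n_removed),
         n_retained = as.integer(n_input - n_removed),
         removed = removed),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: %d of %d %s removed (%d retained)\n",
              x$stage, x$n_removed, x$n_input, x$unit, x$n_retained))
  invisible(x)
}

#' Remove potential false detections (min-lag rule)
#'
#' Acoustic tag collisions can fabricate detections.  A detection is treated
#' as potentially false — and removed — when the time gap to the nearest
#' other detection of the same fish on the same receiver exceeds `tf`
#' seconds; a detection with no same-fish, same-receiver neighbor at all is
#' likewise removed.  The boundary is inclusive: a minimum lag of exactly
#' `tf` is kept.
#'
#' @param events Detection table (`fish_id`, `timestamp`, `receiver_id`).
#' @param tf Time threshold in seconds (default 3600).
#' @return A list: `events` (retained detections, chronological per fish)
#'   and `report` (a `filter_report`).
#' @export
filter_false_detections <- function(events, tf = 3600) {
  if (tf <= 0) stopf("tf must be positive")
  n0 <- nrow(events)
  if (n0 == 0L)
    return(list(events = events,
                report = filter_report("false_detections", "detections", 0L, 0L)))
  ts <- as_utc_time(events$timestamp)
  o <- order(events$fish_id, events$receiver_id, ts)
  ev <- events[o, , drop = FALSE]
  ts <- ts[o]
  grp <- paste(ev$fish_id, ev$receiver_id, sep = "\r")
  new_grp <- c(TRUE, grp[-1L] != grp[-length(grp)])
  lag_prev <- c(NA, as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "secs")))
  lag_prev[new_grp] <- NA
  lag_next <- c(lag_prev[-1L], NA)
  min_lag <- pmin(lag_prev, lag_next, na.rm = TRUE)
  min_lag[is.na(lag_prev) & is.na(lag_next)] <- Inf  # lone detection on receiver
  keep <- min_lag <= tf
  out <- ev[keep, , drop = FALSE]
  out <- out[order(out$fish_id, as_utc_time(out$timestamp)), , drop = FALSE]
  rownames(out) <- NULL
  list(events = out,
       report = filter_report("false_detections", "detections", n0, sum(!keep)))
}

#' Remove detections after transmitter tag life
#'
#' Detections logged after a tag's rated life (default 10 years from
#' tagging) are unreliable and removed.
#'
#' @param events Detection table.
#' @param metadata Fish metadata with `fish_id`, `tagging_date`, and
#'   optionally `tag_life_years` (default 10 where absent).
#' @return A list: `events`, `report`.
#' @export
filter_tag_life <- function(events, metadata) {
  n0 <- nrow(events)
  if (n0 == 0L)
    return(list(events = events,
                report = filter_report("tag_life", "detections", 0L, 0L)))
  idx <- match(as.character(events$fish_id), as.character(metadata$fish_id))
  if (anyNA(idx))
    stopf("fish with detections but no metadata: %s",
          paste(unique(events$fish_id[is.na(idx)]), collapse = ", "))
  life <- if ("tag_life_years" %in% names(metadata)) metadata$tag_life_years else 10
  life <- ifelse(is.na(life), 10, life)
  expiry <- as.POSIXct(paste(as_utc_date(metadata$tagging_date), "00:00:00"),
                       tz = "UTC") + life * 365.25 * 86400
  keep <- as_utc_time(events$timestamp) <= expiry[idx]
  list(events = events[keep, , drop = FALSE],
       report = filter_report("tag_life", "detections", n0, sum(!keep)))
}

#' Remove presumed immature fish
#'
#' Fish with total length strictly below `min_length` (default 1 m) at
#' tagging are presumed sexually immature and excluded.  Fish with unknown
#' length are retained with a warning.
#'
#' @param metadata Fish metadata with `fish_id`, `total_length` (meters).
#' @param min_length Minimum adult length in meters.
#' @return A list: `fish_ids` (retained), `report`.
#' @export
filter_immature <- function(metadata, min_length = 1.0) {
  n0 <- nrow(metadata)
  len <- metadata$total_length
  if (anyNA(len))
    warnf("length unknown for %d fish; retained: %s", sum(is.na(len)),
          paste(metadata$fish_id[is.na(len)], collapse = ", "))
  keep <- is.na(len) | len >= min_length
  list(fish_ids = as.character(metadata$fish_id[keep]),
       report = filter_report("immature", "fish", n0, sum(!keep),
                              removed = as.character(metadata$fish_id[!keep])))
}

#' Remove fish with short detection histories
#'
#' A fish is retained only if the span between its first and last detection
#' (within `window`, when given) is at least `min_years` — the minimum needed
#' to observe a repeated annual pattern.
#'
#' @param events Detection table.
#' @param min_years Minimum history span in years (default 2).
#' @param window Optional date pair restricting which detections count.
#' @return A list: `fish_ids` (retained), `report`.
#' @export
filter_history_span <- function(events, min_years = 2, window = NULL) {
  ts <- as_utc_time(events$timestamp)
  if (!is.null(window)) {
    window <- as_utc_date(window)
    inside <- as_utc_date(ts) >= window[1] & as_utc_date(ts) <= window[2]
    events <- events[inside, , drop = FALSE]
    ts <- ts[inside]
  }
  ids <- unique(as.character(events$fish_id))
  span_days <- vapply(ids, function(f) {
    t <- ts[events$fish_id == f]
    as.numeric(difftime(max(t), min(t), units = "days"))
  }, 0)
  keep <- span_days >= min_years * 365.25
  list(fish_ids = ids[keep],
       report = filter_report("history_span", "fish", length(ids), sum(!keep),
                              removed = ids[!keep]))
}

#' Remove fish with no evidence of a spawning migration
#'
#' Retains a fish only if it has at least one detection within the spawning
#' window (default April 1 – June 30, any year) at a river receiver or a
#' configured en-route receiver; fish that remained in a lake for their
#' entire record are removed.
#'
#' @param events Detection table.
#' @param stations Receiver classification table.
#' @param spawning_window Month-day pair (`"MM-DD"`) bounding the spawning
#'   season, default `c("04-01", "06-30")`.
#' @param river_station_set Receiver ids counting as spawning evidence;
#'   default all river-habitat stations.
#' @return A list: `fish_ids` (retained), `report`.
#' @export
filter_spawning_evidence <- function(events, stations,
                                     spawning_window = c("04-01", "06-30"),
                                     river_station_set = NULL) {
  if (is.null(river_station_set))
    river_station_set <- stations$receiver_id[stations$habitat == "river"]
  if (length(river_station_set) == 0L)
    stopf("empty river station set")
  d <- as_utc_date(as_utc_time(events$timestamp))
  md <- format(d, "%m-%d")
  in_window <- md >= spawning_window[1] & md <= spawning_window[2]
  at_river <- events$receiver_id %in% river_station_set
  ids <- unique(as.character(events$fish_id))
  keep_ids <- unique(as.character(events$fish_id[in_window & at_river]))
  keep <- ids %in% keep_ids
  list(fish_ids = ids[keep],
       report = filter_report("spawning_evidence", "fish", length(ids),
                              sum(!keep), removed = ids[!keep]))
}

#' Remove fish undetected during the analysis timeframe
#'
#' @param events Detection table.
#' @param window Date pair; a fish must have at least one detection inside
#'   it (boundaries inclusive).
#' @return A list: `fish_ids` (retained), `report`.
#' @export
filter_timeframe_coverage <- function(events, window) {
  window <- as_utc_date(window)
  if (window[1] > window[2]) stopf("inverted window")
  d <- as_utc_date(as_utc_time(events$timestamp))
  ids <- unique(as.character(events$fish_id))
  keep_ids <- unique(as.character(events$fish_id[d >= window[1] & d <= window[2]]))
  keep <- ids %in% keep_ids
  list(fish_ids = ids[keep],
       report = filter_report("timeframe_coverage", "fish", length(ids),
                              sum(!keep), removed = ids[!keep]))
}

#' Run the full filtering cascade
#'
#' Applies, in order: the min-lag false-detection rule, the tag-life cut,
#' the maturity (length) filter, the detection-history-span filter, the
#' spawning-evidence filter and, when a timeframe is given, the
#' timeframe-coverage filter.  Detection filters shrink the event table;
#' fish filters shrink the fish set (and the event table with it).
#'
#' @param events Detection table.
#' @param stations Receiver classification table.
#' @param metadata Fish metadata table.
#' @param tf Min-lag threshold, seconds.
#' @param min_length Maturity cutoff, meters.
#' @param min_years Minimum history span, years.
#' @param spawning_window Month-day pair for spawning evidence.
#' @param river_station_set Optional en-route/river receiver ids.
#' @param timeframe Optional analysis window (dates) for the span and
#'   coverage filters.
#' @return A list: `events` (retained detections), `fish_ids` (retained
#'   fish), `reports` (list of per-stage `filter_report`s).
#' @export
filter_detections_and_fish <- function(events, stations, metadata,
                                       tf = 3600, min_length = 1.0,
                                       min_years = 2,
                                       spawning_window = c("04-01", "06-30"),
                                       river_station_set = NULL,
                                       timeframe = NULL) {
  reports <- list()
  s1 <- filter_false_detections(events, tf)
  reports$false_detections <- s1$report
  s2 <- filter_tag_life(s1$events, metadata)
  reports$tag_life <- s2$report
  ev <- s2$events
  meta <- metadata[metadata$fish_id %in% unique(ev$fish_id), , drop = FALSE]

  s3 <- filter_immature(meta, min_length)
  reports$immature <- s3$report
  ev <- ev[ev$fish_id %in% s3$fish_ids, , drop = FALSE]

  s4 <- filter_history_span(ev, min_years, window = timeframe)
  reports$history_span <- s4$report
  ev <- ev[ev$fish_id %in% s4$fish_ids, , drop = FALSE]

  s5 <- filter_spawning_evidence(ev, stations, spawning_window, river_station_set)
  reports$spawning_evidence <- s5$report
  ev <- ev[ev$fish_id %in% s5$fish_ids, , drop = FALSE]

  fish_ids <- s5$fish_ids
  if (!is.null(timeframe)) {
    s6 <- filter_timeframe_coverage(ev, timeframe)
    reports$timeframe_coverage <- s6$report
    ev <- ev[ev$fish_id %in% s6$fish_ids, , drop = FALSE]
    fish_ids <- s6$fish_ids
  }
  rownames(ev) <- NULL
  list(events = ev, fish_ids = fish_ids, reports = reports)
}

#' Serialize filter reports as JSON
#'
#' @param reports List of `filter_report` objects (as from
#'   [filter_detections_and_fish()]).
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
filter_reports_json <- function(reports, path = NULL) {
  x <- lapply(reports, function(r)
    list(stage = r$stage, unit = r$unit, n_input = r$n_input,
         n_removed = r$n_removed, n_retained = r$n_retained))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
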