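# River episodes: maximal runs of river habitat in a daily sequence.

#' Extract river episodes from aligned habitat and regional sequences
#'
#' A river episode is a maximal run of river-habitat days.  Runs are taken
#' over observed or imputed states only; MISSING and VOID days are not river
#' days and terminate a run.  Each episode carries the region label of its
#' first day (from the regional sequence) and whether it overlaps the
#' spawning window.
#'
#' @param habitat_seq,regional_seq Aligned [daily_seq()] objects for the
#'   same fish (same start date and length).
#' @param spawning_window Month-day pair, default `c("04-01", "06-30")`.
#' @return data.frame with one row per episode: `region`, `entry`, `exit`
#'   (dates), `duration` (days), `overlaps_spawning_window`.
#' @export
extract_river_episodes <- function(habitat_seq, regional_seq,
                                   spawning_window = c("04-01", "06-30")) {
  stopifnot(inherits(habitat_seq, "daily_seq"), inherits(regional_seq, "daily_seq"))
  if (habitat_seq$start_date != regional_seq$start_date ||
      length(habitat_seq$states) != length(regional_seq$states) ||
      !identical(habitat_seq$fish_id, regional_seq$fish_id))
    stopf("habitat and regional sequences are misaligned")
  dates <- seq_dates(habitat_seq)
  in_river <- habitat_seq$states == "river"
  if (!any(in_river))
    return(data.frame(region = character(), entry = as.Date(character()),
                      exit = as.Date(character()), duration = integer(),
                      overlaps_spawning_window = logical(),
                      stringsAsFactors = FALSE))
  r <- rle(in_river)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  entry <- dates[starts]; exit <- dates[ends]
  overlaps <- mapply(function(a, b) {
    any(vapply(seq(as.integer(format(a, "%Y")), as.integer(format(b, "%Y"))),
               function(y) {
                 ws <- as.Date(sprintf("%d-%s", y, spawning_window[1]))
                 we <- as.Date(sprintf("%d-%s", y, spawning_window[2]))
                 a <= we && b >= ws
               }, TRUE))
  }, entry, exit)
  data.frame(
    region = regional_seq$states[starts],
    entry = entry, exit = exit,
    duration = as.integer(exit - entry) + 1L,
    overlaps_spawning_window = as.logical(overlaps),
    stringsAsFactors = FALSE
  )
}
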