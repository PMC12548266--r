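#' Construct a migratory behavior archetype
#'
#' An archetype is the idealized seasonal calendar of one migratory behavior:
#' when (by day of year) a fish of that behavior enters and leaves river
#' habitat, how often the migration recurs, and which regions it uses.  The
#' synthetic generator ([simulate_individual()]) turns an archetype into
#' detection events; the classifier ([classify_behavior()]) should invert it.
#'
#' @param name One of the seven labels in [behavior_labels()].
#' @param river_entry_window,river_exit_window Integer day-of-year pairs
#'   `c(lo, hi)` bounding the nominal transition date (the midpoint is the
#'   scheduled date); `NULL` for river residents, which never transition.
#' @param period_years Migration periodicity: 1 = annual, >= 2 = intermittent
#'   (biennial by default for intermittent behaviors).
#' @param route Character vector of region labels in the order first used
#'   within one migratory cycle (the ground-truth contingent signature).
#' @param overwinter_unit Optional region label where the fish overwinters
#'   when that differs from its summer lake (two-step variants with two
#'   habitat transitions; interlake migrants).
#' @param n_transitions For two-step migrants: 1 = direct fall entry into the
#'   spawning river; 2 = fall transit through a river to an overwinter lake
#'   followed by a spring move to the spawning river.
#' @return An object of class `behavior_archetype`.
#' @export
behavior_archetype <- function(name, river_entry_window = NULL,
                               river_exit_window = NULL, period_years = 1L,
                               route, overwinter_unit = NULL,
                               n_transitions = 1L) {
  name <- match.arg(name, .BEHAVIORS)
  period_years <- as.integer(period_years)
  if (period_years < 1L) stopf("period_years must be >= 1")
  if (grepl("^intermittent", name) && period_years < 2L)
    stopf("intermittent archetypes require period_years >= 2")
  if (name == "river_resident") {
    if (!is.null(river_entry_window) || !is.null(river_exit_window))
      stopf("river_resident has no entry/exit windows")
  } else {
    if (is.null(river_entry_window) || is.null(river_exit_window))
      stopf("'%s' requires entry and exit windows", name)
  }
  structure(
    list(
      name = name,
      river_entry_window = river_entry_window,
      river_exit_window = river_exit_window,
      period_years = period_years,
      route = as.character(route),
      overwinter_unit = overwinter_unit,
      n_transitions = as.integer(n_transitions)
    ),
    class = "behavior_archetype"
  )
}

#' The seven default behavior archetypes
#'
#' Nominal calendars for the seven migratory behaviors on the default
#' synthetic study system ([default_layout()]):
#' \describe{
#'   \item{annual_spring_river}{short (~2.5 week) river trip overlapping the
#'     April–June spawning season, every year.}
#'   \item{intermittent_spring_river}{the same trip every other year.}
#'   \item{intermittent_two_step}{fall (~Oct) entry into the spawning river,
#'     overwintering near the spawning site and remaining through the
#'     following summer (~11 months in river), every other year — the long,
#'     50:50 lake:river variant.}
#'   \item{river_resident}{year-round residence in one river.}
#'   \item{annual_summer_river}{enters the river near the spawning season
#'     (~May), stays through the summer, returns to the lake ~Sept.}
#'   \item{annual_winter_river}{the inverse: enters ~Sept to overwinter in
#'     the river, returns to the lake ~mid-April.}
#'   \item{annual_interlake}{overwinters in the connecting lake (LSC,
#'     ~Sept–Apr), transits a river channel in spring, summers in the main
#'     lake, and returns each fall.}
#' }
#'
#' @param intermittent_period Periodicity (years) of the intermittent
#'   archetypes; 2 (biennial) by default, 3+ allowed.
#' @return Named list of [behavior_archetype()] objects.
#' @export
default_archetypes <- function(intermittent_period = 2L) {
  p <- as.integer(intermittent_period)
  list(
    annual_spring_river = behavior_archetype(
      "annual_spring_river",
      river_entry_window = c(doy(4, 25), doy(5, 5)),
      river_exit_window = c(doy(5, 12), doy(5, 22)),
      period_years = 1L, route = c("LH", "SR")
    ),
    intermittent_spring_river = behavior_archetype(
      "intermittent_spring_river",
      river_entry_window = c(doy(4, 25), doy(5, 5)),
      river_exit_window = c(doy(5, 12), doy(5, 22)),
      period_years = p, route = c("LH", "SR")
    ),
    intermittent_two_step = behavior_archetype(
      "intermittent_two_step",
      river_entry_window = c(doy(9, 25), doy(10, 7)),
      river_exit_window = c(doy(9, 1), doy(9, 14)),   # the following year
      period_years = p, route = c("LH", "SR")
    ),
    river_resident = behavior_archetype(
      "river_resident", period_years = 1L, route = "SR"
    ),
    annual_summer_river = behavior_archetype(
      "annual_summer_river",
      river_entry_window = c(doy(5, 5), doy(5, 15)),
      river_exit_window = c(doy(9, 10), doy(9, 20)),
      period_years = 1L, route = c("LH", "SR")
    ),
    annual_winter_river = behavior_archetype(
      "annual_winter_river",
      river_entry_window = c(doy(9, 10), doy(9, 20)),
      river_exit_window = c(doy(4, 10), doy(4, 20)),  # the following year
      period_years = 1L, route = c("LH", "SR")
    ),
    annual_interlake = behavior_archetype(
      "annual_interlake",
      river_entry_window = c(doy(4, 15), doy(4, 27)),
      river_exit_window = c(doy(9, 20), doy(10, 2)),
      period_years = 1L, route = c("LSC", "SCR", "LH"),
      overwinter_unit = "LSC"
    )
  )
}

#' Two-step archetype variants
#'
#' Intermittent two-step migrations vary in periodicity (biennial vs. 3+
#' years), river-residency duration (short ~7–10 months vs. long >= 1 year)
#' and number of habitat transitions (direct fall entry vs. fall transit
#' through a river channel to an overwinter lake, then a spring move to the
#' spawning river).
#'
#' @param period_years Periodicity in years (>= 2).
#' @param duration `"long"` (~11-month river stay, 50:50 lake:river) or
#'   `"short"` (fall entry, exit after the spawning season, lake dominant).
#' @param n_transitions 1 or 2 habitat transitions (see above).
#' @return A [behavior_archetype()].
#' @export
two_step_archetype <- function(period_years = 2L,
                               duration = c("long", "short"),
                               n_transitions = 1L) {
  duration <- match.arg(duration)
  exit <- if (duration == "long") c(doy(9, 1), doy(9, 14)) else c(doy(6, 10), doy(6, 22))
  if (n_transitions == 2L) {
    behavior_archetype(
      "intermittent_two_step",
      river_entry_window = c(doy(9, 25), doy(10, 7)),
      river_exit_window = c(doy(4, 25), doy(5, 7)),  # leaves spawning river in spring
      period_years = period_years, route = c("LH", "SCR", "LSC", "SR"),
      overwinter_unit = "LSC", n_transitions = 2L
    )
  } else {
    behavior_archetype(
      "intermittent_two_step",
      river_entry_window = c(doy(9, 25), doy(10, 7)),
      river_exit_window = exit,
      period_years = period_years, route = c("LH", "SR"), n_transitions = 1L
    )
  }
}

#' Simulation configuration for the synthetic detection generator
#'
#' The configuration fixes the study conditions the generator emulates:
#' multi-year (default 6-year) detection histories of adult fish on a fixed
#' receiver network, with a per-day probability of being detected while near
#' a receiver and Gaussian jitter on migration transition dates.
#'
#' @param n_fish_per_archetype Fish simulated per archetype (default 10).
#' @param years Length of each fish's transmitter record in years (>= 2 so
#'   the two-year history filter can pass; default 6, matching a long-term
#'   telemetry program).
#' @param detection_prob Probability that a fish near a receiver produces at
#'   least one detection on a given day (default 1 = the idealized noise-free
#'   calendar).
#' @param transition_jitter_days SD (days) of Gaussian noise on each
#'   scheduled transition date (default 0).
#' @param seed Integer RNG seed; fully determines the cohort.
#' @param tagging_date_range Two dates between which tagging dates are drawn
#'   uniformly.
#' @param fish_length_range Total length range (m) for simulated adults.
#' @param network Receiver classification table (see [make_network()]).
#' @param pings_per_day Detections emitted per detected fish-day, minutes
#'   apart (a burst, as a tag pinging while a fish holds near a receiver;
#'   must be >= 2 for the bursts to survive the min-lag collision filter).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_fish_per_archetype = 10L, years = 6L,
                       detection_prob = 1, transition_jitter_days = 0,
                       seed = 1L,
                       tagging_date_range = c("2015-01-01", "2015-02-28"),
                       fish_length_range = c(1.1, 2.0),
                       network = make_network(default_layout()),
                       pings_per_day = 3L) {
  if (detection_prob < 0 || detection_prob > 1)
    stopf("detection_prob must be in [0, 1]")
  if (years < 2L) stopf("years must be >= 2 (two-year history filter)")
  if (transition_jitter_days < 0) stopf("transition_jitter_days must be >= 0")
  structure(
    list(
      n_fish_per_archetype = as.integer(n_fish_per_archetype),
      years = as.integer(years),
      detection_prob = detection_prob,
      transition_jitter_days = transition_jitter_days,
      seed = as.integer(seed),
      tagging_date_range = as_utc_date(tagging_date_range),
      fish_length_range = fish_length_range,
      network = network,
      pings_per_day = as.integer(pings_per_day)
    ),
    class = "sim_config"
  )
}
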