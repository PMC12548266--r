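# Synthetic detection generator: archetype calendars -> daily true locations
# -> Bernoulli-thinned detection bursts on the receiver network.

mid_doy <- function(window) as.integer(floor(mean(window)))

date_from_doy <- function(year, d) as.Date(sprintf("%d-01-01", year)) + (d - 1L)

# Scheduled region change points for one fish over [start_date, end_date].
# Jitter (SD days, rounded) is applied to every change date independently;
# dates are then forced strictly increasing so no transition is lost.
archetype_changepoints <- function(arch, start_date, end_date, jitter_sd = 0) {
  home <- arch$route[1L]
  y0 <- as.integer(format(start_date, "%Y"))
  y1 <- as.integer(format(end_date, "%Y"))
  cyc <- seq(y0, y1)
  cyc <- cyc[(cyc - y0) %% arch$period_years == 0L]
  cp <- list(list(date = start_date, region = home))
  add <- function(date, region) cp[[length(cp) + 1L]] <<- list(date = date, region = region)

  if (arch$name != "river_resident") {
    ein <- mid_doy(arch$river_entry_window)
    eout <- mid_doy(arch$river_exit_window)
    next_year_exit <- eout <= ein
    for (y in cyc) {
      if (arch$name == "annual_interlake") {
        add(date_from_doy(y, ein), "SCR")        # spring transit out of LSC
        add(date_from_doy(y, ein) + 15L, "LH")   # summer in the main lake
        add(date_from_doy(y, eout) - 15L, "SCR") # fall transit back
        add(date_from_doy(y, eout), arch$overwinter_unit)
      } else if (arch$name == "intermittent_two_step" && arch$n_transitions == 2L) {
        add(date_from_doy(y, ein), "SCR")                 # fall transit
        add(date_from_doy(y, ein) + 10L, arch$overwinter_unit)
        add(date_from_doy(y + 1L, doy(4, 11)), "SR")      # spring spawning move
        add(date_from_doy(y + 1L, eout), "LH")
      } else {
        add(date_from_doy(y, ein), "SR")
        add(date_from_doy(y + if (next_year_exit) 1L else 0L, eout), "LH")
      }
    }
  }
  dates <- as.Date(vapply(cp, function(x) as.character(x$date), ""))
  regions <- vapply(cp, function(x) x$region, "")
  if (jitter_sd > 0 && length(dates) > 1L) {
    shift <- round(rnorm(length(dates) - 1L, 0, jitter_sd))
    dates[-1L] <- dates[-1L] + shift
  }
  for (i in seq_along(dates)[-1L]) {
    if (dates[i] <= dates[i - 1L]) dates[i] <- dates[i - 1L] + 1L
  }
  keep <- c(TRUE, dates[-1L] > start_date & dates[-1L] <= end_date)
  data.frame(date = dates[keep], region = regions[keep], stringsAsFactors = FALSE)
}

#' Simulate one fish's detection record
#'
#' Expands a behavior archetype into the fish's true daily region over its
#' transmitter life, then emits detections: each day, with probability
#' `cfg$detection_prob`, the fish is logged by one receiver of its current
#' region as a burst of `cfg$pings_per_day` detections minutes apart.
#'
#' With `detection_prob = 1` and `transition_jitter_days = 0` the daily
#' sequence induced by the detections reproduces the archetype calendar
#' exactly, so the full pipeline must recover the archetype's label.
#'
#' @param archetype A [behavior_archetype()].
#' @param cfg A [sim_config()]; supplies the network, detection probability,
#'   jitter, record length and ping burst size.  RNG state is consumed as-is
#'   (seed the caller, or use [simulate_cohort()]).
#' @param fish_id Identifier for the simulated fish.
#' @param tagging_date Optional tagging date; drawn uniformly from
#'   `cfg$tagging_date_range` when `NULL`.
#' @return A list: `detections` (data.frame `fish_id`, `timestamp` POSIXct
#'   UTC, `receiver_id`), `truth` (the archetype name), `truth_route`
#'   (ground-truth contingent signature), `true_states` (data.frame `date`,
#'   `region` of the fish's actual daily location), `tagging_date`.
#' @export
simulate_individual <- function(archetype, cfg, fish_id, tagging_date = NULL) {
  stopifnot(inherits(archetype, "behavior_archetype"), inherits(cfg, "sim_config"))
  net <- cfg$network
  missing_regions <- setdiff(archetype$route, unique(net$region))
  if (length(missing_regions))
    stopf("archetype '%s' routes through region(s) absent from the network: %s",
          archetype$name, paste(missing_regions, collapse = ", "))
  if (is.null(tagging_date)) {
    r <- cfg$tagging_date_range
    tagging_date <- r[1] + floor(runif(1) * (as.numeric(r[2] - r[1]) + 1))
  }
  tagging_date <- as_utc_date(tagging_date)
  end_date <- tagging_date + round(cfg$years * 365.25) - 1L

  cp <- archetype_changepoints(archetype, tagging_date, end_date,
                               cfg$transition_jitter_days)
  dates <- seq(tagging_date, end_date, by = "day")
  region <- cp$region[findInterval(dates, cp$date)]

  detected <- runif(length(dates)) < cfg$detection_prob
  det_idx <- which(detected)
  if (length(det_idx)) {
    recs <- lapply(det_idx, function(i) {
      ids <- net$receiver_id[net$region == region[i]]
      ids[sample.int(length(ids), 1L)]
    })
    start_sec <- floor(runif(length(det_idx), 0, 70000))
    k <- cfg$pings_per_day
    ts <- rep(as.POSIXct(paste(dates[det_idx], "00:00:00"), tz = "UTC"),
              each = k) +
      rep(start_sec, each = k) + rep(seq_len(k) - 1L, length(det_idx)) * 300
    detections <- data.frame(
      fish_id = fish_id,
      timestamp = ts,
      receiver_id = rep(unlist(recs), each = k),
      stringsAsFactors = FALSE
    )
  } else {
    detections <- data.frame(
      fish_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      receiver_id = character(), stringsAsFactors = FALSE
    )
  }
  list(
    detections = detections,
    truth = archetype$name,
    truth_route = paste(archetype$route, collapse = "→"),
    true_states = data.frame(date = dates, region = region,
                             stringsAsFactors = FALSE),
    tagging_date = tagging_date
  )
}

#' Simulate a cohort of fish across behavior archetypes
#'
#' Draws `cfg$n_fish_per_archetype` fish per archetype with randomized
#' tagging dates, lengths and sexes, and concatenates their detection
#' records.  The seed in `cfg` fully determines the output.
#'
#' @param cfg A [sim_config()].
#' @param archetypes List of [behavior_archetype()] objects (default the
#'   seven of [default_archetypes()]).
#' @return A list of data.frames: `detections` (fish_id, timestamp,
#'   receiver_id), `metadata` (fish_id, total_length, sex, tagging_date,
#'   tag_life_years), `truth` (fish_id, behavior, contingent_route), plus
#'   `network` (the station table used).
#' @export
simulate_cohort <- function(cfg, archetypes = default_archetypes()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  det <- list(); meta <- list(); truth <- list()
  fish_no <- 0L
  for (arch in archetypes) {
    for (j in seq_len(cfg$n_fish_per_archetype)) {
      fish_no <- fish_no + 1L
      id <- sprintf("F%03d", fish_no)
      one <- simulate_individual(arch, cfg, id)
      det[[fish_no]] <- one$detections
      meta[[fish_no]] <- data.frame(
        fish_id = id,
        total_length = runif(1, cfg$fish_length_range[1], cfg$fish_length_range[2]),
        sex = sample(c("male", "female"), 1L),
        tagging_date = one$tagging_date,
        tag_life_years = 10,
        stringsAsFactors = FALSE
      )
      truth[[fish_no]] <- data.frame(
        fish_id = id, behavior = one$truth, contingent_route = one$truth_route,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    detections = do.call(rbind, det),
    metadata = do.call(rbind, meta),
    truth = do.call(rbind, truth),
    network = cfg$network
  )
}
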