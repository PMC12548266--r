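# Deterministic rule cascade assigning each fish one of seven migratory
# behaviors.  The cascade stands in for the original workflow's cluster-
# guided visual inspection: rules are evaluated in a fixed order and the
# first match wins.

#' Classification rule configuration
#'
#' Seasonal windows and thresholds driving the behavior rule cascade.  All
#' windows are month-day pairs (`"MM-DD"`) applied to any year.
#'
#' @param spawning_window Typical spawning season (default Apr 1 – Jun 30).
#' @param spring_trip_max_days Longest river stay still read as a short
#'   spawning trip (default 45 d; observed stays are ~1–3 weeks, the margin
#'   absorbs detection lag before a stay reads as summer residence).
#' @param summer_exit_window When annual summer river migrants return to the
#'   lake (default Aug 1 – Oct 31).
#' @param winter_entry_window,winter_exit_window When annual winter river
#'   migrants enter (Jul 1 – Oct 31) and leave (Mar 1 – May 31) the river.
#' @param fall_entry_window When two-step migrants enter the river
#'   (Sep 1 – Dec 31).
#' @param resident_max_lake_fraction Largest lake-time fraction compatible
#'   with river residency (default 0.10, bracketing observed 1–5% values).
#' @param fifty_fifty_band Lake-residency interval read as 50:50 lake:river
#'   use (default 0.35–0.60, bracketing observed 42–52%).
#' @param periodicity_threshold Years-per-trip boundary between annual and
#'   intermittent spring migration (default 1.5; the boundary itself is
#'   annual).
#' @param near_spawning_lead_days Days before the spawning window during
#'   which a river entry still counts as "near" it (default 30).
#' @return Object of class `rule_config`.
#' @export
rule_config <- function(spawning_window = c("04-01", "06-30"),
                        spring_trip_max_days = 45,
                        summer_exit_window = c("08-01", "10-31"),
                        winter_entry_window = c("07-01", "10-31"),
                        winter_exit_window = c("03-01", "05-31"),
                        fall_entry_window = c("09-01", "12-31"),
                        resident_max_lake_fraction = 0.10,
                        fifty_fifty_band = c(0.35, 0.60),
                        periodicity_threshold = 1.5,
                        near_spawning_lead_days = 30) {
  structure(
    list(spawning_window = spawning_window,
         spring_trip_max_days = spring_trip_max_days,
         summer_exit_window = summer_exit_window,
         winter_entry_window = winter_entry_window,
         winter_exit_window = winter_exit_window,
         fall_entry_window = fall_entry_window,
         resident_max_lake_fraction = resident_max_lake_fraction,
         fifty_fifty_band = fifty_fifty_band,
         periodicity_threshold = periodicity_threshold,
         near_spawning_lead_days = near_spawning_lead_days),
    class = "rule_config"
  )
}

md_in_window <- function(dates, window) {
  md <- format(dates, "%m-%d")
  md >= window[1] & md <= window[2]
}

#' Migration periodicity ratio
#'
#' Total years of detection history divided by the number of spring river
#' trips.  A ratio at or below the threshold (default 1.5) classifies the
#' fish as an annual spring migrant (it entered the river most springs);
#' above it, intermittent.
#'
#' @param history_years Length of the fish's detection history in years
#'   (fractional).
#' @param n_spring_trips Number of river trips overlapping the spawning
#'   window (>= 1).
#' @param threshold Boundary (default 1.5); the boundary value is annual.
#' @return List with `ratio` and `class` (`"annual"` or `"intermittent"`).
#' @export
periodicity_ratio <- function(history_years, n_spring_trips, threshold = 1.5) {
  if (n_spring_trips < 1L) stopf("periodicity undefined for zero spring trips")
  if (history_years <= 0) stopf("history_years must be positive")
  ratio <- history_years / n_spring_trips
  list(ratio = ratio,
       class = if (ratio <= threshold) "annual" else "intermittent")
}

#' Fraction of time spent in lake habitat
#'
#' Computed from the habitat sequence: lake days (lake and Lake St. Clair
#' states) over all observed-or-imputed days; MISSING and VOID days are
#' excluded from both numerator and denominator.
#'
#' @param habitat_seq A habitat-level [daily_seq()].
#' @return Fraction in `[0, 1]`.
#' @export
lake_residency <- function(habitat_seq) {
  stopifnot(inherits(habitat_seq, "daily_seq"))
  obs <- habitat_seq$states[!habitat_seq$states %in% c(.MISSING, .VOID)]
  if (length(obs) == 0L) stopf("fish %s: no observed days", habitat_seq$fish_id)
  mean(obs %in% c("lake", "lake_st_clair"))
}

# Count annual interlake cycles: overwinter in Lake St. Clair (on Jan-Mar
# evidence), spring transit via a river, summer in a different (great) lake,
# and a return to Lake St. Clair by the end of January next year.  Returns
# the number of consecutive-year cycle pairs >= 1, i.e. TRUE when >= 2
# consecutive annual cycles exist (a biennial two-step through the same
# overwinter lake has cycles in alternating years only and never qualifies).
has_interlake_pattern <- function(dates, hab) {
  yrs <- sort(unique(as.integer(format(dates, "%Y"))))
  cycle <- vapply(yrs, function(y) {
    q1 <- which(hab == "lake_st_clair" &
                  dates >= as.Date(sprintf("%d-01-01", y)) &
                  dates <= as.Date(sprintf("%d-03-31", y)))
    if (!length(q1)) return(FALSE)
    t1 <- q1[1]
    riv <- which(hab == "river" & seq_along(hab) > t1 &
                   dates <= as.Date(sprintf("%d-12-31", y)))
    if (!length(riv)) return(FALSE)
    t2 <- riv[1]
    lk <- which(hab == "lake" & seq_along(hab) > t2 &
                  dates <= as.Date(sprintf("%d-12-31", y)))
    if (!length(lk)) return(FALSE)
    t3 <- lk[1]
    back <- which(hab == "lake_st_clair" & seq_along(hab) > t3 &
                    dates <= as.Date(sprintf("%d-01-31", y + 1L)))
    length(back) > 0L
  }, TRUE)
  if (length(cycle) < 2L) return(FALSE)
  any(cycle[-length(cycle)] & cycle[-1L])
}

# Two-transition two-step evidence: a fall-entry river episode followed by a
# spawning-window river episode the next spring, with the days between them
# spent overwintering in Lake St. Clair.
has_two_transition_two_step <- function(episodes, dates, hab, rules) {
  if (nrow(episodes) < 2L) return(FALSE)
  fall <- which(md_in_window(episodes$entry, rules$fall_entry_window))
  for (i in fall) {
    later <- which(episodes$entry > episodes$exit[i] &
                     episodes$overlaps_spawning_window)
    for (j in later) {
      gap <- dates > episodes$exit[i] & dates < episodes$entry[j]
      if (any(gap) && all(hab[gap] == "lake_st_clair") &&
          as.numeric(episodes$entry[j] - episodes$exit[i]) < 300)
        return(TRUE)
    }
  }
  FALSE
}

#' Classify one fish's migratory behavior
#'
#' Applies the deterministic rule cascade to a fish's aligned habitat and
#' regional sequences; the first matching rule wins:
#' \enumerate{
#'   \item \strong{river_resident} — lake residency at or below
#'     `resident_max_lake_fraction`;
#'   \item \strong{annual_interlake} — at least two consecutive annual
#'     cycles of Lake St. Clair overwintering, river transit, summering in a
#'     different lake, and return;
#'   \item \strong{annual_winter_river} — river episodes entering in the
#'     winter-entry window and exiting in the winter-exit window in at least
#'     (observed years − 1) years;
#'   \item \strong{annual_summer_river} — episodes entering near the
#'     spawning window, persisting past it, and exiting in the summer-exit
#'     window in at least (observed years − 1) years;
#'   \item \strong{intermittent_two_step} — an episode entering in the fall
#'     window that spans the following spawning window (or the
#'     two-transition form: fall river transit, Lake St. Clair
#'     overwintering, spring spawning-river episode);
#'   \item \strong{spring river migrant} — a short (at most
#'     `spring_trip_max_days`) episode overlapping the spawning window;
#'     split annual vs. intermittent by the periodicity ratio;
#'   \item \strong{UNCLASSIFIED} otherwise.
#' }
#'
#' @param habitat_seq,regional_seq Aligned [daily_seq()] objects.
#' @param rules A [rule_config()].
#' @return List of class `behavior_assignment`: `fish_id`, `behavior`,
#'   `periodicity_ratio` (NA unless a spring migrant), `n_spring_trips`,
#'   `lake_residency`, `residency_class`, `history_years`, `rule_fired`.
#' @export
classify_behavior <- function(habitat_seq, regional_seq, rules = rule_config()) {
  stopifnot(inherits(rules, "rule_config"))
  dates <- seq_dates(habitat_seq)
  hab <- habitat_seq$states
  obs <- !hab %in% c(.MISSING, .VOID)
  if (!any(obs)) stopf("fish %s: no observed days", habitat_seq$fish_id)
  span_days <- as.numeric(dates[max(which(obs))] - dates[min(which(obs))]) + 1
  history_years <- span_days / 365.25
  floor_years <- floor(history_years + 1e-9)
  lake_frac <- lake_residency(habitat_seq)
  episodes <- extract_river_episodes(habitat_seq, regional_seq,
                                     rules$spawning_window)

  behavior <- "UNCLASSIFIED"
  rule_fired <- NA_character_
  ratio <- NA_real_
  n_trips <- NA_integer_

  spring_trips <- which(episodes$overlaps_spawning_window &
                          episodes$duration <= rules$spring_trip_max_days)

  repeat {
    # (1) river resident
    if (lake_frac <= rules$resident_max_lake_fraction) {
      behavior <- "river_resident"; rule_fired <- "resident"; break
    }
    # (2) annual interlake
    if ("lake_st_clair" %in% habitat_seq$alphabet &&
        has_interlake_pattern(dates, hab)) {
      behavior <- "annual_interlake"; rule_fired <- "interlake"; break
    }
    # (3) annual winter river
    winter <- md_in_window(episodes$entry, rules$winter_entry_window) &
      md_in_window(episodes$exit, rules$winter_exit_window)
    if (sum(winter) >= max(1L, floor_years - 1L)) {
      behavior <- "annual_winter_river"; rule_fired <- "winter_river"; break
    }
    # (4) annual summer river
    ws_doy <- as.integer(format(as.Date(paste0("2001-", rules$spawning_window[1])), "%j"))
    near_start <- format(as.Date("2001-01-01") + ws_doy - 1 -
                           rules$near_spawning_lead_days, "%m-%d")
    entry_md <- format(episodes$entry, "%m-%d")
    spawn_end_same_year <- as.Date(paste0(format(episodes$entry, "%Y"), "-",
                                          rules$spawning_window[2]))
    summer <- entry_md >= near_start & entry_md <= rules$spawning_window[2] &
      episodes$exit > spawn_end_same_year &
      md_in_window(episodes$exit, rules$summer_exit_window)
    if (sum(summer) >= max(1L, floor_years - 1L)) {
      behavior <- "annual_summer_river"; rule_fired <- "summer_river"; break
    }
    # (5) intermittent two-step
    spans_next_spawn <- md_in_window(episodes$entry, rules$fall_entry_window) &
      episodes$exit >= as.Date(paste0(as.integer(format(episodes$entry, "%Y")) + 1L,
                                      "-", rules$spawning_window[1]))
    if (any(spans_next_spawn) ||
        has_two_transition_two_step(episodes, dates, hab, rules)) {
      behavior <- "intermittent_two_step"; rule_fired <- "two_step"; break
    }
    # (6) spring river migrant, annual vs intermittent by periodicity
    if (length(spring_trips) >= 1L) {
      n_trips <- length(spring_trips)
      p <- periodicity_ratio(history_years, n_trips,
                             rules$periodicity_threshold)
      ratio <- p$ratio
      behavior <- if (p$class == "annual") "annual_spring_river"
                  else "intermittent_spring_river"
      rule_fired <- "spring_river"
      break
    }
    rule_fired <- "none"
    break
  }

  band <- rules$fifty_fifty_band
  residency_class <- if (lake_frac < band[1]) "river_dominant"
                     else if (lake_frac <= band[2]) "fifty_fifty"
                     else "lake_dominant"

  structure(
    list(fish_id = habitat_seq$fish_id, behavior = behavior,
         periodicity_ratio = ratio, n_spring_trips = n_trips,
         lake_residency = lake_frac, residency_class = residency_class,
         history_years = history_years, rule_fired = rule_fired),
    class = "behavior_assignment"
  )
}

#' @export
print.behavior_assignment <- function(x, ...) {
  cat(sprintf("<behavior_assignment> %s: %s (lake residency %.0f%%, %s)\n",
              x$fish_id, x$behavior, 100 * x$lake_residency, x$residency_class))
  invisible(x)
}

#' Classify a cohort, with clustering as a guide
#'
#' Runs the rule cascade on every fish and, alongside it, the statistical
#' grouping step (Ward tree on the dissimilarity matrix, ASW-selected number
#' of groups).  Each fish's cluster id is recorded next to its rule label
#' and the disagreement rate between the cluster-majority label and the rule
#' label is reported — clustering guides, rules decide.
#'
#' @param habitat_seqs,regional_seqs Named lists of aligned [daily_seq()]
#'   objects (same fish order).
#' @param dissim Dissimilarity matrix over the same fish (or `NULL` to skip
#'   the clustering guide).
#' @param rules A [rule_config()].
#' @param kmax,benchmark Passed to [select_group_number()].
#' @return List: `assignments` (data.frame with fish_id, behavior,
#'   periodicity_ratio, lake_residency, residency_class, cluster_id),
#'   `selection` (a `group_selection` or NULL), `disagreement_rate`.
#' @export
classify_cohort <- function(habitat_seqs, regional_seqs, dissim = NULL,
                            rules = rule_config(), kmax = 10, benchmark = 0.5) {
  ids <- names(habitat_seqs)
  stopifnot(identical(ids, names(regional_seqs)))
  rows <- lapply(ids, function(f) {
    a <- classify_behavior(habitat_seqs[[f]], regional_seqs[[f]], rules)
    data.frame(fish_id = f, behavior = a$behavior,
               periodicity_ratio = a$periodicity_ratio,
               lake_residency = a$lake_residency,
               residency_class = a$residency_class,
               history_years = a$history_years,
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)

  selection <- NULL
  disagreement <- NA_real_
  assignments$cluster_id <- NA_integer_
  if (!is.null(dissim) && nrow(assignments) >= 3L) {
    m <- check_dissim(dissim)[ids, ids]
    selection <- tryCatch(select_group_number(m, kmax, benchmark),
                          error = function(e) NULL)
    if (!is.null(selection)) {
      cl <- cut_tree(ward_tree(m), selection$chosen_k)
      assignments$cluster_id <- as.integer(cl[ids])
      majority <- tapply(assignments$behavior, assignments$cluster_id,
                         function(b) names(sort(table(b), decreasing = TRUE))[1])
      disagreement <- mean(assignments$behavior !=
                             majority[as.character(assignments$cluster_id)])
    }
  }
  list(assignments = assignments, selection = selection,
       disagreement_rate = disagreement)
}
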