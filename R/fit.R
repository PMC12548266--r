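# Main model-fitting interface: detections in, classified cohort out.

#' Classify migratory behaviors of an acoustic-telemetry cohort
#'
#' The package's main fitting function.  Runs the full analysis on a
#' detection table: the filtering cascade, daily habitat- and region-level
#' location histories (LOCF), optimal-matching dissimilarities under the
#' geographic cost model, Ward clustering with ASW group-number selection,
#' the behavior rule cascade, and the contingent/frequency/residency
#' summaries.
#'
#' @param detections data.frame `fish_id`, `timestamp` (UTC), `receiver_id`.
#' @param stations Receiver classification table (`receiver_id`, `habitat`,
#'   `region`).
#' @param metadata Fish metadata (`fish_id`, `total_length`, `sex`,
#'   `tagging_date`, optional `tag_life_years`).
#' @param timeframe Optional analysis window (two dates); default
#'   `[earliest tagging date, last detection]` of the retained fish.
#' @param population Population label attached to all outputs.
#' @param rules A [rule_config()].
#' @param habitat_adjacency Adjacency edges between habitat states for the
#'   cost model (default [default_adjacency()]`("habitat")`).
#' @param kmax,benchmark Group-number selection parameters
#'   (see [select_group_number()]).
#' @param tf,min_length,min_years,river_station_set Filtering parameters
#'   (see [filter_detections_and_fish()]).
#' @param cluster Logical; compute the dissimilarity matrix and clustering
#'   guide (default TRUE; the rule cascade alone still labels every fish
#'   when FALSE, which is much faster for large cohorts).
#' @return Object of class `migr_fit`: list with `assignments` (one row per
#'   retained fish: behavior, periodicity ratio, lake residency, residency
#'   class, cluster id, route signature), `frequency` (a
#'   `frequency_table`), `contingents`, `residency_summary`, `selection`,
#'   `disagreement_rate`, `dissimilarity`, `habitat_seqs`, `regional_seqs`,
#'   `filter_reports`, `timeframe`, `rules`, `population`.
#' @seealso [simulate_cohort()] to generate inputs with known ground truth;
#'   [run_pipeline()] for a file-based run.
#' @export
classify_migration <- function(detections, stations, metadata,
                               timeframe = NULL, population = "all",
                               rules = rule_config(),
                               habitat_adjacency = default_adjacency("habitat"),
                               kmax = 10, benchmark = 0.5,
                               tf = 3600, min_length = 1.0, min_years = 2,
                               river_station_set = NULL, cluster = TRUE) {
  cl <- match.call()
  flt <- filter_detections_and_fish(
    detections, stations, metadata, tf = tf, min_length = min_length,
    min_years = min_years, spawning_window = rules$spawning_window,
    river_station_set = river_station_set, timeframe = timeframe
  )
  if (length(flt$fish_ids) == 0L) stopf("no fish retained after filtering")
  if (is.null(timeframe)) {
    meta_kept <- metadata[metadata$fish_id %in% flt$fish_ids, , drop = FALSE]
    timeframe <- c(min(as_utc_date(meta_kept$tagging_date)),
                   max(as_utc_date(as_utc_time(flt$events$timestamp))))
  }
  timeframe <- as_utc_date(timeframe)

  hab_alph <- intersect(.HABITATS, unique(stations$habitat))
  habitat_seqs <- build_cohort_sequences(flt$events, stations, timeframe,
                                         "habitat", flt$fish_ids, hab_alph)
  regional_seqs <- build_cohort_sequences(flt$events, stations, timeframe,
                                          "region", flt$fish_ids,
                                          unique(stations$region))

  dissim <- NULL
  if (cluster && length(habitat_seqs) >= 3L) {
    edges <- habitat_adjacency[habitat_adjacency[, 1] %in% hab_alph &
                                 habitat_adjacency[, 2] %in% hab_alph, ,
                               drop = FALSE]
    cost <- build_cost_matrix(hab_alph, edges)
    dissim <- dissimilarity_matrix(habitat_seqs, cost)
  }
  coh <- classify_cohort(habitat_seqs, regional_seqs, dissim, rules,
                         kmax, benchmark)
  assignments <- coh$assignments
  assignments$population <- population

  sigs <- vapply(flt$fish_ids, function(f)
    route_signature(regional_seqs[[f]]), "")
  assignments$signature <- unname(sigs[assignments$fish_id])

  structure(
    list(assignments = assignments,
         frequency = behavior_frequency_table(assignments),
         contingents = tabulate_contingents(assignments, sigs),
         residency_summary = lake_residency_summary(assignments),
         selection = coh$selection,
         disagreement_rate = coh$disagreement_rate,
         dissimilarity = dissim,
         habitat_seqs = habitat_seqs, regional_seqs = regional_seqs,
         filter_reports = flt$reports,
         timeframe = timeframe, rules = rules, population = population,
         call = cl),
    class = "migr_fit"
  )
}

#' @export
print.migr_fit <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("Migratory behavior classification — population '%s'\n",
              x$population))
  cat(sprintf("  %d fish over %s .. %s\n", nrow(a),
              format(x$timeframe[1]), format(x$timeframe[2])))
  tb <- table(factor(a$behavior, levels = c(.BEHAVIORS, "UNCLASSIFIED")))
  tb <- tb[tb > 0]
  for (b in names(tb)) cat(sprintf("  %-26s %d\n", b, tb[[b]]))
  if (!is.null(x$selection))
    cat(sprintf("  clustering guide: k = %d (ASW %.2f, %s)\n",
                x$selection$chosen_k,
                x$selection$asw_by_k[[as.character(x$selection$chosen_k)]],
                x$selection$rule_applied))
  invisible(x)
}

#' @export
summary.migr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.migr_fit")
}

#' @export
print.summary.migr_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nBehavior frequencies:\n")
  print(f$frequency)
  cat("\nContingents:\n")
  print(f$contingents$table)
  cat("\nLake residency (% of days, mean ± SD):\n")
  rs <- f$residency_summary
  rs$mean_pct <- round(rs$mean_pct)
  rs$sd_pct <- round(rs$sd_pct)
  print(rs, row.names = FALSE)
  if (!is.na(f$disagreement_rate))
    cat(sprintf("\nCluster-majority vs rule-label disagreement: %.1f%%\n",
                100 * f$disagreement_rate))
  invisible(x)
}

#' Plot a classified cohort as a sequence-index panel
#'
#' Base-graphics index plot of the daily habitat sequences, one row per
#' fish, ordered by assigned behavior; colors code states (MISSING/VOID in
#' gray).
#'
#' @param x A `migr_fit`.
#' @param max_fish Largest number of fish rows to draw (subsampled beyond).
#' @param ... Unused.
#' @export
plot.migr_fit <- function(x, max_fish = 100, ...) {
  a <- x$assignments[order(x$assignments$behavior), , drop = FALSE]
  ids <- a$fish_id
  if (length(ids) > max_fish) ids <- ids[seq(1, length(ids), length.out = max_fish)]
  alph <- x$habitat_seqs[[1]]$alphabet
  lev <- c(alph, .MISSING, .VOID)
  m <- t(vapply(ids, function(f)
    as.integer(factor(x$habitat_seqs[[f]]$states, levels = lev)),
    integer(length(x$habitat_seqs[[1]]$states))))
  cols <- c(hcl.colors(length(alph), "Dark 3"), "gray85", "gray95")
  dates <- seq_dates(x$habitat_seqs[[1]])
  image(x = as.numeric(dates), y = seq_along(ids), z = t(m)[, rev(seq_along(ids))],
        col = cols, zlim = c(1, length(lev)), xaxt = "n", yaxt = "n",
        xlab = "date", ylab = "fish (by behavior)")
  ticks <- pretty(as.numeric(dates))
  axis(1, at = ticks, labels = format(as.Date(ticks, origin = "1970-01-01"), "%Y"))
  legend("topright", legend = lev, fill = cols, cex = 0.7, bg = "white")
  invisible(x)
}
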