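# File-based orchestration: config in, artifact directory out.

#' Write a simulated cohort to CSV files
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (detections, stations, metadata,
#'   truth).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- cohort$detections
  det$timestamp <- format(det$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  paths <- c(
    detections = file.path(dir, "detections.csv"),
    stations = file.path(dir, "stations.csv"),
    metadata = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write.csv(det, paths["detections"], row.names = FALSE)
  write.csv(cohort$network, paths["stations"], row.names = FALSE)
  write.csv(cohort$metadata, paths["metadata"], row.names = FALSE)
  write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Write daily sequences as wide and long CSV with a JSON alphabet sidecar
#'
#' @param seqs Named list of [daily_seq()] objects on one timeframe.
#' @param prefix File-path prefix; writes `<prefix>_wide.csv`,
#'   `<prefix>_long.csv`, `<prefix>_alphabet.json`.
#' @return Invisibly, the paths written.
#' @export
write_sequences_csv <- function(seqs, prefix) {
  dates <- seq_dates(seqs[[1]])
  wide <- data.frame(fish_id = names(seqs),
                     t(vapply(seqs, function(s) s$states,
                              character(length(dates)))),
                     stringsAsFactors = FALSE, check.names = FALSE)
  names(wide)[-1] <- format(dates)
  long <- do.call(rbind, lapply(seqs, function(s)
    data.frame(fish_id = s$fish_id, date = format(seq_dates(s)),
               state = s$states, stringsAsFactors = FALSE)))
  paths <- paste0(prefix, c("_wide.csv", "_long.csv", "_alphabet.json"))
  write.csv(wide, paths[1], row.names = FALSE)
  write.csv(long, paths[2], row.names = FALSE)
  writeLines(jsonlite::toJSON(list(alphabet = seqs[[1]]$alphabet,
                                   level = seqs[[1]]$level,
                                   missing = .MISSING, void = .VOID),
                              auto_unbox = TRUE, pretty = TRUE), paths[3])
  invisible(paths)
}

#' Run configuration for a file-based pipeline run
#'
#' @param detections,stations,metadata Paths to the input CSVs.
#' @param population Population label.
#' @param timeframe Optional date pair.
#' @param kmax,benchmark Clustering parameters.
#' @param seed RNG seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @param rules A [rule_config()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(detections, stations, metadata, population = "all",
                       timeframe = NULL, kmax = 10, benchmark = 0.5,
                       seed = 1L, rules = rule_config()) {
  for (p in c(detections, stations, metadata))
    if (!file.exists(p)) stopf("input file does not exist: %s", p)
  structure(
    list(detections = detections, stations = stations, metadata = metadata,
         population = population, timeframe = timeframe, kmax = kmax,
         benchmark = benchmark, seed = as.integer(seed), rules = rules),
    class = "run_config"
  )
}

#' Save / load a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$rules <- unclass(x$rules)
  if (!is.null(x$timeframe)) x$timeframe <- format(as_utc_date(x$timeframe))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  rules <- do.call(rule_config, lapply(x$rules, function(v)
    if (is.list(v)) unlist(v) else v))
  run_config(x$detections, x$stations, x$metadata,
             population = x$population %||% "all",
             timeframe = x$timeframe, kmax = x$kmax %||% 10,
             benchmark = x$benchmark %||% 0.5, seed = x$seed %||% 1L,
             rules = rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from files to an artifact directory
#'
#' Reads the input CSVs, fits [classify_migration()], and writes every
#' stage's outputs into `out_dir`: filter reports (JSON), habitat and
#' regional sequences (wide/long CSV + alphabet JSON), the dissimilarity
#' matrix (CSV), the group selection (JSON), assignments, contingent,
#' frequency and residency tables (CSV), and a provenance log of all
#' parameters.
#'
#' @param cfg A [run_config()] (or path to its YAML).
#' @param out_dir Output directory.
#' @param cluster Passed to [classify_migration()].
#' @return The `migr_fit`, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, cluster = TRUE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  detections <- read.csv(cfg$detections, stringsAsFactors = FALSE)
  stations <- read.csv(cfg$stations, stringsAsFactors = FALSE)
  metadata <- read.csv(cfg$metadata, stringsAsFactors = FALSE)
  detections$timestamp <- as.POSIXct(detections$timestamp,
                                     format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  fit <- classify_migration(detections, stations, metadata,
                            timeframe = cfg$timeframe,
                            population = cfg$population, rules = cfg$rules,
                            kmax = cfg$kmax, benchmark = cfg$benchmark,
                            cluster = cluster)

  filter_reports_json(fit$filter_reports, file.path(out_dir, "filter_reports.json"))
  write_sequences_csv(fit$habitat_seqs, file.path(out_dir, "habitat_seq"))
  write_sequences_csv(fit$regional_seqs, file.path(out_dir, "regional_seq"))
  if (!is.null(fit$dissimilarity))
    write.csv(fit$dissimilarity, file.path(out_dir, "dissimilarity.csv"))
  if (!is.null(fit$selection))
    writeLines(jsonlite::toJSON(list(asw_by_k = as.list(fit$selection$asw_by_k),
                                     chosen_k = fit$selection$chosen_k,
                                     rule_applied = fit$selection$rule_applied),
                                auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "group_selection.json"))
  write.csv(fit$assignments, file.path(out_dir, "assignments.csv"),
            row.names = FALSE)
  write.csv(fit$contingents$table, file.path(out_dir, "contingents.csv"),
            row.names = FALSE)
  freq <- data.frame(behavior = rownames(fit$frequency$counts),
                     fit$frequency$counts, check.names = FALSE)
  write.csv(freq, file.path(out_dir, "behavior_frequency.csv"), row.names = FALSE)
  write.csv(fit$residency_summary, file.path(out_dir, "lake_residency.csv"),
            row.names = FALSE)
  prov <- list(population = cfg$population, seed = cfg$seed,
               timeframe = format(fit$timeframe), kmax = cfg$kmax,
               benchmark = cfg$benchmark, rules = unclass(cfg$rules),
               n_fish = nrow(fit$assignments),
               package_version = as.character(utils::packageVersion("adfluvial")))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "provenance.json"))
  invisible(fit)
}
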