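#' Published migratory-behavior counts for six Great Lakes populations
#'
#' Per-population counts of classified lake sturgeon by migratory behavior,
#' as reported by a long-term (6–10 year) multi-population acoustic
#' telemetry study of the Laurentian Great Lakes: Huron-Erie Corridor (HEC),
#' Green Bay (GB), St. Louis River Estuary (SLRE), Black Sturgeon River
#' (BSR), eastern Lake Superior (ELS) and eastern Lake Erie (ELE); 618
#' classified fish in total.  Used as a reference input for frequency-table
#' arithmetic (the raw telemetry behind the counts is not public).
#'
#' @param long Logical; return long format (`population`, `behavior`,
#'   `count`) instead of the behavior × population wide table.
#' @return data.frame of counts.
#' @export
published_behavior_counts <- function(long = FALSE) {
  path <- system.file("extdata", "published_behavior_counts.csv",
                      package = "adfluvial", mustWork = TRUE)
  wide <- read.csv(path, stringsAsFactors = FALSE)
  if (!long) return(wide)
  pops <- names(wide)[-1]
  do.call(rbind, lapply(pops, function(p)
    data.frame(population = p, behavior = wide$behavior, count = wide[[p]],
               stringsAsFactors = FALSE)))
}

#' Expand published counts into a pseudo-assignment table
#'
#' Replicates one row per counted fish so that table-level operations
#' ([behavior_frequency_table()]) can be exercised against the published
#' marginals.
#'
#' @return data.frame with `fish_id`, `behavior`, `population`.
#' @export
published_counts_as_assignments <- function() {
  counts <- published_behavior_counts(long = TRUE)
  counts <- counts[counts$count > 0, , drop = FALSE]
  idx <- rep(seq_len(nrow(counts)), counts$count)
  out <- data.frame(
    behavior = counts$behavior[idx],
    population = counts$population[idx],
    stringsAsFactors = FALSE
  )
  out$fish_id <- sprintf("P%04d", seq_len(nrow(out)))
  out[c("fish_id", "behavior", "population")]
}
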