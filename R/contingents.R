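# Contingent route signatures, frequency tables, residency summaries and
# sex-ratio goodness-of-fit tests.

#' Contingent route signature of a fish
#'
#' Collapses a fish's regional sequence to the ordered regions of one
#' representative migratory cycle, rendered `"A→B(→C)"`.  Cycles are
#' delimited by returns to the fish's home region (its first observed
#' region); the representative cycle is the most frequent cycle signature
#' across observed years, ties resolved toward the earliest cycle.  River
#' residents yield a single-region signature.
#'
#' @param regional_seq A region-level [daily_seq()].
#' @param behavior Optional behavior label (unused by the computation,
#'   retained for bookkeeping in combined tables).
#' @return Character scalar, e.g. `"LSC→DR"` or `"SLRE"`.
#' @export
route_signature <- function(regional_seq, behavior = NULL) {
  stopifnot(inherits(regional_seq, "daily_seq"))
  obs <- regional_seq$states[!regional_seq$states %in% c(.MISSING, .VOID)]
  if (length(obs) == 0L) stopf("fish %s: empty sequence", regional_seq$fish_id)
  runs <- rle(obs)$values
  home <- runs[1]
  if (all(runs == home)) return(home)
  anchors <- which(runs == home)
  # cycles: home run up to (but excluding) the next home run
  sigs <- character()
  for (i in seq_along(anchors)) {
    from <- anchors[i]
    to <- if (i < length(anchors)) anchors[i + 1L] - 1L else length(runs)
    cyc <- runs[from:to]
    if (length(cyc) < 2L) next  # no excursion in this cycle
    sigs <- c(sigs, paste(cyc[!duplicated(cyc)], collapse = "→"))
  }
  if (!length(sigs)) {
    # excursions exist but never return home (e.g. truncated record):
    # fall back to first-use order over the whole sequence
    return(paste(runs[!duplicated(runs)], collapse = "→"))
  }
  counts <- table(sigs)
  best <- names(counts)[counts == max(counts)]
  sigs[sigs %in% best][1L]   # earliest among the most frequent
}

#' Tabulate contingents
#'
#' A contingent is a set of fish sharing both a migratory behavior and a
#' route signature.  Counts partition classified fish; the per-population
#' contingent total is the number of distinct (behavior, signature) pairs.
#'
#' @param assignments data.frame with `fish_id`, `behavior`, and optionally
#'   `population`.
#' @param signatures Named character vector of route signatures by fish id.
#' @return List: `table` (population, behavior, signature, count) and
#'   `totals` (population, n_contingents).
#' @export
tabulate_contingents <- function(assignments, signatures) {
  if (nrow(assignments) == 0L)
    return(list(table = data.frame(population = character(),
                                   behavior = character(),
                                   signature = character(), count = integer(),
                                   stringsAsFactors = FALSE),
                totals = data.frame(population = character(),
                                    n_contingents = integer(),
                                    stringsAsFactors = FALSE)))
  pop <- if ("population" %in% names(assignments)) assignments$population
         else rep("all", nrow(assignments))
  sig <- unname(signatures[assignments$fish_id])
  keep <- assignments$behavior != "UNCLASSIFIED"
  df <- data.frame(population = pop[keep],
                   behavior = assignments$behavior[keep],
                   signature = sig[keep], stringsAsFactors = FALSE)
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   df[c("population", "behavior", "signature")], sum)
  agg <- agg[order(agg$population, agg$behavior, -agg$count), , drop = FALSE]
  rownames(agg) <- NULL
  totals <- aggregate(list(n_contingents = agg$count > 0),
                      agg["population"], length)
  list(table = agg, totals = totals)
}

round_half_up <- function(x) floor(x + 0.5)

#' Behavior frequency table
#'
#' Counts and whole-percent shares of each migratory behavior per population
#' and overall, with a total row — percentages are recomputed from the
#' counts and rounded half-up to the nearest whole percent.  UNCLASSIFIED
#' fish are excluded from the table (reported in the `n_unclassified`
#' attribute).
#'
#' @param assignments data.frame with `behavior` and optionally
#'   `population` (single population assumed otherwise).
#' @return Object of class `frequency_table`: list with `counts` (behavior
#'   × population matrix plus `Total` column), `percent` (same shape),
#'   `total_classified` (per population incl. overall).
#' @export
behavior_frequency_table <- function(assignments) {
  pop <- if ("population" %in% names(assignments)) as.character(assignments$population)
         else rep("all", nrow(assignments))
  keep <- assignments$behavior != "UNCLASSIFIED"
  n_uncl <- sum(!keep)
  b <- factor(assignments$behavior[keep], levels = .BEHAVIORS)
  p <- factor(pop[keep], levels = unique(pop))
  counts <- table(b, p)
  counts <- cbind(counts, Total = rowSums(counts))
  col_tot <- colSums(counts)
  percent <- counts
  for (j in seq_len(ncol(counts)))
    percent[, j] <- if (col_tot[j] > 0) round_half_up(100 * counts[, j] / col_tot[j]) else 0
  structure(
    list(counts = counts, percent = percent, total_classified = col_tot,
         n_unclassified = n_uncl),
    class = "frequency_table"
  )
}

#' @export
print.frequency_table <- function(x, ...) {
  m <- x$counts
  disp <- matrix(sprintf("%d (%d%%)", m, x$percent), nrow(m),
                 dimnames = dimnames(m))
  print(noquote(rbind(disp, Total = as.character(x$total_classified))))
  if (x$n_unclassified > 0)
    cat(sprintf("(%d unclassified fish excluded)\n", x$n_unclassified))
  invisible(x)
}

#' Lake-residency summary by behavior and population
#'
#' Mean ± SD percent of time spent in lakes for each behavior × population
#' group, with sample sizes.  Groups of one report the mean only (SD `NA`).
#' Intermittent-behavior groups whose mean observed history is too short to
#' repeat a full migratory cycle (< 4 years for a biennial pattern) are
#' flagged as potentially truncated.
#'
#' @param assignments data.frame with `behavior`, `lake_residency`, and
#'   optionally `population` and `history_years`.
#' @return data.frame: population, behavior, n, mean_pct, sd_pct,
#'   truncated_cycle_flag.
#' @export
lake_residency_summary <- function(assignments) {
  pop <- if ("population" %in% names(assignments)) as.character(assignments$population)
         else rep("all", nrow(assignments))
  keep <- assignments$behavior != "UNCLASSIFIED"
  a <- assignments[keep, , drop = FALSE]
  pop <- pop[keep]
  if (!nrow(a))
    return(data.frame(population = character(), behavior = character(),
                      n = integer(), mean_pct = numeric(), sd_pct = numeric(),
                      truncated_cycle_flag = logical(), stringsAsFactors = FALSE))
  key <- split(seq_len(nrow(a)), list(pop, a$behavior), drop = TRUE)
  rows <- lapply(names(key), function(k) {
    i <- key[[k]]
    pct <- 100 * a$lake_residency[i]
    hy <- if ("history_years" %in% names(a)) mean(a$history_years[i]) else NA_real_
    data.frame(
      population = pop[i[1]], behavior = a$behavior[i[1]], n = length(i),
      mean_pct = mean(pct),
      sd_pct = if (length(i) > 1L) sd(pct) else NA_real_,
      truncated_cycle_flag = grepl("^intermittent", a$behavior[i[1]]) &&
        !is.na(hy) && hy < 4,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$population, out$behavior), , drop = FALSE]
}

#' Chi-square goodness-of-fit test for a sex ratio
#'
#' Tests whether an observed male:female split within a migratory behavior
#' differs from the population-wide sex ratio of classified fish.  Expected
#' counts under ratio `r` (males per female) are `n·r/(1+r)` males and
#' `n/(1+r)` females; the statistic is the textbook
#' `sum((obs − exp)^2 / exp)` on 1 degree of freedom.  Unknown-sex fish must
#' be excluded upstream.
#'
#' @param observed_m,observed_f Observed male and female counts.
#' @param population_ratio_m_to_f Population sex ratio, males per female
#'   (e.g. 1.05 for 1.05:1).
#' @return List: `chi_square`, `df` (1), `p_value`, `expected` (named
#'   vector).  A warning is issued when an expected count is below 5.
#' @examples
#' sex_ratio_test(30, 10, 1)   # chi-square 10.0
#' @export
sex_ratio_test <- function(observed_m, observed_f, population_ratio_m_to_f) {
  n <- observed_m + observed_f
  if (n < 1L) stopf("need at least one sexed fish")
  r <- population_ratio_m_to_f
  if (r <= 0) stopf("sex ratio must be positive")
  expected <- c(male = n * r / (1 + r), female = n / (1 + r))
  if (any(expected < 5))
    warnf("expected count below 5; chi-square approximation is weak")
  observed <- c(observed_m, observed_f)
  chi <- sum((observed - expected)^2 / expected)
  list(chi_square = chi, df = 1L,
       p_value = pchisq(chi, df = 1, lower.tail = FALSE),
       expected = expected)
}
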