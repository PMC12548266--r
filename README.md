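# adfluvial

Classification of adfluvial fish migratory behaviors from multi-year
acoustic telemetry, developed for lake sturgeon (*Acipenser fulvescens*) in
large lake–river systems.

## What it does, and for whom

Fisheries researchers tracking tagged fish on fixed receiver networks need
to turn millions of time-stamped detections into a per-fish answer to one
question: *what kind of migrant is this animal?*  `adfluvial` implements a
complete, tested pipeline for that question:

1. **Detection and fish filtering** — tag-collision min-lag rule, tag-life
   cut, maturity (< 1 m removed), detection-history span (≥ 2 years),
   spawning evidence, timeframe coverage.
2. **Daily location histories** — one habitat state (river / lake / Lake
   St. Clair) and one region state per fish per calendar day, built with
   first-detection-of-day assignment and last-observation-carried-forward
   (LOCF) imputation, with explicit `MISSING` (before first detection) and
   `VOID` (after last detection) coding.
3. **Sequence dissimilarity** — optimal-matching (OM) edit distance with a
   geographic substitution-cost matrix (0 same state / 1 adjacent / 2
   non-adjacent, missing-vs-observed 2) and constant indel cost 1, half the
   maximum substitution cost; the raw distance

   d(x, y) = min over edit scripts of Σ costs,  normalized by
   d(x, y) / max(|x|, |y|),

   computed by the full O(nm) dynamic program (C++ backend).
4. **Ward clustering with silhouette selection** — agglomerative clustering
   of the dissimilarity matrix; the starting number of behavioral groups is
   the smallest k with average silhouette width (ASW) ≥ 0.5, else the
   highest-ASW k.
5. **Rule-based classification** — a deterministic cascade assigns each
   fish one of seven behaviors (annual / intermittent spring river,
   intermittent two-step, river resident, annual summer river, annual
   winter river, annual interlake) or UNCLASSIFIED, plus its periodicity
   ratio (history years / spring trips, annual ≤ 1.5), lake-residency
   fraction, residency class and contingent route signature; summaries
   include behavior frequency tables, contingent tables, lake-residency
   means ± SD and sex-ratio chi-square goodness-of-fit tests.

Because the motivating study's raw telemetry is not public, the package
ships a first-class synthetic detection generator (`simulate_cohort()`)
that emulates all seven behaviors with known ground truth, configurable
detection probability and transition-date jitter — every pipeline stage is
tested against it.

## Worked example

```r
library(adfluvial)

cfg <- sim_config(n_fish_per_archetype = 3, years = 6, detection_prob = 0.8,
                  transition_jitter_days = 3, seed = 1)
cohort <- simulate_cohort(cfg)
fit <- classify_migration(cohort$detections, cohort$network, cohort$metadata,
                          population = "synthetic")
print(fit)
```

```
Migratory behavior classification — population 'synthetic'
  21 fish over 2015-01-04 .. 2021-02-25
  annual_spring_river        3
  intermittent_spring_river  3
  intermittent_two_step      3
  river_resident             3
  annual_summer_river        3
  annual_winter_river        3
  annual_interlake           3
  clustering guide: k = 2 (ASW 0.57, parsimonious_above_benchmark)
```

All 21 simulated fish recover their true behavior despite 20% missed
detection days and 3-day transition jitter.  The clustering guide chooses
k = 2 with ASW 0.57: silhouette-optimal partitions split fish by overall
residence time (river- vs lake-dominant), not by transition timing — which
is exactly why the final labels come from the rule cascade, with the
cluster-vs-rule disagreement reported (`fit$disagreement_rate`, here 0.71)
rather than hidden.  `summary(fit)` adds frequency, contingent and
residency tables; `plot(fit)` draws a sequence-index panel.

Single pieces are usable on their own, e.g. a sex-ratio test of 30 males
and 10 females against an even population ratio:

```r
sex_ratio_test(30, 10, 1)
#> $chi_square  10      $df  1      $p_value  0.00157
```

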