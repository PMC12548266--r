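---
title: "Classifying adfluvial migratory behaviors from acoustic telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying adfluvial migratory behaviors from acoustic telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adfluvial)
```

## The problem

Lake sturgeon (*Acipenser fulvescens*) are long-lived, adfluvial fish: they
reside in lakes and migrate into rivers, classically for spring spawning.
Multi-year acoustic telemetry shows that this textbook picture hides
substantial within-population diversity — some fish enter rivers every
spring, some every second or third year, some overwinter in the river near
the spawning site, some live in the river year-round, and a few shuttle
between lakes through connecting channels.  `adfluvial` turns raw detection
records (fish, timestamp, receiver) into per-fish daily location histories,
quantifies how similar those histories are, and classifies each fish into
one of seven migratory behaviors with supporting statistics (contingent
routes, periodicity, lake residency, behavior frequencies, sex-ratio
tests).

The pipeline has five stages, each exposed as ordinary functions and
wrapped by the fitting function `classify_migration()`:

1. **Filtering** (`filter_detections_and_fish()`).  Detections pass a
   min-lag tag-collision filter and a tag-life cut; fish pass maturity
   (total length ≥ 1 m), history-span (≥ 2 years between first and last
   detection, the minimum to observe a repeated annual pattern),
   spawning-evidence (≥ 1 river detection inside the April–June window) and
   timeframe-coverage filters, in that order.
2. **Daily location histories** (`build_daily_sequence()`).  Each fish gets
   one state per calendar day at habitat level (river / lake / Lake
   St. Clair) and at region level.  A day with detections takes its *first*
   detection's location; undetected days carry forward the *last* detection
   of the most recent detection day (LOCF); days before the first detection
   are `MISSING`; days after the final detection are `VOID`.
3. **Dissimilarity** (`om_distance()`, `dissimilarity_matrix()`).  Optimal
   matching with a geographic substitution-cost matrix: 0 for the same
   state, 1 for adjacent states (sharing a confluence), 2 otherwise; indel
   cost 1; `MISSING` costs 2 against any observed state.  Distances are
   normalized by the longer sequence's length.
4. **Clustering guide** (`ward_tree()`, `select_group_number()`).  Ward
   agglomerative clustering on the dissimilarity matrix; the starting group
   number is the smallest k whose average silhouette width (ASW) reaches
   0.5, falling back to the highest-ASW k.
5. **Rule cascade** (`classify_behavior()`).  A deterministic, ordered rule
   set stands in for case-by-case visual inspection and assigns the final
   label; the cluster labels are recorded next to the rule labels and the
   disagreement rate is reported.

## The cost model and why indel = 1

Substitution costs are a crude geography: moving a fish's state between
adjacent waters costs 1, between non-adjacent waters 2.  The indel cost of
1 is half the maximum substitution cost, which guarantees an insertion or
deletion is never cheaper than a substitution — sequences are compared in
calendar alignment unless shifting is genuinely cheaper.  Left-missing days
cost 2 against any observed state, which pins late-starting sequences to
their true calendar position instead of letting them slide left to align
with earlier starters; two fish both unobserved on a day cost 0 (we do not
invent dissimilarity from shared ignorance).  With these values the raw
distance is a true metric (symmetry, zero self-distance, triangle
inequality), which the test suite verifies on random triples.

"Abbott's normalization" is implemented as raw distance divided by the
longer sequence's length — the *maxlength* convention.  The source
literature names the normalization without writing the formula; maxlength
is the standard reading of "dissimilarity that does not depend solely on
differences in sequence lengths" and is flagged here as an interpretation.

`VOID` suffixes are stripped before any distance computation: days after a
fish's final detection carry no behavioral information, and carrying LOCF
across them would fabricate months of residence (a dead battery is not site
fidelity).  For the same reason `lake_residency()` excludes `MISSING` and
`VOID` days from both numerator and denominator.

## Clustering choices

Ward clustering on a precomputed, non-Euclidean dissimilarity is executed
with `stats::hclust(method = "ward.D2")`, the classical AGNES "ward"
behavior (the Lance–Williams recurrence on squared dissimilarities); the
test suite checks partition-level equivalence against `cluster::agnes` on
random matrices.  The ASW benchmark comparison uses ≥ 0.5 (the boundary
value counts as biologically relevant); ties in the fallback rule go to the
smaller k.  Silhouettes use the standard convention s(i) = 0 for singleton
clusters and for the degenerate 0/0 case.

Clustering is a *guide*, not the classifier: silhouette-optimal partitions
of habitat sequences separate fish by overall residence time rather than by
transition timing (on the synthetic seven-archetype cohort the selected k
is typically 2 — river-dominant versus lake-dominant — exactly the behavior
reported for real data).  The deterministic rule cascade therefore makes
the final call, and the fit records the cluster-versus-rule disagreement
rate rather than hiding it.

## The rule cascade

Rules are evaluated in a fixed order and the first match wins:
river resident → annual interlake → annual winter river → annual summer
river → intermittent two-step → spring river migrant (annual vs.
intermittent by periodicity ratio) → UNCLASSIFIED.  The ordering resolves
genuine overlaps: a two-step migrant also enters the river in the fall
(like a winter-river migrant), but only the winter-river migrant leaves in
March–May; a summer-river migrant's episode overlaps the spawning window
(like a spring trip) but fails the trip-length cap.

Thresholds that the source description leaves qualitative are configurable
in `rule_config()` with the following defaults, chosen once from the
reported summaries:

* `spring_trip_max_days = 45` — reported spring trips last ~1–3 weeks; 45
  days gives margin for detection lag before a stay reads as summer
  residence.
* `resident_max_lake_fraction = 0.10` — river residents' reported lake time
  is 1–5%.
* `fifty_fifty_band = c(0.35, 0.60)` — brackets the reported 42–52% lake
  residency of long two-step migrants.
* "Annual" patterns must recur in at least (observed years − 1) years,
  tolerating one missed year from detection gaps.
* The periodicity ratio (history years / spring trips) splits annual
  (≤ 1.5) from intermittent (> 1.5) spring migrants, boundary inclusive.
  Spring trips are counted against the configurable spawning window
  (April–June by default); the source text mentions both March–April and
  April–June windows, so the window is a parameter rather than a guess, and
  history years are fractional.

One deliberate extension: the two-step rule also recognizes the
two-transition variant (fall transit through a connecting river to Lake
St. Clair, overwintering there, then a spring move to the spawning river).
Under a literal one-line rule — "a fall-entry episode spanning the next
spawning window" — that variant's short fall transit and short spring
episode would fall through to the spring-migrant rule and be mislabeled.
The extension requires the between-episode days to be spent in Lake
St. Clair, so ordinary spring migrants cannot trigger it.

The interlake rule requires the annual cycle (Lake St. Clair overwinter,
river transit, a different lake in summer, return) in at least two
*consecutive* years: a biennial two-step migrant overwintering in Lake
St. Clair produces the same within-year pattern but only every other year,
and consecutiveness is what separates them.

## The synthetic generator

No raw telemetry from the source study is public, so the generator is the
package's test bed and defines the study conditions: a compact
Huron–Erie-like geography (`default_layout()`: main lake, Lake St. Clair,
connecting channel, spawning river, two receivers per region), seven
behavior archetypes with nominal transition calendars (`default_archetypes()`;
e.g. spring migrants enter ~Apr 30 for ~2.5 weeks, winter migrants hold the
river ~Sep 15–Apr 15, the long biennial two-step holds it ~Oct 1–Sep 7 the
following year), 6-year records, and tagging dates spread over Jan–Feb of
year one.  Two noise dials exist: the per-day detection probability and
Gaussian jitter (SD in days) on every scheduled transition date.  A
detected fish-day emits a burst of three pings minutes apart — what a
69 kHz tag does while a fish holds near a receiver — because a single ping
per day would be isolated on its receiver and the min-lag collision filter
would (correctly) delete the entire record.

What the generator does *not* emulate: receiver-coverage gaps and array
turnover, tag death before the analysis window ends, partial river
penetration (a fish detected only at a river mouth), multi-river
contingents within one population, fine-scale movement within a region, and
behavior switching between years.  Tests that pass on synthetic cohorts
therefore demonstrate that the pipeline inverts its own generative
assumptions — 100% label recovery noise-free, and ≥ 95% at detection
probability 0.3 with 7-day transition jitter — not that it would classify
every real fish correctly; real sequences that conform to no rule end up
UNCLASSIFIED by design.

Problem sizes used in the shipped tests and acceptance script were chosen
to exercise every stage at realistic scale while staying quick on a
laptop: 7 archetypes × 10 fish × 6 years (≈ 2,200-day sequences, 2,415
pairwise distances) for the end-to-end runs, 200+ random short sequences
for the distance oracle, 50 random matrices for the clustering oracle, and
1,000 random triples for the metric properties.

## Numerical and degenerate-input conventions

* Calendar days are UTC; a detection belongs to the UTC date of its
  timestamp (reproducibility over local-time fidelity; the original
  study's convention is unstated).
* The min-lag boundary is inclusive (a gap of exactly `tf` seconds is
  kept), and the maturity cut is strict (`< 1 m` removed, 1.00 m kept).
* Fish with unknown length are retained with a warning — only confirmed
  sub-meter fish are removed.
* Merge tie-breaks in clustering follow `hclust`'s deterministic ordering;
  the selection rule breaks ASW ties toward smaller k.
* Percentages in frequency tables round half-up to whole percent;
  residency summaries use the sample SD and report mean-only for n = 1.
* Chi-square sex-ratio tests warn when an expected count drops below 5;
  unknown-sex fish must be excluded upstream.
* Empty layouts, inverted windows, unknown receivers, zero spring trips and
  all-MISSING sequences raise immediate errors naming the offender.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_fish_per_archetype = 3, years = 6, detection_prob = 0.8,
                  transition_jitter_days = 3, seed = 1)
cohort <- simulate_cohort(cfg)
fit <- classify_migration(cohort$detections, cohort$network, cohort$metadata,
                          population = "synthetic")
print(fit)
summary(fit)
plot(fit)
table(truth = cohort$truth$behavior,
      assigned = fit$assignments$behavior[match(cohort$truth$fish_id,
                                                fit$assignments$fish_id)])
```

For a file-based run, `write_cohort()` + `run_config()` + `run_pipeline()`
write every stage's artifacts (filter reports, sequences, dissimilarity
matrix, group selection, assignments, tables, provenance) to a directory,
and re-running the same configuration reproduces them byte-for-byte.

## Known limitations

* The rule cascade is an explicit stand-in for expert visual inspection;
  behaviors outside its vocabulary (e.g. multi-river annual cycles) are
  UNCLASSIFIED rather than approximated.
* Route signatures take one representative cycle; fish alternating between
  spawning rivers are summarized by their most frequent cycle only.
* The normalization and squared-dissimilarity conventions are documented
  interpretations of named methods, configurable where they matter.
* Lake-residency values for behaviors whose full cycle exceeds the analysis
  window are flagged, not corrected.
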