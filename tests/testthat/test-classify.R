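# Helper: build aligned habitat/regional sequences from a region state vector
# on the default study-system geography.
seq_pair <- function(regions, start = "2015-01-01", fish = "f") {
  r2h <- c(LH = "lake", LSC = "lake_st_clair", SCR = "river", SR = "river",
           MISSING = "MISSING", VOID = "VOID")
  hab <- unname(r2h[regions])
  list(
    habitat = daily_seq(fish, start, hab, "habitat",
                        c("river", "lake", "lake_st_clair")),
    regional = daily_seq(fish, start, regions, "region",
                         c("LH", "LSC", "SCR", "SR"))
  )
}

test_that("river episodes are maximal river runs with region and window flags", {
  regions <- c(rep("LH", 100), rep("SR", 20), rep("LH", 1), rep("SR", 5),
               rep("LH", 239))
  sp <- seq_pair(regions)  # starts Jan 1: river runs in Apr/May
  ep <- extract_river_episodes(sp$habitat, sp$regional)
  expect_equal(nrow(ep), 2L)   # a single lake day splits the runs
  expect_equal(ep$region, c("SR", "SR"))
  expect_equal(ep$duration, c(20L, 5L))
  expect_true(all(ep$overlaps_spawning_window))

  all_lake <- seq_pair(rep("LH", 50))
  expect_equal(nrow(extract_river_episodes(all_lake$habitat, all_lake$regional)), 0L)

  mis <- seq_pair(rep("LH", 49))
  expect_error(extract_river_episodes(all_lake$habitat, mis$regional),
               "misaligned")
})

test_that("periodicity ratio follows the 1.5 threshold with inclusive boundary", {
  expect_equal(periodicity_ratio(6, 6), list(ratio = 1, class = "annual"))
  expect_equal(periodicity_ratio(6, 3), list(ratio = 2, class = "intermittent"))
  expect_equal(periodicity_ratio(3, 2), list(ratio = 1.5, class = "annual"))
  expect_equal(periodicity_ratio(1.51, 1)$class, "intermittent")
  expect_error(periodicity_ratio(6, 0), "zero")
  # enumerated grid: exact ratios and classes
  for (y in 2:8) for (trips in 1:6) {
    p <- periodicity_ratio(y, trips)
    expect_equal(p$ratio, y / trips)
    expect_equal(p$class, if (y / trips <= 1.5) "annual" else "intermittent")
  }
})

test_that("lake residency counts lake states over observed days only", {
  all_lake <- seq_pair(rep("LH", 40))
  expect_equal(lake_residency(all_lake$habitat), 1.0)

  half <- seq_pair(c(rep("LH", 183), rep("SR", 183)))
  expect_equal(lake_residency(half$habitat), 0.5)

  with_gaps <- seq_pair(c(rep("MISSING", 10), rep("LH", 30), rep("SR", 10),
                          rep("VOID", 5)))
  expect_equal(lake_residency(with_gaps$habitat), 30 / 40)

  # counting oracle on a generated archetype
  cfg <- sim_config(years = 5, detection_prob = 1, transition_jitter_days = 0,
                    seed = 17, tagging_date_range = c("2015-01-01", "2015-01-01"))
  set.seed(7)
  one <- simulate_individual(default_archetypes()$annual_spring_river, cfg, "f")
  s <- build_daily_sequence(one$detections, cfg$network, level = "habitat")
  expect_equal(lake_residency(s), mean(one$true_states$region == "LH"))
})

test_that("noise-free archetype sequences invert to their own labels", {
  cfg <- sim_config(years = 6, detection_prob = 1, transition_jitter_days = 0,
                    seed = 23, tagging_date_range = c("2015-01-01", "2015-01-01"))
  archs <- c(default_archetypes(),
             list(two_step_short = two_step_archetype(duration = "short"),
                  two_step_two_transitions = two_step_archetype(n_transitions = 2)))
  expected <- c(names(default_archetypes()), "intermittent_two_step",
                "intermittent_two_step")
  for (i in seq_along(archs)) {
    set.seed(100 + i)
    one <- simulate_individual(archs[[i]], cfg, paste0("f", i))
    hab <- build_daily_sequence(one$detections, cfg$network, level = "habitat")
    reg <- build_daily_sequence(one$detections, cfg$network, level = "region")
    a <- classify_behavior(hab, reg)
    expect_equal(a$behavior, expected[i],
                 label = sprintf("archetype %s", names(archs)[i]))
  }
})

test_that("long biennial two-step reads as 50:50 lake:river residency", {
  cfg <- sim_config(years = 6, detection_prob = 1, transition_jitter_days = 0,
                    seed = 29, tagging_date_range = c("2015-01-01", "2015-01-01"))
  set.seed(3)
  one <- simulate_individual(default_archetypes()$intermittent_two_step, cfg, "f")
  hab <- build_daily_sequence(one$detections, cfg$network, level = "habitat")
  reg <- build_daily_sequence(one$detections, cfg$network, level = "region")
  a <- classify_behavior(hab, reg)
  expect_equal(a$behavior, "intermittent_two_step")
  expect_equal(a$residency_class, "fifty_fifty")
  expect_true(is.na(a$periodicity_ratio))
})

test_that("river residents keep lake residency below the resident cutoff", {
  cfg <- sim_config(years = 4, detection_prob = 1, seed = 31)
  set.seed(5)
  one <- simulate_individual(default_archetypes()$river_resident, cfg, "f")
  hab <- build_daily_sequence(one$detections, cfg$network, level = "habitat")
  reg <- build_daily_sequence(one$detections, cfg$network, level = "region")
  a <- classify_behavior(hab, reg)
  expect_equal(a$behavior, "river_resident")
  expect_true(a$lake_residency <= rule_config()$resident_max_lake_fraction)
  expect_equal(a$residency_class, "river_dominant")
})

test_that("sequences conforming to no rule fall through to UNCLASSIFIED", {
  # mid-winter two-week river blip each year: no rule matches
  regions <- rep("LH", 365 * 3)
  dates <- seq(as.Date("2015-01-01"), by = "day", length.out = length(regions))
  regions[format(dates, "%m-%d") >= "01-10" &
            format(dates, "%m-%d") <= "01-24"] <- "SR"
  sp <- seq_pair(regions)
  a <- classify_behavior(sp$habitat, sp$regional)
  expect_equal(a$behavior, "UNCLASSIFIED")
})

test_that("classification is deterministic and exclusive", {
  cfg <- sim_config(n_fish_per_archetype = 1, years = 4, detection_prob = 0.6,
                    transition_jitter_days = 2, seed = 37)
  coh <- simulate_cohort(cfg)
  tf <- range(as.Date(format(coh$detections$timestamp, tz = "UTC", "%Y-%m-%d")))
  hab <- build_cohort_sequences(coh$detections, coh$network, tf, "habitat")
  reg <- build_cohort_sequences(coh$detections, coh$network, tf, "region")
  r1 <- classify_cohort(hab, reg)
  r2 <- classify_cohort(hab, reg)
  expect_identical(r1$assignments, r2$assignments)
  expect_equal(nrow(r1$assignments), length(hab))
  expect_true(all(r1$assignments$behavior %in% c(behavior_labels(),
                                                 "UNCLASSIFIED")))
})

test_that("cluster guide separates two clearly distinct archetypes", {
  cfg <- sim_config(n_fish_per_archetype = 4, years = 4, detection_prob = 1,
                    transition_jitter_days = 0, seed = 41)
  coh <- simulate_cohort(cfg, default_archetypes()[c("river_resident",
                                                     "annual_spring_river")])
  tf <- range(as.Date(format(coh$detections$timestamp, tz = "UTC", "%Y-%m-%d")))
  hab <- build_cohort_sequences(coh$detections, coh$network, tf, "habitat")
  reg <- build_cohort_sequences(coh$detections, coh$network, tf, "region")
  cost <- build_cost_matrix(c("river", "lake", "lake_st_clair"),
                            default_adjacency("habitat"))
  d <- dissimilarity_matrix(hab, cost)
  res <- classify_cohort(hab, reg, d)
  expect_equal(res$selection$chosen_k, 2L)
  # each cluster is pure in rule labels
  tab <- table(res$assignments$cluster_id, res$assignments$behavior)
  expect_true(all(rowSums(tab > 0) == 1L))
  expect_equal(res$disagreement_rate, 0)
})
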