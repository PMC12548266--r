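test_that("min-lag rule removes isolated detections, keeps bursts, boundary inclusive", {
  ev <- det(
    c("f1", "f1", "f1", "f2", "f2", "f3"),
    c("2020-05-01 10:00:00", "2020-05-01 10:01:00",  # 60 s burst: kept
      "2020-06-01 00:00:00",                          # isolated on R1: removed
      "2020-05-01 10:00:00", "2020-05-01 12:00:00",  # 7200 s apart: removed
      "2020-05-01 10:00:00"),                         # lone detection: removed
    c("R1", "R1", "R1", "R1", "R1", "R1")
  )
  out <- filter_false_detections(ev, tf = 3600)
  expect_equal(nrow(out$events), 2L)
  expect_true(all(out$events$fish_id == "f1"))
  expect_equal(out$report$n_removed, 4L)
  expect_equal(out$report$n_removed + out$report$n_retained, out$report$n_input)

  # boundary: min lag exactly tf is kept
  ev2 <- det(c("f", "f"), c("2020-05-01 10:00:00", "2020-05-01 11:00:00"), "R1")
  expect_equal(nrow(filter_false_detections(ev2, tf = 3600)$events), 2L)
  # ... and one second more is removed
  ev3 <- det(c("f", "f"), c("2020-05-01 10:00:00", "2020-05-01 11:00:01"), "R1")
  expect_equal(nrow(filter_false_detections(ev3, tf = 3600)$events), 0L)

  expect_error(filter_false_detections(ev, tf = 0), "positive")

  # projection + idempotence
  again <- filter_false_detections(out$events, tf = 3600)
  expect_equal(again$events, out$events)
})

test_that("tag-life filter drops detections past expiry", {
  meta <- data.frame(fish_id = "f1", total_length = 1.4, sex = "male",
                     tagging_date = as.Date("2010-01-01"), tag_life_years = 10)
  ev <- det("f1",
            c("2019-12-01 00:00:00",   # 9.9 years: kept
              "2020-01-02 00:00:00"),  # 10 years + 1 day: removed
            c("R1", "R1"))
  out <- filter_tag_life(ev, meta)
  expect_equal(nrow(out$events), 1L)
  expect_equal(out$report$n_removed, 1L)

  empty <- ev[0, ]
  out0 <- filter_tag_life(empty, meta)
  expect_equal(nrow(out0$events), 0L)
  expect_equal(out0$report$n_input, 0L)

  expect_error(filter_tag_life(det("ghost", "2020-01-01 00:00:00", "R1"), meta),
               "ghost")
})

test_that("maturity filter is strict at 1 m and warns on unknown lengths", {
  meta <- data.frame(fish_id = c("a", "b", "c", "d"),
                     total_length = c(0.95, 1.00, 1.50, NA))
  expect_warning(out <- filter_immature(meta), "unknown")
  expect_setequal(out$fish_ids, c("b", "c", "d"))
  expect_equal(out$report$removed, "a")
})

test_that("history-span filter requires two years between first and last detection", {
  ev <- rbind(
    det("short", c("2018-01-01 00:00:00", "2019-11-27 00:00:00"), "R1"), # 1.9 y
    det("long", c("2018-01-01 00:00:00", "2020-02-06 00:00:00"), "R1"),  # 2.1 y
    det("single", "2018-06-01 00:00:00", "R1")
  )
  out <- filter_history_span(ev, min_years = 2)
  expect_equal(out$fish_ids, "long")
  expect_setequal(out$report$removed, c("short", "single"))
})

test_that("spawning-evidence filter needs a river detection inside the window", {
  st <- two_region_stations()
  ev <- rbind(
    det("lakeonly", c("2019-05-01 00:00:00", "2019-08-01 00:00:00"),
        c("LK-01", "LK-02")),
    det("spawner", "2019-05-10 00:00:00", "RV-01"),
    det("augriver", "2019-08-15 00:00:00", "RV-01")
  )
  out <- filter_spawning_evidence(ev, st)
  expect_equal(out$fish_ids, "spawner")
  expect_error(filter_spawning_evidence(ev, st, river_station_set = character()),
               "empty river station set")
})

test_that("timeframe-coverage filter keeps boundary detections", {
  ev <- rbind(det("early", "2015-01-01 00:00:00", "R1"),
              det("edge", "2018-01-01 00:00:00", "R1"),
              det("inside", "2019-06-01 00:00:00", "R1"))
  out <- filter_timeframe_coverage(ev, c("2018-01-01", "2020-01-01"))
  expect_setequal(out$fish_ids, c("edge", "inside"))
  expect_error(filter_timeframe_coverage(ev, c("2020-01-01", "2018-01-01")),
               "inverted")
})

test_that("cascade applies filters in order and reconciles counts", {
  cfg <- sim_config(n_fish_per_archetype = 2, years = 3, detection_prob = 0.5,
                    seed = 5)
  coh <- simulate_cohort(cfg)
  out <- filter_detections_and_fish(coh$detections, coh$network, coh$metadata)
  expect_equal(names(out$reports),
               c("false_detections", "tag_life", "immature", "history_span",
                 "spawning_evidence"))
  for (r in out$reports)
    expect_equal(r$n_removed + r$n_retained, r$n_input)
  expect_true(all(out$events$fish_id %in% out$fish_ids))
  expect_true(nrow(out$events) <= nrow(coh$detections))
  # all simulated adults with 3-year records survive the cascade
  expect_setequal(out$fish_ids, coh$metadata$fish_id)
})
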