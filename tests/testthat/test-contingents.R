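mkreg <- function(regions, fish = "f") {
  daily_seq(fish, "2015-01-01", regions, "region", unique(regions))
}

test_that("route signatures collapse a representative cycle", {
  # LSC winter, Detroit River spring trip, back to LSC — every year
  yr <- c(rep("LSC", 100), rep("DR", 20), rep("LSC", 245))
  expect_equal(route_signature(mkreg(rep(yr, 3))), "LSC→DR")

  # year-round river resident
  expect_equal(route_signature(mkreg(rep("SLRE", 400))), "SLRE")

  # interlake loop: LSC -> DR -> LE -> DR -> LSC collapses to first-use order
  loop <- c(rep("LSC", 100), rep("DR", 15), rep("LE", 130), rep("DR", 15),
            rep("LSC", 105))
  expect_equal(route_signature(mkreg(rep(loop, 2))), "LSC→DR→LE")

  # most frequent cycle wins; ties resolve to the earliest
  mixed <- c(rep(c(rep("LM", 300), rep("MR", 65)), 2),
             rep("LM", 300), rep("PR", 65), rep("LM", 10))
  expect_equal(route_signature(mkreg(mixed)), "LM→MR")

  expect_error(route_signature(mkreg(rep("MISSING", 5))), "empty")
})

test_that("contingent tabulation counts distinct behavior-route pairs", {
  a <- data.frame(
    fish_id = c("f1", "f2", "f3", "f4", "f5"),
    behavior = c("annual_spring_river", "annual_spring_river",
                 "annual_spring_river", "river_resident", "UNCLASSIFIED"),
    population = "HEC", stringsAsFactors = FALSE
  )
  sig <- c(f1 = "LSC→DR", f2 = "LSC→DR", f3 = "LSC→SCR", f4 = "DR", f5 = "LE")
  out <- tabulate_contingents(a, sig)
  expect_equal(sum(out$table$count), 4L)       # unclassified excluded
  expect_equal(nrow(out$table), 3L)            # three contingents
  expect_equal(out$totals$n_contingents, 3L)
  expect_equal(out$table$count[out$table$signature == "LSC→DR"], 2L)

  # invariant to fish ordering
  out2 <- tabulate_contingents(a[5:1, ], sig)
  expect_equal(out$table, out2$table)

  empty <- tabulate_contingents(a[0, ], sig)
  expect_equal(nrow(empty$table), 0L)
})

test_that("frequency table reproduces published marginals from raw counts", {
  tab <- behavior_frequency_table(published_counts_as_assignments())
  expect_equal(unname(tab$total_classified[["Total"]]), 618)
  expect_equal(unname(tab$counts["intermittent_spring_river", "Total"]), 169)
  expect_equal(unname(tab$percent["intermittent_spring_river", "Total"]), 27)
  expect_equal(unname(tab$counts["annual_interlake", "Total"]), 22)
  expect_equal(unname(tab$percent["annual_interlake", "Total"]), 4)
  # column totals reconcile with per-population classified counts
  expect_equal(unname(tab$total_classified[c("HEC", "GB", "SLRE", "BSR",
                                             "ELS", "ELE")]),
               c(238, 185, 94, 18, 28, 55))

  single <- behavior_frequency_table(
    data.frame(fish_id = "x", behavior = "river_resident",
               stringsAsFactors = FALSE))
  expect_equal(unname(single$percent["river_resident", "Total"]), 100)
})

test_that("lake residency summary uses sample SD and flags short intermittent groups", {
  a <- data.frame(
    fish_id = c("a", "b", "c", "d", "e"),
    behavior = c("annual_spring_river", "annual_spring_river",
                 "intermittent_two_step", "intermittent_two_step",
                 "river_resident"),
    lake_residency = c(0.4, 0.6, 1.0, 1.0, 0.02),
    history_years = c(6, 6, 2.5, 2.5, 6),
    stringsAsFactors = FALSE
  )
  out <- lake_residency_summary(a)
  spring <- out[out$behavior == "annual_spring_river", ]
  expect_equal(spring$mean_pct, 50)
  expect_equal(round(spring$sd_pct), 14)
  two <- out[out$behavior == "intermittent_two_step", ]
  expect_equal(two$mean_pct, 100)
  expect_equal(two$sd_pct, 0)
  expect_true(two$truncated_cycle_flag)
  res <- out[out$behavior == "river_resident", ]
  expect_equal(res$n, 1L)
  expect_true(is.na(res$sd_pct))
})

test_that("sex-ratio chi-square matches closed form and the textbook formula", {
  expect_equal(sex_ratio_test(30, 10, 1)$chi_square, 10)
  expect_equal(sex_ratio_test(20, 20, 1)$chi_square, 0)
  t3 <- sex_ratio_test(20, 20, 1.05)
  expect_equal(t3$expected[["male"]], 40 * 1.05 / 2.05)
  expect_equal(t3$chi_square, 0.0238, tolerance = 1e-2)
  expect_equal(t3$df, 1L)

  set.seed(51)
  for (i in 1:25) {
    m <- sample(5:60, 1); f <- sample(5:60, 1)
    r <- runif(1, 0.5, 2)
    got <- sex_ratio_test(m, f, r)
    ref <- suppressWarnings(
      stats::chisq.test(c(m, f), p = c(r / (1 + r), 1 / (1 + r))))
    expect_equal(got$chi_square, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
    expect_true(got$chi_square >= 0)
  }
  expect_warning(sex_ratio_test(3, 1, 1), "below 5")
  expect_error(sex_ratio_test(0, 0, 1), "at least one")
})
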