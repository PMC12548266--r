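random_dissim <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("ward tree joins zero-distance pairs first with monotone heights", {
  m <- matrix(1, 4, 4); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0
  m[3, 4] <- m[4, 3] <- 0
  tree <- ward_tree(m)
  expect_equal(tree$height[1:2], c(0, 0))
  expect_equal(sort(cut_tree(tree, 2)), sort(c(1, 1, 2, 2)))
  expect_true(same_partition(cut_tree(tree, 2), c(1, 1, 2, 2)))

  set.seed(31)
  for (i in 1:10) {
    tr <- ward_tree(random_dissim(8))
    expect_true(all(diff(tr$height) >= -1e-12))
  }

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_tree(bad), "symmetric")
  expect_error(ward_tree(matrix(-1, 2, 2)), "negative")
})

test_that("ward partitions match the AGNES reference at every k", {
  set.seed(32)
  for (rep in 1:50) {
    n <- sample(4:10, 1)
    m <- random_dissim(n)
    tree <- ward_tree(m)
    ref <- cluster::agnes(as.dist(m), diss = TRUE, method = "ward")
    for (k in 2:(n - 1)) {
      expect_true(same_partition(cut_tree(tree, k),
                                 cutree(as.hclust(ref), k)))
    }
  }
})

test_that("cut_tree spans singletons to one group and refines downward", {
  set.seed(33)
  m <- random_dissim(7)
  tree <- ward_tree(m)
  expect_equal(length(unique(cut_tree(tree, 7))), 7L)
  expect_equal(length(unique(cut_tree(tree, 1))), 1L)
  expect_error(cut_tree(tree, 0), "k must be")
  expect_error(cut_tree(tree, 8), "k must be")
  for (k in 2:6) {
    lo <- cut_tree(tree, k)
    hi <- cut_tree(tree, k + 1)
    # every k+1 group sits inside one k group
    expect_true(all(tapply(lo, hi, function(g) length(unique(g))) == 1L))
  }
})

test_that("average silhouette matches closed-form arithmetic and conventions", {
  # perfect separation: within 0, between 1
  m <- matrix(1, 4, 4); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0; m[3, 4] <- m[4, 3] <- 0
  expect_equal(average_silhouette(m, c(1, 1, 2, 2)), 1)

  # all-identical points: 0/0 -> 0 convention
  z <- matrix(0, 4, 4)
  expect_equal(average_silhouette(z, c(1, 2, 1, 2)), 0)

  # 5-point fixed case, verified term-by-term
  m5 <- matrix(0, 5, 5)
  m5[1, 2] <- 0.1; m5[1, 3] <- 0.9; m5[1, 4] <- 0.8; m5[1, 5] <- 0.7
  m5[2, 3] <- 0.85; m5[2, 4] <- 0.75; m5[2, 5] <- 0.95
  m5[3, 4] <- 0.2; m5[3, 5] <- 0.25
  m5[4, 5] <- 0.15
  m5 <- m5 + t(m5)
  lab <- c(1, 1, 2, 2, 2)
  s1 <- (mean(c(0.9, 0.8, 0.7)) - 0.1) / mean(c(0.9, 0.8, 0.7))
  s2 <- (mean(c(0.85, 0.75, 0.95)) - 0.1) / mean(c(0.85, 0.75, 0.95))
  s3 <- (mean(c(0.9, 0.85)) - mean(c(0.2, 0.25))) / mean(c(0.9, 0.85))
  s4 <- (mean(c(0.8, 0.75)) - mean(c(0.2, 0.15))) / mean(c(0.8, 0.75))
  s5 <- (mean(c(0.7, 0.95)) - mean(c(0.25, 0.15))) / mean(c(0.7, 0.95))
  expect_equal(average_silhouette(m5, lab), mean(c(s1, s2, s3, s4, s5)))

  # independent implementation agreement on random instances
  set.seed(34)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    m <- random_dissim(n)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ref <- mean(cluster::silhouette(lab, dmatrix = m)[, "sil_width"])
    got <- average_silhouette(m, lab)
    expect_equal(got, ref)
    expect_true(got >= -1 && got <= 1)
  }

  expect_error(average_silhouette(z, rep(1, 4)), "single group")
})

test_that("group-number selection applies parsimony, fallback and tie rules", {
  sel1 <- apply_selection_rule(c("2" = 0.81, "3" = 0.62, "4" = 0.55))
  expect_equal(sel1$chosen_k, 2L)
  expect_equal(sel1$rule_applied, "parsimonious_above_benchmark")

  sel2 <- apply_selection_rule(c("2" = 0.30, "3" = 0.39))
  expect_equal(sel2$chosen_k, 3L)
  expect_equal(sel2$rule_applied, "max_asw")

  sel3 <- apply_selection_rule(c("2" = 0.6, "3" = 0.6))
  expect_equal(sel3$chosen_k, 2L)

  # boundary: exactly 0.5 meets the benchmark
  expect_equal(apply_selection_rule(c("2" = 0.4, "3" = 0.5))$chosen_k, 3L)

  # raising the benchmark never lowers the chosen k under parsimony
  set.seed(35)
  for (i in 1:30) {
    asw <- setNames(runif(5, 0, 1), 2:6)
    k_low <- apply_selection_rule(asw, benchmark = 0.3)
    k_high <- apply_selection_rule(asw, benchmark = 0.7)
    if (k_low$rule_applied == "parsimonious_above_benchmark" &&
        k_high$rule_applied == "parsimonious_above_benchmark")
      expect_true(k_high$chosen_k >= k_low$chosen_k)
  }
})

test_that("select_group_number recovers planted structure end to end", {
  set.seed(36)
  # two tight groups far apart
  m <- matrix(1, 6, 6); diag(m) <- 0
  within <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  for (r in seq_len(nrow(within))) {
    m[within[r, 1], within[r, 2]] <- 0.05
    m[within[r, 2], within[r, 1]] <- 0.05
  }
  sel <- select_group_number(m)
  expect_equal(sel$chosen_k, 2L)
  expect_true(sel$asw_by_k[["2"]] > 0.5)
  expect_error(select_group_number(m[1:2, 1:2]), "at least 3")
})
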