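# Ward agglomerative clustering on precomputed dissimilarities and
# silhouette-based selection of the starting number of behavioral groups.

check_dissim <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stopf("dissimilarity matrix must be square")
  if (any(m < 0)) stopf("dissimilarity matrix has negative entries")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stopf("dissimilarity matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stopf("dissimilarity matrix diagonal must be zero")
  m
}

#' Ward agglomerative hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative merging under the Ward criterion via the Lance–Williams
#' recurrence on squared dissimilarities (`stats::hclust`, method
#' `"ward.D2"` — the classical AGNES "ward" behavior); merge heights are
#' monotone non-decreasing.  Deterministic given the matrix.
#'
#' @param d Symmetric non-negative dissimilarity matrix (or `dist`).
#' @return An `hclust` merge tree.
#' @export
ward_tree <- function(d) {
  m <- check_dissim(d)
  if (nrow(m) < 2L) stopf("need at least two items to cluster")
  hclust(as.dist(m), method = "ward.D2")
}

#' Cut a merge tree into k groups
#'
#' @param tree An `hclust` tree (from [ward_tree()]).
#' @param k Number of groups, `1 <= k <= n`.
#' @return Integer vector of group labels named by item.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stopf("k must be in [1, %d]", n)
  cutree(tree, k = k)
}

#' Average silhouette width of a partition
#'
#' For each item, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the
#' mean dissimilarity to the item's own group and `b(i)` the smallest mean
#' dissimilarity to any other group; singletons take `s(i) = 0`, as does the
#' degenerate `0/0` case.  Returns the mean over items (in `[-1, 1]`).
#'
#' @param d Dissimilarity matrix.
#' @param labels Group labels, one per item, at least two distinct values.
#' @return Numeric scalar.
#' @export
average_silhouette <- function(d, labels) {
  m <- check_dissim(d)
  labels <- as.vector(labels)
  if (length(labels) != nrow(m)) stopf("labels length must match matrix size")
  groups <- unique(labels)
  if (length(groups) < 2L) stopf("silhouette undefined for a single group")
  s <- vapply(seq_len(nrow(m)), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)
    a <- mean(m[i, setdiff(own, i)])
    b <- min(vapply(setdiff(groups, labels[i]), function(g)
      mean(m[i, labels == g]), 0))
    if (a == 0 && b == 0) return(0)
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Select the starting number of behavioral groups
#'
#' Computes the average silhouette width (ASW) of the Ward partition at each
#' `k = 2..min(kmax, n-1)` and applies the selection rule: if any partition
#' reaches the benchmark (ASW >= 0.5 by default, the level considered
#' biologically relevant), choose the most parsimonious (smallest) such `k`;
#' otherwise fall back to the `k` with the highest ASW (ties favor the
#' smaller `k`).
#'
#' @param d Dissimilarity matrix (n >= 3 items).
#' @param kmax Largest number of groups considered (default 10).
#' @param benchmark ASW benchmark (default 0.5).
#' @param tree Optional precomputed [ward_tree()] for `d`.
#' @return Object of class `group_selection`: list with `asw_by_k` (named
#'   numeric), `chosen_k`, `rule_applied`
#'   (`"parsimonious_above_benchmark"` or `"max_asw"`).
#' @export
select_group_number <- function(d, kmax = 10, benchmark = 0.5, tree = NULL) {
  m <- check_dissim(d)
  n <- nrow(m)
  if (n < 3L) stopf("need at least 3 items to select a group number")
  if (is.null(tree)) tree <- ward_tree(m)
  ks <- 2:min(kmax, n - 1L)
  asw <- vapply(ks, function(k) average_silhouette(m, cut_tree(tree, k)), 0)
  names(asw) <- ks
  selection_from_asw(asw, benchmark)
}

# Selection rule on a precomputed k -> ASW map (exposed for rule testing).
selection_from_asw <- function(asw, benchmark = 0.5) {
  ks <- as.integer(names(asw))
  meets <- asw >= benchmark
  if (any(meets)) {
    chosen <- min(ks[meets])
    rule <- "parsimonious_above_benchmark"
  } else {
    chosen <- ks[which.max(asw)]  # which.max takes the first, i.e. smallest k
    rule <- "max_asw"
  }
  structure(
    list(asw_by_k = asw, chosen_k = chosen, rule_applied = rule,
         benchmark = benchmark),
    class = "group_selection"
  )
}

#' Apply the group-number selection rule to a precomputed ASW map
#'
#' @param asw Named numeric vector mapping `k` to ASW.
#' @param benchmark ASW benchmark (default 0.5).
#' @return A `group_selection` object (see [select_group_number()]).
#' @export
apply_selection_rule <- function(asw, benchmark = 0.5) {
  if (is.null(names(asw))) stopf("asw must be named by k")
  selection_from_asw(asw, benchmark)
}

#' @export
print.group_selection <- function(x, ...) {
  cat(sprintf("<group_selection> chosen k = %d (%s, benchmark %.2f)\n",
              x$chosen_k, x$rule_applied, x$benchmark))
  print(round(x$asw_by_k, 3))
  invisible(x)
}
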