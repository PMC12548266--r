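# Normalized optimal-matching distances between daily state sequences.

# Map a daily_seq's states onto cost-model state indices (VOID stripped).
seq_state_index <- function(x, cost) {
  y <- strip_void(x)
  if (length(y$states) == 0L)
    stopf("fish %s: empty sequence after VOID stripping", x$fish_id)
  idx <- match(y$states, cost$states)
  if (anyNA(idx))
    stopf("fish %s: states outside the cost-model alphabet: %s", x$fish_id,
          paste(unique(y$states[is.na(idx)]), collapse = ", "))
  idx
}

#' Optimal-matching distance between two sequences
#'
#' Computes the minimum total cost of transforming one daily state sequence
#' into the other via substitutions (geographic cost model) and indels
#' (constant cost), by the full dynamic-programming edit-distance recurrence.
#' VOID suffixes are stripped before computation; MISSING states participate
#' with the cost model's missing cost.  The normalized distance divides the
#' raw distance by the longer sequence's length, so dissimilarity does not
#' depend solely on length differences.
#'
#' @param a,b [daily_seq()] objects over the same alphabet.
#' @param cost A [build_cost_matrix()] cost model.
#' @return Named numeric vector `c(raw = , normalized = )`.
#' @examples
#' cm <- build_cost_matrix(c("L", "R"), rbind(c("L", "R")))
#' s1 <- daily_seq("a", "2020-01-01", c("L", "L", "R"), "habitat", c("L", "R"))
#' s2 <- daily_seq("b", "2020-01-01", c("L", "R", "R"), "habitat", c("L", "R"))
#' om_distance(s1, s2, cm)  # raw 1 (one adjacent substitution), normalized 1/3
#' @export
om_distance <- function(a, b, cost) {
  stopifnot(inherits(a, "daily_seq"), inherits(b, "daily_seq"),
            inherits(cost, "cost_model"))
  if (!identical(a$alphabet, b$alphabet))
    stopf("sequences have different alphabets")
  ia <- seq_state_index(a, cost)
  ib <- seq_state_index(b, cost)
  raw <- om_raw_c(ia, ib, cost$substitution, cost$indel)
  c(raw = raw, normalized = raw / max(length(ia), length(ib)))
}

#' Pairwise normalized dissimilarity matrix
#'
#' Normalized optimal-matching distances for all pairs of sequences.
#'
#' @param sequences Named list of [daily_seq()] objects sharing one alphabet.
#' @param cost A [build_cost_matrix()] cost model.
#' @return Symmetric numeric matrix with zero diagonal, fish ids as
#'   dimnames; values in `[0, 2]`.
#' @export
dissimilarity_matrix <- function(sequences, cost) {
  stopifnot(inherits(cost, "cost_model"))
  if (length(sequences) < 2L) stopf("need at least two sequences")
  alph <- sequences[[1]]$alphabet
  ok <- vapply(sequences, function(s) identical(s$alphabet, alph), TRUE)
  if (!all(ok)) stopf("sequences have mismatched alphabets")
  idx <- lapply(sequences, seq_state_index, cost = cost)
  m <- om_pairwise_c(idx, cost$substitution, cost$indel, TRUE)
  ids <- names(sequences)
  if (is.null(ids)) ids <- vapply(sequences, function(s) s$fish_id, "")
  dimnames(m) <- list(ids, ids)
  m
}
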