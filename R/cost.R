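# Geographic substitution-cost model for optimal matching.

#' Build the substitution-cost model for optimal matching
#'
#' Substitution costs reflect geographic distance between states: 0 for the
#' same habitat/region, 1 for adjacent ones (sharing a confluence), 2 for
#' non-adjacent ones.  Left-missing days (`MISSING`) cost 2 against any
#' observed state — pinning sequences that start late to their true calendar
#' position instead of letting them shift left — and 0 against another
#' `MISSING`.  The constant indel cost of 1 is half the maximum substitution
#' cost, so an insertion or deletion is never cheaper than a substitution.
#'
#' @param alphabet Ordered character vector of observable state labels.
#' @param adjacency Either a two-column character matrix of undirected edges
#'   over `alphabet`, or a square logical/numeric matrix with `alphabet`
#'   dimnames (must be symmetric).
#' @param missing_cost Cost of substituting `MISSING` with an observed state
#'   (default 2).
#' @param indel Insertion/deletion cost (default 1).
#' @return An object of class `cost_model`: list with `alphabet`, `states`
#'   (alphabet plus `MISSING`), `substitution` (symmetric matrix, zero
#'   diagonal), `indel`.
#' @examples
#' cm <- build_cost_matrix(c("lake", "river"), rbind(c("lake", "river")))
#' cm$substitution["lake", "river"]  # 1: adjacent
#' @export
build_cost_matrix <- function(alphabet, adjacency, missing_cost = 2, indel = 1) {
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet)) stopf("alphabet labels must be unique")
  if (.MISSING %in% alphabet || .VOID %in% alphabet)
    stopf("MISSING/VOID are reserved labels")
  k <- length(alphabet)
  adj <- matrix(FALSE, k, k, dimnames = list(alphabet, alphabet))
  if (is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency) &&
      !is.null(dimnames(adjacency)) && all(rownames(adjacency) %in% alphabet) &&
      nrow(adjacency) == k) {
    m <- adjacency[alphabet, alphabet] != 0
    if (!isTRUE(all.equal(m, t(m)))) stopf("adjacency matrix must be symmetric")
    adj <- m
  } else if (is.matrix(adjacency) && ncol(adjacency) == 2L) {
    unknown <- setdiff(unique(as.character(adjacency)), alphabet)
    if (length(unknown))
      stopf("adjacency references labels not in alphabet: %s",
            paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(adjacency))) {
      a <- adjacency[i, 1]; b <- adjacency[i, 2]
      adj[a, b] <- TRUE; adj[b, a] <- TRUE
    }
  } else if (length(adjacency) == 0L) {
    # no adjacency: all distinct pairs cost 2
  } else {
    stopf("adjacency must be an edge list (2 columns) or a square named matrix")
  }
  diag(adj) <- FALSE

  states <- c(alphabet, .MISSING)
  sub <- matrix(2, k + 1L, k + 1L, dimnames = list(states, states))
  sub[seq_len(k), seq_len(k)][adj] <- 1
  diag(sub) <- 0
  sub[.MISSING, alphabet] <- missing_cost
  sub[alphabet, .MISSING] <- missing_cost
  sub[.MISSING, .MISSING] <- 0

  structure(
    list(alphabet = alphabet, states = states, substitution = sub,
         indel = indel),
    class = "cost_model"
  )
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("<cost_model> %d states (+MISSING), indel = %g\n",
              length(x$alphabet), x$indel))
  print(x$substitution)
  invisible(x)
}
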