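# Independent oracles and small constructors shared across the test suite.

# Brute-force optimal-matching distance: naive recursion with memoization,
# written directly from the edit-distance definition and independent of the
# package's dynamic-programming backend.
om_oracle <- function(a, b, sub, indel) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n + 1L, m + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L && j == 0L) 0
    else if (i == 0L) j * indel
    else if (j == 0L) i * indel
    else min(rec(i - 1L, j - 1L) + sub[a[i], b[j]],
             rec(i - 1L, j) + indel,
             rec(i, j - 1L) + indel)
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(n, m)
}

# Random cost model over a small alphabet with random adjacency.
random_cost_model <- function(k) {
  alphabet <- LETTERS[seq_len(k)]
  pairs <- t(combn(alphabet, 2))
  edges <- pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE]
  build_cost_matrix(alphabet, edges)
}

# Random state-index sequence over the model's states, with optional
# leading-MISSING injection (MISSING is the last state index).
random_state_seq <- function(cost, max_len = 12, p_missing = 0.3) {
  len <- sample(1:max_len, 1)
  idx <- sample(length(cost$alphabet), len, replace = TRUE)
  if (runif(1) < p_missing) {
    k <- sample(seq_len(max(1, len - 1)), 1)
    idx[seq_len(k)] <- length(cost$states)  # MISSING prefix
  }
  idx
}

make_seq <- function(states, alphabet, fish_id = "x", start = "2020-01-01") {
  daily_seq(fish_id, start, states, "habitat", alphabet)
}

# Do two label vectors describe the same partition?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Compact detection-table constructor: one row per (fish, time, receiver).
det <- function(fish_id, timestamp, receiver_id) {
  data.frame(fish_id = fish_id,
             timestamp = as.POSIXct(timestamp, tz = "UTC"),
             receiver_id = receiver_id, stringsAsFactors = FALSE)
}

two_region_stations <- function() {
  make_network(list(LK = list(habitat = "lake", n = 2),
                    RV = list(habitat = "river", n = 2)))
}
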