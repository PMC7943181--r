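# Independent oracles, deliberately written on different code paths than the
# package implementations they check.

# Goodman-Kruskal gamma by explicit enumeration of all C(n,2) pairs.
oracle_gamma <- function(bets, acc) {
  n <- length(bets)
  ns <- 0L; nd <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bets[i] == bets[j] || acc[i] == acc[j]) next
      if ((bets[i] > bets[j]) == (acc[i] > acc[j])) ns <- ns + 1L else nd <- nd + 1L
    }
  }
  if (ns + nd == 0L) NA_real_ else (ns - nd) / (ns + nd)
}

# Brute-force complete-linkage agglomerator: holds explicit member lists and
# scans every cluster pair at every step. Returns the merge-height sequence
# and the partition (as labels) at every k.
oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- vector("list", n)
  partitions[[n]] <- seq_len(n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    heights <- c(heights, best)
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# two partitions describe the same clustering iff relabelling is a bijection
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    length(unique(paste(a, b))) == length(unique(a))
}

# random betting round: mixed tie structure, occasional zeros
random_round <- function(n = 12, bet_max = 10, p_zero = 0.15) {
  bets <- sample(0:bet_max, n, replace = TRUE)
  bets[runif(n) < p_zero] <- 0L
  acc <- rbinom(n, 1, runif(1, 0.1, 0.9))
  list(bets = bets, acc = acc)
}

# random strictly increasing map over the positive bet values, fixing 0
random_increasing_map <- function(bets, bet_max = 10) {
  vals <- sort(unique(bets[bets > 0]))
  if (length(vals) == 0) return(bets)
  new_vals <- sort(sample(seq_len(5 * bet_max), length(vals)))
  out <- bets
  for (i in seq_along(vals)) out[bets == vals[i]] <- new_vals[i]
  out
}

# one-round trial table for a single participant, used by I/O and CLI tests
one_round_trials_df <- function(id, bets, acc) {
  data.frame(participant_id = id, age_group = "other", list_version = "unknown",
             round = 1L, position = seq_along(bets), word = NA_character_,
             bet = bets, recalled = acc, stringsAsFactors = FALSE)
}

TABLE1_A <- list(bets = c(10, 10, 10, 10, 10, 10, 5, 10, 10, 10, 10, 10),
                 acc = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
TABLE1_B <- list(bets = c(10, 10, 3, 3, 3, 1, 1, 1, 1, 2, 1, 1),
                 acc = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
TABLE2_C <- list(bets = c(1, 1, 4, 3, 4, 4, 4, 3, 4, 3, 3),
                 acc = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
TABLE2_D <- list(bets = c(5, 4, 1, 3, 1, 2, 10, 6, 5, 5, 10),
                 acc = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
TABLE3_E <- list(bets = c(4, 4, 4, 4, 4, 2, 2, 2, 2, 2, 2, 2),
                 acc = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
TABLE3_F <- list(bets = c(10, 10, 10, 10, 10, 1, 1, 1, 1, 1, 1, 1),
                 acc = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
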