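# Independent brute-force oracles used to pin expected values.

# Greedy left-to-right peeling of maximal fragment sets with a non-empty
# common intersection; plain loop over a data frame, no package code.
oracle_families <- function(frags) {
  frags <- frags[order(frags$frag_start, frags$frag_stop, frags$clone_id), ]
  fam <- rep(NA_integer_, nrow(frags))
  current <- 0L
  while (anyNA(fam)) {
    current <- current + 1L
    lo <- NA
    hi <- NA
    for (i in seq_len(nrow(frags))) {
      if (!is.na(fam[i])) next
      if (is.na(lo)) {
        lo <- frags$frag_start[i]; hi <- frags$frag_stop[i]
        fam[i] <- current
      } else {
        new_lo <- max(lo, frags$frag_start[i])
        new_hi <- min(hi, frags$frag_stop[i])
        if (new_lo <= new_hi) {
          lo <- new_lo; hi <- new_hi
          fam[i] <- current
        }
      }
    }
  }
  frags$family <- fam
  frags
}

# Exhaustive triple loop: which unordered edges lie on a triangle.
oracle_triangle_edges <- function(a, b) {
  nodes <- sort(unique(c(a, b)))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_along(a)) {
    if (a[i] != b[i]) adj[a[i], b[i]] <- adj[b[i], a[i]] <- TRUE
  }
  flagged <- logical(length(a))
  for (i in seq_along(a)) {
    if (a[i] == b[i]) next
    for (c in nodes) {
      if (c != a[i] && c != b[i] && adj[a[i], c] && adj[b[i], c]) {
        flagged[i] <- TRUE
        break
      }
    }
  }
  flagged
}

# BFS all-pairs distances on an undirected simple graph given as edge lists.
oracle_bfs_distances <- function(nodes, a, b) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  nbr <- vector("list", n)
  for (i in seq_along(a)) {
    if (a[i] == b[i]) next
    u <- idx[[a[i]]]; v <- idx[[b[i]]]
    nbr[[u]] <- union(nbr[[u]], v)
    nbr[[v]] <- union(nbr[[v]], u)
  }
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in nbr[[u]]) {
        if (is.infinite(d[s, v])) {
          d[s, v] <- d[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  d
}

# Two-sided Fisher p by enumeration of all 2x2 tables with the observed
# margins: sum the probabilities of tables no more probable than observed.
oracle_fisher_two_sided <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  support <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, N - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided enrichment tail P(X >= k) by direct summation.
oracle_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

# Small scored-interaction fixture: one row per pair with the given PBS
# labels; pairs are disjoint unless stated.
make_interactions <- function(pbs, prefix = "x") {
  n <- length(pbs)
  tibble::tibble(
    bait_protein = sprintf("%sb%04d", prefix, seq_len(n)),
    prey_protein = sprintf("%sp%04d", prefix, seq_len(n)),
    screens = "S001",
    sid_starts = "1", sid_stops = "100",
    n_sids = 1L, n_clones = 3L, n_distinct_fragments = 3L,
    support_score = 3L, all_singleton = FALSE,
    reciprocal = FALSE, in_cycle = FALSE, promiscuity = 1L,
    pbs = pbs
  )
}

# PLA measurement table for one interaction.
pla_tbl <- function(ppi, prey, compartment = "membrane") {
  tibble::tibble(cell_id = seq_along(ppi), compartment = compartment,
                 ppi_spots = ppi, prey_spots = prey)
}

# Random fragment tables for property tests.
random_fragments <- function(n, max_pos = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(80, n, replace = TRUE)
  tibble::tibble(
    prey_protein = "prey1",
    clone_id = sprintf("c%04d", seq_len(n)),
    frag_start = start,
    frag_stop = start + len
  )
}
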