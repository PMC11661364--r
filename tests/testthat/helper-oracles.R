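# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the slowest, most literal formulation of each
# definition so they share no code path with the package.

# triple-loop box scanner: walk every lattice box and test occupancy
brute_box_count <- function(grid, s) {
  d <- dim(grid)
  n <- 0L
  for (i in seq(1L, d[1], by = s))
    for (j in seq(1L, d[2], by = s))
      for (k in seq(1L, d[3], by = s)) {
        blk <- grid[i:min(i + s - 1L, d[1]),
                    j:min(j + s - 1L, d[2]),
                    k:min(k + s - 1L, d[3])]
        if (any(blk != 0)) n <- n + 1L
      }
  n
}

# literal step-up definition of Benjamini-Hochberg
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    v <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- v
    prev <- v
  }
  pmin(adj, 1)
}

# per-node nearest-neighbour enumeration with repeated min scans
brute_knn_edge <- function(values, i, k) {
  n <- length(values)
  d <- abs(values - values[i])
  cand <- setdiff(seq_len(n), i)
  picked <- integer(0)
  while (length(picked) < k - 1L) {
    best <- NA_integer_
    for (j in cand)
      if (is.na(best) || d[j] < d[best] || (d[j] == d[best] && j < best))
        best <- j
    picked <- c(picked, best)
    cand <- setdiff(cand, best)
  }
  sort(c(i, picked))
}

# AUC by exhaustive concordant-pair counting (ties count 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos)
    for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

random_mask <- function(seed, max_dim = 32L, density = 0.1) {
  set.seed(seed)
  d <- sample(8:max_dim, 3, replace = TRUE)
  array(as.integer(stats::runif(prod(d)) < density), dim = d)
}

clinical_cols <- c("age", "sex", "target_stn", "bilateral",
                   "motor_improvement_pct")
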