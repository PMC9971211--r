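# Independent oracle implementations used to validate package routines.
# These deliberately use the most direct (brute-force) formulation and stay
# free of any package internals.

# Brute-force Benjamini-Hochberg step-up.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(m * ranked[i:m] / (i:m), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive optimal-cutoff sweep: rule "x >= cutoff -> class 1".
# The criterion is compared in exact integer form so ties are deterministic
# (youden ordering is equivalent to #TP * n0 - #FP * n1).
cutoff_sweep_bruteforce <- function(ctl, trt, criterion = "youden") {
  n0 <- length(ctl); n1 <- length(trt)
  cand <- sort(unique(c(ctl, trt)))
  best <- -Inf; best_c <- NA; best_val <- NA
  for (cc in cand) {
    tp <- sum(trt >= cc); fp <- sum(ctl >= cc)
    int_crit <- if (criterion == "youden") tp * n0 - fp * n1
                else tp + (n0 - fp)
    if (int_crit > best) {
      best <- int_crit
      best_c <- cc
      best_val <- if (criterion == "youden") tp / n1 + (n0 - fp) / n0 - 1
                  else (tp + (n0 - fp)) / (n0 + n1)
    }
  }
  list(cutoff = best_c, value = best_val)
}

# All-pairs shortest paths by BFS on an adjacency matrix (unweighted,
# undirected); Inf when unreachable.
apsp_bfs <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] > 0)
        new <- nb[d[s, nb] == Inf]
        d[s, new] <- depth
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# Brute-force centralities from an adjacency matrix, following the same
# conventions the package documents (per-component distances, unnormalized
# pair-counted betweenness, local clustering coefficient, isolated-node
# conventions).
centralities_bruteforce <- function(adj) {
  n <- nrow(adj)
  d <- apsp_bfs(adj)
  deg <- rowSums(adj)
  btw <- numeric(n)
  # count shortest paths through each interior node, per unordered pair
  npaths <- function(s, t) {
    if (d[s, t] == Inf) return(0)
    if (d[s, t] == 0) return(1)
    sum(vapply(which(adj[s, ] > 0 & d[, t] == d[s, t] - 1),
               function(v) npaths(v, t), numeric(1)))
  }
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || d[s, t] == Inf) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + npaths(s, v) * npaths(v, t) / npaths(s, t)
      }
    }
    btw[v] <- tot
  }
  clo <- asp <- ecc <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0) next
    clo[v] <- length(reach) / sum(d[v, reach])
    asp[v] <- sum(d[v, reach]) / length(reach)
    ecc[v] <- max(d[v, reach])
  }
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) { cc[v] <- 0; next }
    links <- sum(adj[nb, nb]) / 2
    cc[v] <- links / (length(nb) * (length(nb) - 1) / 2)
  }
  data.frame(betweenness = btw, closeness = clo,
             avg_shortest_path_length = asp, clustering_coefficient = cc,
             degree = deg, eccentricity = ecc)
}

# Direct hypergeometric tail sum P(X >= k), X ~ Hypergeom(K white, N-K
# black, n drawn).
hyper_tail_bruteforce <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
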