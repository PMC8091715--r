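# Independent brute-force oracles, deliberately naive: each recomputes a
# statistic from its definition with explicit loops, without reusing any
# package internals.

# betaMNTD by double loop over taxa of each sample pair
oracle_bmntd <- function(counts, dmat) {
  n <- nrow(counts)
  out <- matrix(0, n, n)
  for (k in seq_len(n)) for (l in seq_len(n)) {
    ik <- which(counts[k, ] > 0)
    il <- which(counts[l, ] > 0)
    fk <- counts[k, ik] / sum(counts[k, ik])
    fl <- counts[l, il] / sum(counts[l, il])
    term1 <- sum(vapply(seq_along(ik), function(a)
      fk[a] * min(dmat[ik[a], il]), numeric(1)))
    term2 <- sum(vapply(seq_along(il), function(b)
      fl[b] * min(dmat[il[b], ik]), numeric(1)))
    out[k, l] <- 0.5 * (term1 + term2)
  }
  out
}

# shortest-path distance matrix by Floyd-Warshall on an adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (via in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, via] + d[via, j] < d[i, j]) d[i, j] <- d[i, via] + d[via, j]
  d
}

# betweenness by explicit enumeration of all shortest paths (small n only)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  # count shortest paths s->t via dynamic programming on distance layers
  nsp <- matrix(0, n, n)
  diag(nsp) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
      nsp[s, t] <- sum(nsp[s, preds])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || s == v || t == v) next
    if (!is.finite(d[s, t])) next
    if (d[s, v] + d[v, t] == d[s, t])
      btw[v] <- btw[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
  }
  btw / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  vapply(seq_len(nrow(adj)), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(ncol(d)) != v)
    if (!length(reach)) return(NaN)
    length(reach) / sum(d[v, reach])
  }, numeric(1))
}

oracle_eigenvector <- function(adj, iter = 5000) {
  x <- rep(1, nrow(adj))
  for (i in seq_len(iter)) {
    x_new <- adj %*% x
    x <- as.numeric(x_new) / sqrt(sum(x_new^2))
  }
  x / max(x)
}

oracle_natural_connectivity <- function(adj) {
  lam <- eigen(adj)$values
  log(mean(exp(lam)))
}

oracle_levins <- function(counts) {
  vapply(seq_len(ncol(counts)), function(j) {
    P <- counts[, j] / sum(counts[, j])
    1 / sum(P^2)
  }, numeric(1))
}

# undirected G from an edge list on 1..n, as adjacency matrix
adj_from_igraph <- function(g) {
  igraph::as_adjacency_matrix(g, sparse = FALSE)
}

# small random rarefied community fixture
random_table <- function(n_samples, n_otus, depth = 200, seed = 1) {
  set.seed(seed)
  counts <- t(stats::rmultinom(n_samples, depth,
                               prob = stats::runif(n_otus)^2 + 0.01))
  dimnames(counts) <- list(paste0("S", seq_len(n_samples)),
                           paste0("OTU_", seq_len(n_otus)))
  otu_table(counts)
}
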