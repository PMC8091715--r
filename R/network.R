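## Co-occurrence network construction (Spearman + FDR), topology,
## module/keystone analysis, Erdos-Renyi baselines and natural-connectivity
## robustness.

#' Filter an OTU table for network construction
#'
#' Removes OTUs occurring in fewer than `min_occupancy` of the analysis
#' samples, then keeps the `top_n` most abundant survivors (total count;
#' ties at the cut broken deterministically by OTU id).
#'
#' @param table an [otu_table()] restricted to the analysis sample set
#'   (overall or one zone).
#' @param min_occupancy minimum fraction of samples an OTU must occur in
#'   (default 0.5).
#' @param top_n maximum number of OTUs retained (default 300).
#' @return filtered [otu_table()]; error if fewer than 4 OTUs survive.
#' @export
filter_for_network <- function(table, min_occupancy = 0.5, top_n = 300) {
  m <- unclass(table)
  occ <- colMeans(m > 0)
  m <- m[, occ >= min_occupancy, drop = FALSE]
  if (ncol(m) < 4)
    stop("fewer than 4 OTUs pass the occupancy filter; no meaningful network")
  ord <- order(-colSums(m), colnames(m))
  m <- m[, sort(ord[seq_len(min(top_n, ncol(m)))]), drop = FALSE]
  otu_table(m)
}

#' Build a Spearman/FDR co-occurrence network
#'
#' Computes Spearman's rho (midrank ties) between all OTU pairs across
#' samples, two-sided p-values by the t approximation, Benjamini-Hochberg
#' FDR over the full upper triangle, and keeps an edge iff `|rho| >
#' rho_min` and `q < q_max`. The returned graph is undirected and simple;
#' the correlation sign is stored as edge metadata but all topology
#' metrics treat the graph as unweighted and unsigned.
#'
#' Constant OTU vectors (undefined correlation) are dropped with a
#' message.
#'
#' @param table a filtered [otu_table()] with >= 5 samples (see
#'   [filter_for_network()]).
#' @param rho_min correlation magnitude threshold (default 0.6, strict).
#' @param q_max FDR-adjusted p-value threshold (default 0.01, strict).
#' @return an [igraph::igraph] with vertex attributes `name`,
#'   `total_abundance` and edge attributes `rho`, `q`, `sign` ("+"/"-"),
#'   plus graph attributes `rho_min`, `q_max`.
#' @export
build_network <- function(table, rho_min = 0.6, q_max = 0.01) {
  m <- unclass(table)
  if (nrow(m) < 5) stop("need >= 5 samples to estimate correlations")
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    message(sum(constant), " constant OTU(s) dropped (undefined correlation)")
    m <- m[, !constant, drop = FALSE]
  }
  n <- nrow(m)
  rho <- stats::cor(m, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[abs(rho) >= 1] <- 0
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  q <- stats::p.adjust(pval[ut], method = "BH")
  keep <- abs(rho[ut]) > rho_min & q < q_max
  edges <- data.frame(from = colnames(m)[ut[keep, 1]],
                      to = colnames(m)[ut[keep, 2]],
                      rho = rho[ut][keep], q = q[keep],
                      sign = ifelse(rho[ut][keep] > 0, "+", "-"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = colnames(m),
                          total_abundance = colSums(m)))
  g <- igraph::set_graph_attr(g, "rho_min", rho_min)
  igraph::set_graph_attr(g, "q_max", q_max)
}

#' Graph-level topology summary
#'
#' The standard co-occurrence network report: size, links, average degree
#' (2E/N), average local clustering coefficient (nodes of degree < 2
#' count 0), diameter and average path length over connected node pairs,
#' density (2E/(N(N-1))), modularity of the best Louvain partition,
#' power-law degree-distribution fit R^2 (OLS of log10 frequency on log10
#' degree, zero-count bins excluded), and the fraction of positive edges.
#'
#' @param g a graph from [build_network()] (any igraph works; sign-based
#'   fields are NA without edge signs).
#' @param modules optional result of [detect_modules()] (recomputed with
#'   `seed` when missing).
#' @param seed seed for module detection when `modules` is missing.
#' @return data.frame with one row of topology metrics.
#' @export
graph_topology <- function(g, modules = NULL, seed = 1) {
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) stop("empty graph")
  if (is.null(modules)) modules <- detect_modules(g, seed = seed)
  deg <- igraph::degree(g)
  signs <- igraph::edge_attr(g, "sign")
  data.frame(
    n_nodes = n, n_edges = e,
    avg_degree = 2 * e / n,
    avg_clustering = igraph::transitivity(g, type = "localaverage",
                                          isolates = "zero"),
    diameter = igraph::diameter(g, unconnected = TRUE),
    density = igraph::edge_density(g),
    avg_path_length = igraph::mean_distance(g, unconnected = TRUE),
    modularity = modules$Q,
    n_modules = length(unique(modules$membership)),
    powerlaw_r2 = .powerlaw_r2(deg),
    positive_edge_fraction = if (is.null(signs)) NA_real_
                             else mean(signs == "+"))
}

.powerlaw_r2 <- function(deg) {
  deg <- deg[deg >= 1]
  tab <- table(deg)
  if (length(tab) < 3) return(NA_real_)
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  summary(stats::lm(y ~ x))$r.squared
}

#' Node-level centralities
#'
#' Degree, betweenness (normalized by (N-1)(N-2)/2), closeness (per
#' component: reachable nodes minus one over summed distances) and
#' eigenvector centrality (principal adjacency eigenvector scaled to
#' maximum 1) for every node.
#'
#' @param g an igraph.
#' @return data.frame with columns otu_id, degree, betweenness,
#'   closeness, eigenvector.
#' @export
node_topology <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  data.frame(
    otu_id = igraph::V(g)$name,
    degree = unname(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, normalized = TRUE)),
    closeness = unname(suppressWarnings(
      igraph::closeness(g, normalized = TRUE))),  # per component by design
    eigenvector = unname(igraph::eigen_centrality(g)$vector),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect network modules (Louvain)
#'
#' Louvain modularity maximization, run `n_runs` times from different
#' seeds keeping the highest-Q partition (the heuristic is stochastic).
#' Q > 0.4 is conventionally read as a modular network.
#'
#' @param g an igraph.
#' @param seed master seed; run r uses `seed + r - 1`.
#' @param resolution Louvain resolution parameter (default 1).
#' @param n_runs restarts (default 10).
#' @return list with `membership` (named integer vector) and `Q`.
#' @export
detect_modules <- function(g, seed = 1, resolution = 1, n_runs = 10) {
  best <- NULL
  for (r in seq_len(n_runs)) {
    set.seed(seed + r - 1)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    q <- igraph::modularity(cl)
    if (is.null(best) || q > best$Q)
      best <- list(membership = igraph::membership(cl), Q = q)
  }
  best
}

#' Zi-Pi classification of node roles
#'
#' Within-module degree z-score `Zi = (k_within - mean_within) /
#' sd_within` (mean and SD over the node's module; modules with zero SD
#' give their members Zi = 0, logged) and among-module participation
#' coefficient `Pi = 1 - sum_s (k_is / k_i)^2`. Roles: network hubs
#' (Zi > 2.5, Pi > 0.62), module hubs (Zi > 2.5, Pi <= 0.62), connectors
#' (Zi <= 2.5, Pi > 0.62), peripherals (the rest). Hubs and connectors
#' are flagged keystone taxa.
#'
#' @param g an igraph.
#' @param modules result of [detect_modules()].
#' @param zi_cut,pi_cut role thresholds (defaults 2.5 and 0.62).
#' @return data.frame with columns otu_id, module, degree, zi, pi, role,
#'   keystone.
#' @export
zipi_classify <- function(g, modules, zi_cut = 2.5, pi_cut = 0.62) {
  memb <- modules$membership
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(adj)
  mods <- sort(unique(memb))
  # k_is: links from node i into module s
  k_is <- vapply(mods, function(s) rowSums(adj[, memb == s, drop = FALSE]),
                 numeric(length(deg)))
  k_within <- k_is[cbind(seq_along(deg), match(memb, mods))]
  zi <- numeric(length(deg))
  n_flat <- 0
  for (s in mods) {
    idx <- memb == s
    mu <- mean(k_within[idx])
    sdv <- stats::sd(k_within[idx])
    if (is.na(sdv) || sdv == 0) {
      zi[idx] <- 0
      n_flat <- n_flat + 1
    } else zi[idx] <- (k_within[idx] - mu) / sdv
  }
  if (n_flat > 0)
    message(n_flat, " module(s) with zero within-degree variance; Zi set to 0")
  pi <- ifelse(deg == 0, 0, 1 - rowSums((k_is / pmax(deg, 1))^2))
  role <- ifelse(zi > zi_cut & pi > pi_cut, "network_hub",
          ifelse(zi > zi_cut, "module_hub",
          ifelse(pi > pi_cut, "connector", "peripheral")))
  data.frame(otu_id = igraph::V(g)$name, module = as.integer(memb),
             degree = unname(deg), zi = unname(zi), pi = unname(pi),
             role = role, keystone = role != "peripheral",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Erdos-Renyi random-network baseline ensemble
#'
#' Generates `reps` uniform G(n, m) graphs with the same node and edge
#' counts as a reference network and summarizes the null distribution of
#' average local clustering, average path length (over connected pairs)
#' and Louvain modularity — the comparison used to show an empirical
#' network is non-random.
#'
#' @param n_nodes,n_edges size of every random graph.
#' @param reps ensemble size (default 1000).
#' @param seed master seed; replicate r uses `seed + r - 1`.
#' @param metrics subset of c("clustering", "path_length", "modularity").
#' @return data.frame with columns metric, mean, sd, reps.
#' @export
random_ensemble <- function(n_nodes, n_edges, reps = 1000, seed = 1,
                            metrics = c("clustering", "path_length",
                                        "modularity")) {
  stopifnot(n_edges <= n_nodes * (n_nodes - 1) / 2)
  metrics <- match.arg(metrics, several.ok = TRUE)
  vals <- matrix(NA_real_, reps, length(metrics),
                 dimnames = list(NULL, metrics))
  for (r in seq_len(reps)) {
    set.seed(seed + r - 1)
    g <- igraph::sample_gnm(n_nodes, n_edges)
    if ("clustering" %in% metrics)
      vals[r, "clustering"] <- igraph::transitivity(g, type = "localaverage",
                                                    isolates = "zero")
    if ("path_length" %in% metrics)
      vals[r, "path_length"] <- igraph::mean_distance(g, unconnected = TRUE)
    if ("modularity" %in% metrics)
      vals[r, "modularity"] <- igraph::modularity(igraph::cluster_louvain(g))
  }
  data.frame(metric = metrics,
             mean = apply(vals, 2, mean),
             sd = apply(vals, 2, stats::sd),
             reps = reps, row.names = NULL, stringsAsFactors = FALSE)
}

#' Natural connectivity
#'
#' `ln((1/N) sum_i exp(lambda_i))` over the eigenvalues of the unweighted,
#' unsigned adjacency matrix — the log average closed-walk weight, a
#' smooth measure of structural robustness. Computed stably by shifting
#' by the largest eigenvalue. An edgeless graph scores 0.
#'
#' @param g an igraph with >= 1 node.
#' @return non-negative scalar.
#' @export
natural_connectivity <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) stop("empty node set")
  if (igraph::ecount(g) == 0) return(0)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj[adj != 0] <- 1
  lam <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(lam)
  lmax + log(mean(exp(lam - lmax)))
}

#' Robustness curve under node removal
#'
#' Removes a growing fraction of nodes — uniformly at random per
#' replicate, or once by descending degree — and tracks the natural
#' connectivity of the induced subgraph. The faster the curve falls, the
#' less robust the network.
#'
#' @param g an igraph.
#' @param strategy "random" (default) or "degree_desc" (targeted attack;
#'   a single deterministic curve, SD 0).
#' @param step removal-fraction increment (default 0.05).
#' @param max_frac maximum removal fraction (default 0.8).
#' @param reps random-removal replicates (default 100).
#' @param seed integer seed.
#' @return data.frame with columns removal_fraction, nc_mean, nc_sd,
#'   strategy.
#' @export
robustness_curve <- function(g, strategy = c("random", "degree_desc"),
                             step = 0.05, max_frac = 0.8, reps = 100,
                             seed = NULL) {
  strategy <- match.arg(strategy)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  fracs <- seq(0, max_frac, by = step)
  n_remove <- pmin(round(fracs * n), n - 1)
  if (!is.null(seed)) set.seed(seed)
  orders <- if (strategy == "degree_desc") {
    list(order(-igraph::degree(g), igraph::V(g)$name))
  } else {
    lapply(seq_len(reps), function(r) sample.int(n))
  }
  nc <- vapply(orders, function(ord)
    vapply(n_remove, function(k) {
      natural_connectivity(igraph::delete_vertices(g, ord[seq_len(k)]))
    }, numeric(1)), numeric(length(fracs)))
  nc <- matrix(nc, nrow = length(fracs))
  data.frame(removal_fraction = fracs,
             nc_mean = rowMeans(nc),
             nc_sd = if (ncol(nc) > 1) apply(nc, 1, stats::sd) else 0,
             strategy = strategy, row.names = NULL,
             stringsAsFactors = FALSE)
}
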