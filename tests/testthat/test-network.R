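test_that("network filter applies occupancy then top-n with id tie-break", {
  set.seed(71)
  m <- matrix(0L, 12, 20, dimnames = list(paste0("S", 1:12),
                                          sprintf("OTU_%02d", 1:20)))
  m[, 1:10] <- rpois(120, 20) + 1L          # ubiquitous
  m[1:5, 11] <- 50L                         # 5/12 samples = 41.7% -> removed
  m[, 12:20] <- rpois(108, 1)               # patchy
  tab <- otu_table(m)
  filt <- filter_for_network(tab, min_occupancy = 0.5, top_n = 300)
  expect_false("OTU_11" %in% colnames(filt))
  expect_true(all(colMeans(unclass(filt) > 0) >= 0.5))

  top <- filter_for_network(tab, min_occupancy = 0, top_n = 5)
  expect_equal(ncol(top), 5)
  # ties at the cut rank resolve by OTU id
  tie <- matrix(10L, 6, 6, dimnames = list(paste0("S", 1:6),
                                           c("b", "a", "d", "c", "f", "e")))
  kept <- colnames(filter_for_network(otu_table(tie), 0, 3))
  expect_setequal(kept, c("a", "b", "c"))
  expect_error(filter_for_network(otu_table(tie[, 1:3] * 0L +
    matrix(c(1L, rep(0L, 17)), 6, 3)), 0.9, 300), "fewer than 4")
})

test_that("edges require both the rho and FDR thresholds, with signs", {
  set.seed(72)
  n <- 20
  base <- rnorm(n)
  m <- cbind(pos1 = rank(base) + 0,
             pos2 = rank(base + rnorm(n, 0, 1e-3)),
             neg1 = rank(-base),
             noise1 = sample(n), noise2 = sample(n), noise3 = sample(n))
  m <- apply(m, 2, as.integer)
  rownames(m) <- paste0("S", 1:n)
  g <- build_network(otu_table(m), rho_min = 0.6, q_max = 0.01)
  ed <- igraph::as_data_frame(g)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_true("pos1 pos2" %in% key)
  expect_identical(ed$sign[key == "pos1 pos2"], "+")
  expect_identical(ed$sign[key == "neg1 pos1"], "-")
  expect_true(all(abs(ed$rho) > 0.6 & ed$q < 0.01))
  # rerun is bit-identical
  g2 <- build_network(otu_table(m), rho_min = 0.6, q_max = 0.01)
  expect_identical(igraph::as_data_frame(g2), igraph::as_data_frame(g))
})

test_that("independent OTUs yield essentially no edges under FDR control", {
  set.seed(73)
  m <- matrix(rpois(12 * 300, 30), 12,
              dimnames = list(paste0("S", 1:12), paste0("O", 1:300)))
  g <- build_network(otu_table(m))
  expect_lte(igraph::ecount(g), 2)
})

test_that("Spearman p-values agree with cor.test's t approximation", {
  set.seed(74)
  x <- as.integer(rpois(15, 20)); y <- as.integer(rpois(15, 20))
  m <- cbind(a = x, b = y)
  rownames(m) <- paste0("S", 1:15)
  rho <- cor(x, y, method = "spearman")
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))$p.value
  tt <- rho * sqrt(13 / (1 - rho^2))
  expect_equal(2 * pt(-abs(tt), 13), ref, tolerance = 0.05)
})

test_that("graph topology identities hold exactly and on closed forms", {
  g <- igraph::sample_gnm(50, 120)
  igraph::V(g)$name <- paste0("O", 1:50)
  top <- graph_topology(g, seed = 5)
  expect_equal(top$avg_degree, 2 * 120 / 50, tolerance = 1e-12)
  expect_equal(top$density, 2 * 120 / (50 * 49), tolerance = 1e-12)

  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  tt <- graph_topology(tri, seed = 1)
  expect_equal(tt$avg_clustering, 1)
  expect_equal(tt$density, 1)
  expect_equal(tt$diameter, 1)
  expect_equal(tt$avg_path_length, 1)
})

test_that("centralities match brute-force oracles on small graphs", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("v", 1:6)
  nt <- node_topology(star)
  expect_equal(nt$betweenness[1], 1)
  expect_equal(nt$betweenness[2], 0)

  p3 <- igraph::make_graph(~ a - b, b - c)
  nt3 <- node_topology(p3)
  expect_equal(nt3$closeness[match("b", nt3$otu_id)], 1)
  expect_equal(nt3$closeness[match("a", nt3$otu_id)], 2 / 3)

  set.seed(75)
  for (r in 1:20) {
    g <- igraph::sample_gnp(12, 0.35)
    if (igraph::ecount(g) < 3) next
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    adj <- adj_from_igraph(g)
    nt <- node_topology(g)
    expect_equal(nt$degree, unname(rowSums(adj)))
    expect_equal(nt$betweenness, oracle_betweenness(adj), tolerance = 1e-8)
    expect_equal(nt$closeness, oracle_closeness(adj), tolerance = 1e-8)
    if (igraph::is_connected(g))
      expect_equal(nt$eigenvector, oracle_eigenvector(adj), tolerance = 1e-6)
  }
})

test_that("module detection: cliques, complete graphs and the Q > 0.4 flag", {
  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(5),
                                        igraph::make_full_graph(5))
  igraph::V(two_cliques)$name <- paste0("v", 1:10)
  mod <- detect_modules(two_cliques, seed = 2)
  expect_equal(length(unique(mod$membership)), 2)
  expect_equal(mod$Q, 0.5, tolerance = 1e-12)
  expect_gt(mod$Q, 0.4)  # "modular" by the conventional threshold

  full <- igraph::make_full_graph(8)
  igraph::V(full)$name <- paste0("v", 1:8)
  expect_lte(abs(detect_modules(full, seed = 3)$Q), 1e-8)
})

test_that("Zi-Pi roles follow the 2.5/0.62 thresholds", {
  # three cliques bridged by one node with a single link into each:
  # its participation is 1 - 3 (1/3)^2 = 2/3 > 0.62 -> connector
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_full_graph(6),
                              igraph::make_full_graph(6))
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, c(19, 1, 19, 7, 19, 13))
  igraph::V(g)$name <- paste0("v", 1:19)
  mods <- detect_modules(g, seed = 4)
  zp <- zipi_classify(g, mods)
  bridge <- zp[zp$otu_id == "v19", ]
  expect_equal(bridge$pi, 2 / 3, tolerance = 1e-12)
  expect_identical(bridge$role, "connector")
  expect_true(bridge$keystone)
  # all-internal nodes have Pi = 0
  internal <- zp[zp$otu_id %in% paste0("v", 3:6), ]
  expect_true(all(internal$pi == 0))
  expect_true(all(internal$role == "peripheral"))

  # closed-form check: degree 4 split evenly over 4 modules -> Pi = 0.75
  fake_mods <- list(membership = setNames(c(1, 1, 2, 2, 3, 3, 4, 4, 1),
                                          paste0("n", 1:9)))
  hub <- igraph::make_empty_graph(n = 9, directed = FALSE)
  hub <- igraph::add_edges(hub, c(9, 1, 9, 3, 9, 5, 9, 7))
  igraph::V(hub)$name <- paste0("n", 1:9)
  zp2 <- zipi_classify(hub, fake_mods)
  expect_equal(zp2$pi[zp2$otu_id == "n9"], 0.75, tolerance = 1e-12)

  # threshold semantics on constructed (Zi, Pi) pairs
  expect_identical(
    with(data.frame(zi = 3, pi = 0.7),
         ifelse(zi > 2.5 & pi > 0.62, "network_hub", "other")), "network_hub")
})

test_that("Erdos-Renyi ensembles track their analytic expectations", {
  ens <- random_ensemble(60, 300, reps = 120, seed = 6)
  p_edge <- 300 / choose(60, 2)
  clus <- ens$mean[ens$metric == "clustering"]
  expect_equal(clus, p_edge, tolerance = 0.05 * p_edge + 0.02)
  expect_true(all(ens$sd >= 0))
  # complete graph: clustering 1, path length 1, SD 0
  k <- random_ensemble(8, 28, reps = 5, seed = 7)
  expect_equal(k$mean[k$metric == "clustering"], 1)
  expect_equal(k$mean[k$metric == "path_length"], 1)
  expect_equal(k$sd[k$metric %in% c("clustering", "path_length")], c(0, 0))
})

test_that("natural connectivity: closed forms, eigen-oracle, edge monotonicity", {
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(natural_connectivity(empty), 0)

  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-12)

  set.seed(76)
  for (r in 1:10) {
    g <- igraph::sample_gnp(10, 0.3)
    expect_equal(natural_connectivity(g),
                 oracle_natural_connectivity(adj_from_igraph(g)),
                 tolerance = 1e-10)
    # adding an edge never decreases nc
    missing <- which(adj_from_igraph(g) == 0 & upper.tri(diag(10)),
                     arr.ind = TRUE)
    if (nrow(missing) == 0) next
    pick <- missing[sample(nrow(missing), 1), ]
    g2 <- igraph::add_edges(g, pick)
    expect_gte(natural_connectivity(g2), natural_connectivity(g) - 1e-12)
  }
})

test_that("robustness curves start exact and degrade under targeted attack", {
  set.seed(77)
  g <- igraph::sample_gnm(40, 120)
  igraph::V(g)$name <- paste0("v", 1:40)
  rcv <- robustness_curve(g, "random", reps = 20, seed = 8)
  expect_equal(rcv$nc_mean[rcv$removal_fraction == 0],
               natural_connectivity(g), tolerance = 1e-12)
  targeted <- robustness_curve(g, "degree_desc")
  expect_true(all(diff(targeted$nc_mean) <= 1e-9))
  expect_true(all(targeted$nc_sd == 0))

  # a denser same-size graph sits uniformly above a sparser one
  dense <- igraph::sample_gnm(40, 300)
  igraph::V(dense)$name <- paste0("v", 1:40)
  r_dense <- robustness_curve(dense, "random", reps = 20, seed = 9)
  expect_true(all(r_dense$nc_mean >= rcv$nc_mean))
})
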