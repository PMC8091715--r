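test_that("betaMNTD equals the brute-force oracle on random instances", {
  set.seed(41)
  for (r in 1:20) {
    n_otu <- sample(5:9, 1)
    tree <- ape::rphylo(n_otu, 1, 0)
    tree$tip.label <- paste0("OTU_", seq_len(n_otu))
    counts <- matrix(rpois(3 * n_otu, 3), 3,
                     dimnames = list(paste0("S", 1:3), tree$tip.label))
    counts[1, ] <- counts[1, ] + 1L  # no empty sample
    counts[2, ] <- counts[2, ] + 1L
    if (any(rowSums(counts) == 0)) next
    tab <- otu_table(counts)
    got <- beta_mntd(tab, tree)
    ora <- oracle_bmntd(counts, ape::cophenetic.phylo(tree))
    expect_equal(unname(got), ora, tolerance = 1e-10)
  }
})

test_that("betaMNTD closed forms: identical samples and star trees", {
  tree <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  counts <- rbind(S1 = c(A = 3L, B = 2L, C = 0L, D = 0L),
                  S2 = c(A = 3L, B = 2L, C = 0L, D = 0L),
                  S3 = c(A = 0L, B = 0L, C = 1L, D = 4L))
  bm <- beta_mntd(otu_table(counts), tree)
  expect_equal(bm["S1", "S2"], 0)           # identical composition
  expect_equal(bm["S1", "S3"], 4)           # disjoint on a star: 2 * branch
  expect_equal(unname(diag(bm)), rep(0, 3))
  expect_equal(bm, t(bm))
})

test_that("betaMNTD agrees with picante::comdistnt", {
  skip_if_not_installed("picante")
  tab <- random_table(6, 25, depth = 300, seed = 42)
  tree <- ape::rphylo(25, 1, 0)
  tree$tip.label <- colnames(tab)
  got <- beta_mntd(tab, tree)
  ref <- as.matrix(picante::comdistnt(unclass(tab),
                                      ape::cophenetic.phylo(tree),
                                      abundance.weighted = TRUE))
  expect_equal(unname(got), unname(ref[rownames(tab), rownames(tab)]),
               tolerance = 1e-10)
})

test_that("betaMNTD is invariant under joint OTU/tip relabeling", {
  tab <- random_table(5, 20, seed = 43)
  tree <- ape::rphylo(20, 1, 0)
  tree$tip.label <- colnames(tab)
  base <- beta_mntd(tab, tree)
  perm <- sample(20)
  tab2 <- otu_table(unclass(tab)[, perm])
  expect_equal(beta_mntd(tab2, tree), base, tolerance = 1e-12)
})

test_that("betaNTI recovers selection regimes and stays calibrated when neutral", {
  tt <- simulate_tree_with_traits(100, seed = 44)
  meta <- simulate_metacommunity(100, 2, seed = 45)
  sdt <- sd(tt$traits)

  neutral <- simulate_neutral_local(meta, 1000, m = 0.5, n_samples = 12,
                                    seed = 46)
  bn <- beta_nti(neutral$table, tt$tree, n_null = 199, seed = 47)
  vals <- bn$bnti[upper.tri(bn$bnti)]
  expect_lte(mean(abs(vals) >= 2, na.rm = TRUE), 0.10)
  expect_equal(bn$bnti, t(bn$bnti))

  env2 <- c(rep(-3 * sdt, 6), rep(3 * sdt, 6)) + mean(tt$traits)
  var_sel <- simulate_niche_local(meta, tt$traits, env2, 0.5 * sdt, 1000,
                                  seed = 48)
  bn2 <- beta_nti(var_sel$table, tt$tree, n_null = 199, seed = 49)
  between <- bn2$bnti[1:6, 7:12]
  expect_gt(median(between), 2)

  # homogeneous selection needs membership turnover within a consistent
  # clade: a larger pool, shallow samples and a tight filter at an extreme
  # trait optimum give drift-driven turnover under one shared environment
  tt_big <- simulate_tree_with_traits(300, seed = 144)
  meta_big <- simulate_metacommunity(300, 2, seed = 145)
  sd_big <- sd(tt_big$traits)
  env1 <- rep(unname(quantile(tt_big$traits, 0.85)), 12)
  hom_sel <- simulate_niche_local(meta_big, tt_big$traits, env1,
                                  0.15 * sd_big, 200, seed = 50)
  bn3 <- suppressMessages(
    beta_nti(hom_sel$table, tt_big$tree, n_null = 199, seed = 51))
  expect_lt(median(bn3$bnti[upper.tri(bn3$bnti)], na.rm = TRUE), -2)

  # sample relabeling leaves betaNTI values intact
  perm <- c(3, 1, 2, 4:12)
  tab_perm <- otu_table(unclass(neutral$table)[perm, ])
  bn_perm <- beta_nti(tab_perm, tt$tree, n_null = 199, seed = 47)
  expect_equal(unname(bn_perm$bnti[rownames(neutral$table),
                                   rownames(neutral$table)]),
               unname(bn$bnti), tolerance = 1e-10)
})

test_that("RC_Bray is bounded, symmetric, and extreme for duplicate samples", {
  tab <- random_table(8, 60, depth = 400, seed = 52)
  m <- unclass(tab)
  m[2, ] <- m[1, ]   # make S2 a copy of S1
  tab <- otu_table(m)
  rc <- raup_crick_bray(tab, n_null = 199, seed = 53)
  off <- rc[upper.tri(rc)]
  expect_true(all(off >= -1 & off <= 1))
  expect_equal(rc, t(rc))
  expect_lte(rc["S1", "S2"], -0.95)
})

test_that("the five-process partition follows the bNTI/RC decision rules", {
  b <- matrix(0, 5, 5); diag(b) <- NA
  r <- matrix(0, 5, 5); diag(r) <- NA
  b[1, 2] <- b[2, 1] <- 3                         # variable selection, any RC
  b[1, 5] <- b[5, 1] <- -3; r[1, 5] <- r[5, 1] <- -0.99  # still selection
  b[1, 3] <- b[3, 1] <- 0.5; r[1, 3] <- r[3, 1] <- 0.99  # dispersal limitation
  r[2, 3] <- r[3, 2] <- -0.99                     # homogenizing dispersal
  b[1, 4] <- b[4, 1] <- -1                        # undominated (RC = 0)
  pp <- partition_processes(b, r)
  expect_equal(pp$n_pairs, 10)
  expect_equal(pp$counts[["variable_selection"]], 1)
  expect_equal(pp$counts[["homogeneous_selection"]], 1)  # RC ignored when bNTI < -2
  expect_equal(pp$counts[["dispersal_limitation"]], 1)
  expect_equal(pp$counts[["homogenizing_dispersal"]], 1)
  expect_equal(pp$counts[["undominated"]], 6)
  expect_equal(sum(pp$fractions), 1, tolerance = 1e-12)
  expect_equal(pp$determinism + pp$stochasticity, 1, tolerance = 1e-12)

  # boundary: bNTI exactly +/-2 goes to the stochastic side
  b2 <- matrix(c(NA, 2, -2, 2, NA, 0, -2, 0, NA), 3)
  r2 <- matrix(0, 3, 3); diag(r2) <- NA
  pp2 <- partition_processes(b2, r2)
  expect_equal(pp2$counts[["undominated"]], 3)
  expect_equal(pp2$determinism, 0)
})

test_that("neutral synthetic data is dominated by stochastic processes", {
  meta <- simulate_metacommunity(120, 2, seed = 54)
  tt <- simulate_tree_with_traits(120, seed = 55)
  sim <- simulate_neutral_local(meta, 1000, m = 0.5, n_samples = 12, seed = 56)
  bn <- beta_nti(sim$table, tt$tree, n_null = 199, seed = 57)
  rc <- raup_crick_bray(sim$table, n_null = 199, seed = 58)
  pp <- partition_processes(bn$bnti, rc)
  expect_gt(pp$stochasticity, 0.8)
})
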