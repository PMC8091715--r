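## Null-model partition of community assembly processes:
## betaMNTD / betaNTI (phylogenetic turnover vs a tip-shuffle null) and
## Bray-Curtis Raup-Crick (taxonomic turnover vs a random-assembly null),
## combined into the five-process framework.

# nearest-taxon distance matrix: M[i, l] = min over taxa j present in
# sample l of d[i, j] (self included, so M[i, l] = 0 when i is in l)
.min_dist_to_samples <- function(d, pres_idx) {
  vapply(pres_idx, function(idx)
    do.call(pmin, c(asplit(d[, idx, drop = FALSE], 2), list(na.rm = FALSE))),
    numeric(nrow(d)))
}

# betaMNTD for all sample pairs given weights F (otus x samples, columns
# sum to 1) and presence index list; pure matrix algebra:
# bMNTD(k,l) = 0.5 * (f_k . M[,l] + f_l . M[,k])
.bmntd_from_dist <- function(d, F_w, pres_idx) {
  M <- .min_dist_to_samples(d, pres_idx)
  A <- crossprod(F_w, M)
  0.5 * (A + t(A))
}

#' Between-sample beta mean nearest taxon distance (betaMNTD)
#'
#' For each pair of samples, the abundance-weighted mean of the patristic
#' distance from every taxon in one sample to its phylogenetically nearest
#' taxon in the other, averaged over both directions:
#' `betaMNTD(k,l) = 0.5 * (sum_i f_ik min_j d_ij + sum_j f_jl min_i d_ij)`
#' with `f` the within-sample relative abundances among analysed taxa and
#' `d` the patristic distance. A taxon present in both samples is its own
#' nearest neighbour (distance zero), so identical samples score 0.
#'
#' OTUs absent from the tree are dropped (with a warning) and abundances
#' renormalized over the retained set.
#'
#' @param table an [otu_table()], typically rarefied.
#' @param tree an [ape::phylo] whose tips cover the table's OTUs.
#' @param abundance_weighted weight by relative abundance (default TRUE);
#'   FALSE gives each present taxon equal weight.
#' @return symmetric samples x samples matrix, zero diagonal.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  prep <- .prep_phylo_table(table, tree)
  .bmntd_from_dist(prep$d, prep$F_w, prep$pres)
}

.prep_phylo_table <- function(table, tree, abundance_weighted = TRUE) {
  m <- unclass(table)
  shared <- intersect(colnames(m), tree$tip.label)
  if (length(shared) == 0) stop("no OTUs shared between table and tree")
  dropped <- setdiff(colnames(m), tree$tip.label)
  if (length(dropped))
    warning(length(dropped), " OTUs absent from the tree were dropped")
  m <- m[, shared, drop = FALSE]
  d <- stats::cophenetic(tree)[shared, shared]
  W <- if (abundance_weighted) t(m) else t(m > 0) * 1
  cs <- colSums(W)
  if (any(cs == 0)) stop("sample(s) with no tree-matched taxa: ",
                         paste(rownames(m)[cs == 0], collapse = ", "))
  F_w <- sweep(W, 2, cs, "/")          # otus x samples, columns sum to 1
  pres <- apply(m > 0, 1, which, simplify = FALSE)
  list(d = d, F_w = F_w, pres = pres, sample_ids = rownames(m))
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of [beta_mntd()] against a taxa-shuffle null:
#' each of `n_null` randomizations permutes all tip identities across the
#' phylogeny once (breaking any phylogenetic structure in the communities
#' while preserving composition and tree shape) and recomputes betaMNTD
#' for every pair. `betaNTI = (obs - mean_null) / sd_null`. Values > 2
#' indicate more phylogenetic turnover than expected (variable selection),
#' values < -2 less than expected (homogeneous selection).
#'
#' Pairs whose null SD is zero (e.g. identical samples) are returned as
#' `NA` and counted in a message; they are excluded by
#' [partition_processes()].
#'
#' @inheritParams beta_mntd
#' @param n_null number of randomizations (default 999).
#' @param seed integer seed.
#' @return list with symmetric matrices `bmntd_obs` and `bnti` (NA
#'   diagonal), and `n_null`.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = NULL,
                     abundance_weighted = TRUE) {
  prep <- .prep_phylo_table(table, tree, abundance_weighted)
  obs <- .bmntd_from_dist(prep$d, prep$F_w, prep$pres)
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(prep$d)
  n <- length(prep$sample_ids)
  sum1 <- matrix(0, n, n)
  sum2 <- matrix(0, n, n)
  for (r in seq_len(n_null)) {
    perm <- sample.int(S)
    nb <- .bmntd_from_dist(prep$d[perm, perm], prep$F_w, prep$pres)
    sum1 <- sum1 + nb
    sum2 <- sum2 + nb^2
  }
  mu <- sum1 / n_null
  sdv <- sqrt(pmax(0, sum2 / n_null - mu^2) * n_null / (n_null - 1))
  bnti <- (obs - mu) / sdv
  bnti[sdv == 0] <- NA
  diag(bnti) <- NA
  n_degenerate <- (sum(sdv == 0, na.rm = TRUE) - n) / 2
  if (n_degenerate > 0)
    message(n_degenerate, " sample pair(s) had zero null variance; ",
            "betaNTI set to NA")
  dimnames(obs) <- dimnames(bnti) <- list(prep$sample_ids, prep$sample_ids)
  list(bmntd_obs = obs, bnti = bnti, n_null = n_null)
}

# assemble one null community: draw `rich` species without replacement
# with probability ~ occupancy, then distribute the remaining individuals
# ~ regional relative abundance among the drawn species
.null_assemble <- function(rich, depth, occ_w, ab_w) {
  sp <- sample.int(length(occ_w), rich, prob = occ_w)
  counts <- rep(1L, rich)
  if (depth > rich)
    counts <- counts + stats::rmultinom(1, depth - rich, ab_w[sp])[, 1]
  list(sp = sp, counts = counts)
}

.bray <- function(a, b) {
  shared <- intersect(a$sp, b$sp)
  smin <- sum(pmin(a$counts[match(shared, a$sp)],
                   b$counts[match(shared, b$sp)]))
  1 - 2 * smin / (sum(a$counts) + sum(b$counts))
}

#' Bray-Curtis based Raup-Crick (RC_Bray)
#'
#' For every sample pair, compares the observed Bray-Curtis dissimilarity
#' to a null distribution in which both communities are assembled at
#' random: each null community draws the sample's observed richness of
#' species with probability proportional to occupancy across all samples,
#' then fills to the sample's observed depth with individuals drawn
#' proportional to regional relative abundance. The metric is the null
#' quantile rescaled to \[-1, 1\]:
#' `RC = 2 * ((n_less + 0.5 * n_equal) / n_null - 0.5)`.
#' RC_Bray > 0.95 flags pairs more dissimilar than expected (dispersal
#' limitation, given |betaNTI| < 2), RC_Bray < -0.95 less dissimilar
#' (homogenizing dispersal).
#'
#' @param table a rarefied [otu_table()].
#' @param n_null null replicates per pair (default 999).
#' @param seed integer seed.
#' @return symmetric samples x samples matrix in \[-1, 1\], NA diagonal.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = NULL) {
  m <- unclass(table)
  if (!is.null(seed)) set.seed(seed)
  occ_w <- colSums(m > 0)
  ab_w <- colSums(m)
  keep <- occ_w > 0
  m <- m[, keep, drop = FALSE]
  occ_w <- occ_w[keep]
  ab_w <- ab_w[keep] / sum(ab_w[keep])
  n <- nrow(m)
  rich <- rowSums(m > 0)
  depth <- rowSums(m)
  obs <- as.matrix(vegan::vegdist(m, method = "bray"))
  rc <- matrix(NA_real_, n, n, dimnames = dimnames(obs))
  for (k in seq_len(n - 1)) {
    for (l in seq((k + 1), n)) {
      nulls <- vapply(seq_len(n_null), function(r)
        .bray(.null_assemble(rich[k], depth[k], occ_w, ab_w),
              .null_assemble(rich[l], depth[l], occ_w, ab_w)),
        numeric(1))
      stat <- (sum(nulls < obs[k, l]) + 0.5 * sum(nulls == obs[k, l])) / n_null
      rc[k, l] <- rc[l, k] <- 2 * (stat - 0.5)
    }
  }
  rc
}

#' Five-process partition of community assembly
#'
#' Classifies every pairwise comparison by the two null models:
#' \describe{
#'   \item{variable_selection}{betaNTI > 2}
#'   \item{homogeneous_selection}{betaNTI < -2}
#'   \item{dispersal_limitation}{|betaNTI| < 2 and RC_Bray > 0.95}
#'   \item{homogenizing_dispersal}{|betaNTI| < 2 and RC_Bray < -0.95}
#'   \item{undominated}{|betaNTI| < 2 and |RC_Bray| <= 0.95 — drift, weak
#'     selection, weak dispersal and diversification}
#' }
#' Ties at exactly |betaNTI| = 2 go to the stochastic side. Determinism is
#' the summed selection fractions; stochasticity the remaining three.
#'
#' @param bnti betaNTI matrix (from [beta_nti()]); NA pairs are excluded.
#' @param rc RC_Bray matrix (from [raup_crick_bray()]), aligned with
#'   `bnti`.
#' @param bnti_cut,rc_cut significance bounds (defaults 2 and 0.95).
#' @return object of class `process_partition`: list with `counts`,
#'   `fractions` (both named over the five classes), `n_pairs`,
#'   `determinism`, `stochasticity`.
#' @export
partition_processes <- function(bnti, rc, bnti_cut = 2, rc_cut = 0.95) {
  stopifnot(identical(dim(bnti), dim(rc)))
  ut <- upper.tri(bnti)
  b <- bnti[ut]
  r <- rc[ut]
  ok <- !is.na(b) & !is.na(r)
  b <- b[ok]
  r <- r[ok]
  classes <- c("variable_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal",
               "undominated")
  lab <- ifelse(b > bnti_cut, classes[1],
         ifelse(b < -bnti_cut, classes[2],
         ifelse(r > rc_cut, classes[3],
         ifelse(r < -rc_cut, classes[4], classes[5]))))
  counts <- table(factor(lab, levels = classes))
  fractions <- as.numeric(counts) / sum(counts)
  names(fractions) <- classes
  structure(list(counts = stats::setNames(as.integer(counts), classes),
                 fractions = fractions, n_pairs = length(b),
                 determinism = sum(fractions[1:2]),
                 stochasticity = sum(fractions[3:5])),
            class = "process_partition")
}

#' @export
print.process_partition <- function(x, ...) {
  cat("Assembly-process partition over", x$n_pairs, "pairwise comparisons\n")
  for (cl in names(x$fractions))
    cat(sprintf("  %-24s %5d  (%.1f%%)\n", cl, x$counts[cl],
                100 * x$fractions[cl]))
  cat(sprintf("  determinism %.1f%% / stochasticity %.1f%%\n",
              100 * x$determinism, 100 * x$stochasticity))
  invisible(x)
}
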