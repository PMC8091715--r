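#' Simulate a Yule tree with a Brownian-motion trait
#'
#' Generates a pure-birth (Yule) phylogeny of `n_otus` tips and evolves a
#' continuous trait along it by Brownian motion. Niche selection in
#' [simulate_niche_local()] acts on this trait, so the selective signal is
#' phylogenetically conserved — the prerequisite for phylogenetic-turnover
#' metrics (betaNTI) to detect it.
#'
#' @param n_otus number of tips (>= 3); tips are labeled "OTU_1" ...
#' @param seed integer seed.
#' @param birth Yule speciation rate (default 1; only rescales branch
#'   lengths).
#' @param sigma_bm Brownian-motion rate (trait SD per unit branch length).
#' @return list with `tree` (ape::phylo, rooted, tip labels OTU ids) and
#'   `traits` (named numeric vector over tips).
#' @export
simulate_tree_with_traits <- function(n_otus, seed = NULL, birth = 1, sigma_bm = 1) {
  if (n_otus < 3) stop("n_otus must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_otus, birth = birth, death = 0)
  tree$tip.label <- paste0("OTU_", seq_len(n_otus))
  traits <- ape::rTraitCont(tree, model = "BM", sigma = sigma_bm)
  names(traits) <- tree$tip.label
  list(tree = tree, traits = traits)
}

#' Simulate a log-normal metacommunity
#'
#' Regional relative abundances proportional to exp(Normal(0, sd^2)) — the
#' log-normal species-abundance distribution typical of microbial source
#' pools.
#'
#' @param n_otus number of OTUs (>= 2).
#' @param lognormal_sd SD of log abundance (> 0); larger values give a more
#'   uneven pool.
#' @param seed integer seed.
#' @return named probability vector over "OTU_1" ... (sums to 1).
#' @export
simulate_metacommunity <- function(n_otus, lognormal_sd = 2, seed = NULL) {
  stopifnot(n_otus >= 2, lognormal_sd > 0)
  if (!is.null(seed)) set.seed(seed)
  ab <- exp(stats::rnorm(n_otus, 0, lognormal_sd))
  p <- ab / sum(ab)
  names(p) <- paste0("OTU_", seq_len(n_otus))
  p
}

# One local community under the Moran birth-death process: n_events death
# events; the replacement is an immigrant (prob m, species ~ meta) or a
# local birth (prob 1 - m, parent uniform over living individuals).
# Individuals are tracked explicitly so every per-event draw is a uniform
# index, presampled in bulk.
moran_community <- function(meta, n_individuals, m, n_events) {
  S <- length(meta)
  individuals <- sample.int(S, n_individuals, replace = TRUE, prob = meta)
  immigrant <- stats::runif(n_events) < m
  n_imm <- sum(immigrant)
  imm_pool <- if (n_imm) sample.int(S, n_imm, replace = TRUE, prob = meta) else integer()
  deaths <- sample.int(n_individuals, n_events, replace = TRUE)
  births <- sample.int(n_individuals, n_events, replace = TRUE)
  k <- 0L
  for (e in seq_len(n_events)) {
    if (immigrant[e]) {
      k <- k + 1L
      individuals[deaths[e]] <- imm_pool[k]
    } else {
      individuals[deaths[e]] <- individuals[births[e]]
    }
  }
  tabulate(individuals, nbins = S)
}

#' Simulate neutral local communities (Sloan/Hubbell dynamics)
#'
#' Each sample is an independent local community of `n_individuals`
#' individuals: initialized by a multinomial draw from the metacommunity,
#' then iterated through Moran death events in which the replacement is an
#' immigrant (species drawn from the metacommunity) or otherwise a local
#' birth (parent drawn proportional to current local abundance).
#'
#' `m` is interpreted on one of two scales. With `m_scale = "sloan"` (the
#' default) it is the migration rate of the Sloan neutral model: the
#' per-event immigration probability is set to
#' `m_e = N m / (N - 1 + N m)` so that the chain's exact stationary
#' distribution — beta-binomial with scale `m_e (N - 1) / (1 - m_e)` — has
#' the Beta(N m p, N m (1 - p)) relative-abundance law whose parameter
#' [fit_ncm()] estimates. With `m_scale = "event"`, `m` is the raw
#' per-event immigration probability itself (so `m = 1` makes every
#' replacement an immigrant and each sample converges to a fresh
#' multinomial draw from the metacommunity); the two scales are related by
#' `m_sloan = m_e (N - 1) / (N (1 - m_e))` and agree when m is small.
#'
#' The default event count scales as `1/m_e` because the stationary
#' variance is approached at rate `2 m_e / N` per event; 2.5 relaxation
#' times leave under 1% of the initial variance deficit.
#'
#' @param meta metacommunity probability vector (see
#'   [simulate_metacommunity()]).
#' @param n_individuals individuals per local community (>= 100); equals
#'   the read depth of the resulting table.
#' @param m migration rate in (0, 1], interpreted per `m_scale`.
#' @param n_samples number of local communities.
#' @param n_events Moran death events per community (default
#'   `max(10, 2.5 / m_e) * n_individuals`, enough for quasi-stationarity
#'   at any m).
#' @param seed integer seed.
#' @param m_scale "sloan" (default) or "event"; see Details.
#' @return list with `table` ([otu_table()], rows sum to `n_individuals`;
#'   all-zero OTU columns retained) and `truth` (regime, m_true, scale,
#'   seed).
#' @export
simulate_neutral_local <- function(meta, n_individuals = 1000, m, n_samples = 48,
                                   n_events = NULL, seed = NULL,
                                   m_scale = c("sloan", "event")) {
  m_scale <- match.arg(m_scale)
  stopifnot(n_individuals >= 100)
  if (!(m > 0 && m <= 1)) stop("m must lie in (0, 1]")
  N <- n_individuals
  m_event <- if (m_scale == "sloan") N * m / (N - 1 + N * m) else m
  if (is.null(n_events))
    n_events <- ceiling(max(10, 2.5 / m_event) * n_individuals)
  if (!is.null(seed)) set.seed(seed)
  counts <- t(vapply(seq_len(n_samples), function(s)
    moran_community(meta, n_individuals, m_event, n_events),
    integer(length(meta))))
  dimnames(counts) <- list(paste0("S", seq_len(n_samples)), names(meta))
  list(table = otu_table(counts),
       truth = list(regime = "neutral", m_true = m, m_scale = m_scale,
                    m_event = m_event, n_individuals = n_individuals,
                    seed = seed))
}

#' Simulate niche-selected local communities
#'
#' Sample `s` is a multinomial draw of `n_individuals` with weights
#' `w_i = meta_i * exp(-(trait_i - env_s)^2 / (2 * sigma_sel^2))` — Gaussian
#' environmental filtering on a phylogenetically conserved trait. A single
#' shared environment value produces the homogeneous-selection scenario
#' (betaNTI < -2 among samples); two contrasting environment blocks produce
#' variable selection (betaNTI > 2 between blocks).
#'
#' @param meta metacommunity probability vector.
#' @param traits named trait vector over the same OTUs (from
#'   [simulate_tree_with_traits()]).
#' @param env_by_sample numeric environment value per sample (names become
#'   sample ids when present).
#' @param sigma_sel niche width (> 0), in trait units; small values mean
#'   strong selection, `sigma_sel -> Inf` recovers a neutral multinomial.
#' @param n_individuals individuals per sample.
#' @param seed integer seed.
#' @return list with `table` and `truth` as in [simulate_neutral_local()].
#' @export
simulate_niche_local <- function(meta, traits, env_by_sample, sigma_sel,
                                 n_individuals = 1000, seed = NULL) {
  stopifnot(sigma_sel > 0, all(is.finite(env_by_sample)))
  stopifnot(identical(names(meta), names(traits)))
  if (!is.null(seed)) set.seed(seed)
  n_samples <- length(env_by_sample)
  counts <- t(vapply(seq_len(n_samples), function(s) {
    w <- meta * exp(-(traits - env_by_sample[s])^2 / (2 * sigma_sel^2))
    if (sum(w) == 0) stop("all selection weights zero for sample ", s,
                          "; widen sigma_sel")
    as.integer(stats::rmultinom(1, n_individuals, w))
  }, integer(length(meta))))
  ids <- names(env_by_sample)
  if (is.null(ids) || anyDuplicated(ids)) ids <- paste0("S", seq_len(n_samples))
  dimnames(counts) <- list(ids, names(meta))
  list(table = otu_table(counts),
       truth = list(regime = if (length(unique(env_by_sample)) > 1)
                      "variable_selection" else "homogeneous_selection",
                    sigma_sel = sigma_sel, env_by_sample = env_by_sample,
                    n_individuals = n_individuals, seed = seed))
}

#' Simulate dispersal-limited communities via region-restricted pools
#'
#' Each region gets its own perturbed copy of the metacommunity (a
#' Dirichlet resample with concentration `alpha0 * meta`); samples are
#' multinomial draws from their region's pool. Small `alpha0` makes
#' regional pools diverge strongly, which raises between-region Raup-Crick
#' (RC_Bray > 0.95) without generating a phylogenetic selection signal —
#' the dispersal-limitation scenario of the five-process framework.
#'
#' @param meta metacommunity probability vector.
#' @param regions character vector, one region label per sample.
#' @param alpha0 Dirichlet concentration (> 0); smaller = stronger
#'   divergence between regional pools. The default 10 makes regional
#'   pools overlap only weakly (strong dispersal limitation between
#'   regions) while keeping within-region communities coherent.
#' @param n_individuals individuals per sample.
#' @param seed integer seed.
#' @return list with `table`, `truth`, and `region_pools` (matrix, regions
#'   x OTUs).
#' @export
simulate_dispersal_limited <- function(meta, regions, alpha0 = 10,
                                       n_individuals = 1000, seed = NULL) {
  stopifnot(alpha0 > 0)
  if (!is.null(seed)) set.seed(seed)
  reg <- unique(regions)
  pools <- t(vapply(reg, function(r) {
    g <- stats::rgamma(length(meta), shape = alpha0 * meta)
    if (sum(g) == 0) g <- meta
    g / sum(g)
  }, numeric(length(meta))))
  rownames(pools) <- reg
  counts <- t(vapply(seq_along(regions), function(s)
    as.integer(stats::rmultinom(1, n_individuals, pools[regions[s], ])),
    integer(length(meta))))
  dimnames(counts) <- list(paste0("S", seq_along(regions)), names(meta))
  list(table = otu_table(counts),
       truth = list(regime = "dispersal_limited", alpha0 = alpha0,
                    regions = regions, n_individuals = n_individuals,
                    seed = seed),
       region_pools = pools)
}

#' Generate a complete synthetic dataset for one assembly regime
#'
#' Convenience wrapper producing the OTU table, metadata, tree + traits and
#' ground truth for a named regime, mirroring the sampling design the
#' package targets (by default 48 samples in 4 regions x 4 vegetation
#' zones).
#'
#' @param regime one of "neutral", "variable_selection",
#'   "homogeneous_selection", "dispersal_limited".
#' @param n_otus,n_samples,n_individuals community dimensions.
#' @param m immigration rate for the neutral regime.
#' @param sigma_sel_frac niche width as a fraction of the trait SD for the
#'   selection regimes (default 0.5).
#' @param lognormal_sd metacommunity log-normal SD.
#' @param seed integer seed fixing tree, traits, pool and communities.
#' @param out_dir optional directory; when given, writes otu_table.tsv,
#'   metadata.tsv, tree.nwk and truth.json there.
#' @return list with `table`, `metadata`, `tree`, `traits`, `truth`.
#' @export
simulate_dataset <- function(regime = c("neutral", "variable_selection",
                                        "homogeneous_selection",
                                        "dispersal_limited"),
                             n_otus = 300, n_samples = 48,
                             n_individuals = 1000, m = 0.5,
                             sigma_sel_frac = 0.5, lognormal_sd = 2,
                             seed = 1, out_dir = NULL) {
  regime <- match.arg(regime)
  set.seed(seed)
  tt <- simulate_tree_with_traits(n_otus)
  meta <- simulate_metacommunity(n_otus, lognormal_sd)
  trait_sd <- stats::sd(tt$traits)
  n_regions <- 4
  regions <- rep(paste0("R", seq_len(n_regions)), length.out = n_samples)
  zones <- rep(c("mangrove", "ecotone", "cordgrass", "mudflat"),
               length.out = n_samples)
  sim <- switch(regime,
    neutral = simulate_neutral_local(meta, n_individuals, m, n_samples),
    variable_selection = {
      env <- ifelse(seq_len(n_samples) %% 2 == 0, 3, -3) * trait_sd +
        mean(tt$traits)
      simulate_niche_local(meta, tt$traits, env, sigma_sel_frac * trait_sd,
                           n_individuals)
    },
    homogeneous_selection = {
      env <- rep(mean(tt$traits), n_samples)
      simulate_niche_local(meta, tt$traits, env, sigma_sel_frac * trait_sd,
                           n_individuals)
    },
    dispersal_limited =
      simulate_dispersal_limited(meta, regions, n_individuals = n_individuals))
  metadata <- data.frame(sample_id = rownames(sim$table), region = regions,
                         site = paste0(regions, "_",
                                       stats::ave(regions, regions, FUN = seq_along)),
                         zone = zones, stringsAsFactors = FALSE)
  out <- list(table = sim$table, metadata = metadata, tree = tt$tree,
              traits = tt$traits, truth = c(sim$truth, list(master_seed = seed)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_otu_table(out$table, file.path(out_dir, "otu_table.tsv"))
    utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(out$tree, file.path(out_dir, "tree.nwk"))
    jsonlite::write_json(out$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
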