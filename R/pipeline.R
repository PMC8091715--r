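#' Pipeline configuration
#'
#' Collects every threshold, replicate count and seed of the analysis in
#' one validated list. Defaults are the conventional values of the
#' framework: 0.1%/1% rare/abundant cuts, Spearman rho > 0.6 with FDR
#' q < 0.01, 50% occupancy + top-300 network filter, |betaNTI| bound 2 and
#' RC_Bray bound 0.95, Zi/Pi 2.5/0.62, 999 null randomizations, 1000
#' bootstrap replicates, 1000 random graphs, 100 robustness replicates.
#'
#' All randomized stages derive their seed from `seed` (stage r uses
#' `seed + r`), so one integer fixes the whole run.
#'
#' @param seed master seed.
#' @param rare_cut,abundant_cut abundance-category thresholds.
#' @param rho_min,q_max network edge thresholds.
#' @param min_occupancy,top_n network OTU filter.
#' @param bnti_cut,rc_cut process-partition bounds.
#' @param zi_cut,pi_cut keystone role thresholds.
#' @param n_null,n_boot,n_random,n_robust_reps replicate counts.
#' @param zone_column metadata column defining sample groups.
#' @param stages character vector of stages to run, a subset of
#'   c("diversity", "ncm", "assembly", "niche", "network").
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, rare_cut = 0.001, abundant_cut = 0.01,
                            rho_min = 0.6, q_max = 0.01,
                            min_occupancy = 0.5, top_n = 300,
                            bnti_cut = 2, rc_cut = 0.95,
                            zi_cut = 2.5, pi_cut = 0.62,
                            n_null = 999, n_boot = 1000, n_random = 1000,
                            n_robust_reps = 100, zone_column = "zone",
                            stages = c("diversity", "ncm", "assembly",
                                       "niche", "network")) {
  stopifnot(rare_cut > 0, abundant_cut > rare_cut, abundant_cut < 1,
            rho_min > 0, rho_min < 1, q_max > 0, q_max < 1,
            min_occupancy >= 0, min_occupancy <= 1, top_n >= 4,
            bnti_cut > 0, rc_cut > 0, rc_cut <= 1,
            n_null >= 1, n_boot >= 0, n_random >= 1, n_robust_reps >= 1)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_seed <- function(config, stage) {
  config$seed + match(stage, c("diversity", "ncm", "assembly", "niche",
                               "network"))
}

#' Run the full assembly + network pipeline
#'
#' Executes the enabled stages for the overall sample set and for each
#' zone subset, writing tab-separated / JSON outputs under `out_dir` and
#' returning the summary invisibly. The assembly stage requires `tree`;
#' without one it errors (drop "assembly" from `config$stages` for
#' tree-free runs).
#'
#' @param table an [otu_table()], rarefied to equal depth.
#' @param metadata data.frame as from [read_metadata()]; optional (NULL
#'   skips per-zone runs).
#' @param tree an [ape::phylo] or NULL.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); NULL skips file
#'   output.
#' @return (invisibly) nested list: one entry per analysis set ("overall"
#'   plus each zone), each holding the stage results, plus `config`.
#' @export
run_pipeline <- function(table, metadata = NULL, tree = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if ("assembly" %in% config$stages && is.null(tree))
    stop("the assembly stage requires a phylogenetic tree; supply `tree` ",
         "or drop \"assembly\" from config$stages")
  sets <- list(overall = rownames(table))
  if (!is.null(metadata)) {
    zc <- config$zone_column
    md <- metadata[match(rownames(table), metadata$sample_id), ]
    for (z in unique(md[[zc]])) sets[[z]] <- md$sample_id[md[[zc]] == z]
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  res <- list(config = config)
  for (set_name in names(sets)) {
    sub <- otu_table(unclass(table)[sets[[set_name]], , drop = FALSE])
    sub <- otu_table(unclass(sub)[, colSums(sub) > 0, drop = FALSE])
    dir_s <- if (!is.null(out_dir)) file.path(out_dir, set_name)
    if (!is.null(dir_s)) dir.create(dir_s, showWarnings = FALSE)
    r <- .run_stages(sub, tree, config, dir_s)
    res[[set_name]] <- r
  }
  if (!is.null(out_dir)) {
    summ <- lapply(res[setdiff(names(res), "config")], function(r) list(
      n_samples = r$n_samples, n_otus = r$n_otus,
      m = r$ncm$m, ncm_r_squared = r$ncm$r_squared,
      process_fractions = as.list(r$partition$fractions),
      determinism = r$partition$determinism,
      stochasticity = r$partition$stochasticity,
      mean_bcom = if (!is.null(r$bcom)) mean(r$bcom),
      network = if (!is.null(r$topology)) as.list(r$topology),
      n_keystone = if (!is.null(r$zipi)) sum(r$zipi$keystone)))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(res)
}

.run_stages <- function(sub, tree, config, dir_s) {
  r <- list(n_samples = nrow(sub), n_otus = ncol(sub))
  tsv <- function(df, name) if (!is.null(dir_s))
    utils::write.table(df, file.path(dir_s, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if ("diversity" %in% config$stages) {
    r$alpha <- alpha_diversity(sub)
    r$categories <- classify_abundance_categories(
      relative_abundance(sub), config$rare_cut, config$abundant_cut)
    tsv(r$alpha, "alpha_diversity.tsv")
    tsv(r$categories, "categories.tsv")
  }
  if ("ncm" %in% config$stages) {
    r$ncm <- fit_ncm(sub, n_boot = config$n_boot,
                     seed = .stage_seed(config, "ncm"))
    tsv(r$ncm$otus, "ncm_fit.tsv")
    if (!is.null(dir_s))
      jsonlite::write_json(r$ncm[c("m", "N", "d", "r_squared", "m_ci")],
                           file.path(dir_s, "ncm_summary.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  if ("assembly" %in% config$stages) {
    s <- .stage_seed(config, "assembly")
    r$bnti <- beta_nti(sub, tree, n_null = config$n_null, seed = s)
    r$rc <- raup_crick_bray(sub, n_null = config$n_null, seed = s + 1000L)
    r$partition <- partition_processes(r$bnti$bnti, r$rc,
                                       config$bnti_cut, config$rc_cut)
    if (!is.null(dir_s)) {
      utils::write.table(r$bnti$bnti, file.path(dir_s, "bnti.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(r$rc, file.path(dir_s, "rc_bray.tsv"),
                         sep = "\t", quote = FALSE)
      jsonlite::write_json(unclass(r$partition),
                           file.path(dir_s, "partition.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if ("niche" %in% config$stages) {
    B <- levins_breadth(sub)
    r$bcom <- community_breadth(sub)
    tsv(data.frame(otu_id = names(B), B = B), "niche_breadth.tsv")
    tsv(data.frame(sample_id = names(r$bcom), bcom = r$bcom), "bcom.tsv")
  }
  if ("network" %in% config$stages) {
    s <- .stage_seed(config, "network")
    filt <- filter_for_network(sub, config$min_occupancy, config$top_n)
    g <- build_network(filt, config$rho_min, config$q_max)
    r$graph <- g
    if (igraph::ecount(g) > 0) {
      mods <- detect_modules(g, seed = s)
      r$topology <- graph_topology(g, modules = mods)
      r$nodes <- node_topology(g)
      r$zipi <- zipi_classify(g, mods, config$zi_cut, config$pi_cut)
      r$ensemble <- random_ensemble(igraph::vcount(g), igraph::ecount(g),
                                    reps = config$n_random, seed = s)
      r$robustness <- robustness_curve(g, "random",
                                       reps = config$n_robust_reps,
                                       seed = s)
      if (!is.null(dir_s)) {
        tsv(igraph::as_data_frame(g, what = "edges"), "edges.tsv")
        tsv(merge(r$nodes, r$zipi[, c("otu_id", "module", "zi", "pi",
                                      "role", "keystone")], by = "otu_id"),
            "nodes.tsv")
        jsonlite::write_json(as.list(r$topology),
                             file.path(dir_s, "topology.json"),
                             auto_unbox = TRUE, digits = NA)
        tsv(r$ensemble, "random_ensemble.tsv")
        tsv(r$robustness, "robustness.tsv")
        igraph::write_graph(g, file.path(dir_s, "network.graphml"),
                            format = "graphml")
      }
    }
  }
  r
}
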