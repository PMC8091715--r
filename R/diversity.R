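#' Relative abundance matrix
#'
#' @param table an [otu_table()] (or count matrix); every row sum must be
#'   positive.
#' @return matrix of within-sample proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- unclass(table)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("zero-sum samples: ", paste(rownames(m)[rs == 0], collapse = ", "))
  sweep(m, 1, rs, "/")
}

#' Per-sample alpha diversity
#'
#' OTU richness (count of OTUs with count > 0) and the Shannon-Wiener
#' index, H = -sum p log p over nonzero proportions. Natural log by
#' default; `base = 2` switches to bits.
#'
#' @param table an [otu_table()], typically rarefied.
#' @param base logarithm base for Shannon (default `exp(1)`, nats).
#' @return data.frame with columns sample_id, richness, shannon.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  m <- unclass(table)
  data.frame(sample_id = rownames(m),
             richness = rowSums(m > 0),
             shannon = vegan::diversity(m, index = "shannon", base = base),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Monte-Carlo rarefaction curves
#'
#' Mean subsampled richness per sample over a grid of depths, averaged over
#' `reps` random subsamples without replacement per depth.
#'
#' @param table an [otu_table()].
#' @param depths integer vector of subsampling depths (each must not exceed
#'   the smallest sample depth it is applied to).
#' @param reps Monte-Carlo replicates per depth (default 10).
#' @param seed integer seed.
#' @return data.frame with columns sample_id, depth, mean_richness.
#' @export
rarefaction_curve <- function(table, depths, reps = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(table)
  out <- expand.grid(sample_id = rownames(m), depth = sort(depths),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_richness <- mapply(function(s, d) {
    x <- m[s, ]
    if (d > sum(x)) stop("depth ", d, " exceeds reads in sample ", s)
    if (d == sum(x)) return(sum(x > 0))
    mean(vapply(seq_len(reps), function(r)
      sum(vegan::rrarefy(x, d) > 0), numeric(1)))
  }, out$sample_id, out$depth)
  out
}

#' Classify OTUs into the six abundance categories
#'
#' Categories follow the conditional rare/abundant framework with the
#' conventional 0.1% (rare) and 1% (abundant) relative-abundance cuts:
#' \describe{
#'   \item{AAT}{always abundant: >= `abundant_cut` in all samples}
#'   \item{ART}{always rare: < `rare_cut` in all samples}
#'   \item{MT}{moderate: within \[`rare_cut`, `abundant_cut`) in all samples}
#'   \item{CRT}{conditionally rare: < `abundant_cut` in all samples and
#'     < `rare_cut` in some}
#'   \item{CAT}{conditionally abundant: >= `rare_cut` in all samples,
#'     >= `abundant_cut` in some, never rare}
#'   \item{CRAT}{conditionally rare and abundant: spans < `rare_cut` to
#'     >= `abundant_cut`}
#' }
#' Ties at exactly `rare_cut` count as non-rare ("< 0.1%" is strict);
#' `abundant_cut` is inclusive. The six categories partition the OTUs.
#'
#' @param rel relative-abundance matrix (see [relative_abundance()]).
#' @param rare_cut rare threshold as a proportion (default 0.001).
#' @param abundant_cut abundant threshold as a proportion (default 0.01).
#' @return data.frame with columns otu_id, category (factor with the six
#'   levels).
#' @export
classify_abundance_categories <- function(rel, rare_cut = 0.001,
                                          abundant_cut = 0.01) {
  always_ab <- colSums(rel >= abundant_cut) == nrow(rel)
  ever_ab <- colSums(rel >= abundant_cut) > 0
  always_rare <- colSums(rel < rare_cut) == nrow(rel)
  ever_rare <- colSums(rel < rare_cut) > 0
  cat <- ifelse(always_ab, "AAT",
         ifelse(always_rare, "ART",
         ifelse(!ever_rare & !ever_ab, "MT",
         ifelse(ever_rare & !ever_ab, "CRT",
         ifelse(!ever_rare & ever_ab, "CAT", "CRAT")))))
  stopifnot(!anyNA(cat))  # the five conditions are exhaustive by construction
  data.frame(otu_id = colnames(rel),
             category = factor(cat, levels = c("AAT", "ART", "MT", "CRT",
                                               "CAT", "CRAT")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit a truncated Preston log-normal to an abundance distribution
#'
#' Bins OTU total abundances into doubling (log2) octaves and fits the
#' Gaussian octave curve S(R) = S0 exp(-(R - R0)^2 / (2 sigma^2)), either
#' by quasi-Poisson regression on octave counts (`octave_glm`,
#' [vegan::prestonfit()] with ties split between adjacent octaves) or by
#' maximum likelihood on log2 abundances (`log2_mle`,
#' [vegan::prestondistr()]). The extrapolated ("unveiled") richness is
#' S0 sigma sqrt(2 pi); coverage is observed richness over extrapolated
#' richness — the fraction of the regional richness the sampling captured.
#'
#' @param abundances vector of per-OTU total abundances (>= 10 positive
#'   entries required).
#' @param method "octave_glm" or "log2_mle".
#' @return object of class `preston_fit`: list with `octaves` (observed and
#'   fitted counts per octave), `coefficients` (mode, width, S0),
#'   `observed_richness`, `extrapolated_richness`, `coverage`, `method`.
#' @export
preston_fit <- function(abundances, method = c("octave_glm", "log2_mle")) {
  method <- match.arg(method)
  abundances <- abundances[abundances > 0]
  if (length(abundances) < 10) stop("need >= 10 OTUs with positive abundance")
  fit <- tryCatch(
    if (method == "octave_glm") vegan::prestonfit(abundances, tiesplit = TRUE)
    else vegan::prestondistr(abundances),
    error = function(e) stop("Preston fit failed (", conditionMessage(e),
                             "); octave table: ",
                             paste(names(table(ceiling(log2(abundances)))),
                                   table(ceiling(log2(abundances))),
                                   sep = ":", collapse = " ")))
  veil <- vegan::veiledspec(fit)
  co <- fit$coefficients  # mode, width, S0
  ext <- unname(veil["Extrapolated"])
  obs <- length(abundances)
  structure(list(octaves = fit$freq, fitted = fit$fitted,
                 coefficients = co, observed_richness = obs,
                 extrapolated_richness = ext,
                 coverage = obs / ext, method = method),
            class = "preston_fit")
}

#' @export
print.preston_fit <- function(x, ...) {
  cat("Truncated Preston log-normal (", x$method, ")\n",
      "  mode ", signif(x$coefficients["mode"], 4),
      ", width ", signif(x$coefficients["width"], 4),
      ", S0 ", signif(x$coefficients["S0"], 4), "\n",
      "  observed richness ", x$observed_richness,
      ", extrapolated ", round(x$extrapolated_richness, 1),
      " (coverage ", sprintf("%.1f%%", 100 * x$coverage), ")\n", sep = "")
  invisible(x)
}

#' Gaussian-octave extrapolated richness
#'
#' Closed form for the area under the Preston curve:
#' S0 * sigma * sqrt(2 pi).
#'
#' @param S0 modal octave height. @param sigma octave-scale width.
#' @return total (veiled + unveiled) richness implied by the fit.
#' @export
preston_total_richness <- function(S0, sigma) S0 * sigma * sqrt(2 * pi)

#' Tukey HSD pairwise comparisons
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference test
#' (studentized-range distribution), as used for group comparisons of
#' alpha diversity and niche breadth.
#'
#' @param values numeric response vector.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @return data.frame with columns group1, group2, diff (mean difference),
#'   lwr, upr, p_adj.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  if (stats::sd(values) == 0) stop("response has zero variance")
  fit <- stats::aov(values ~ groups)
  td <- stats::TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(td), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, "", 1),
             group2 = vapply(pairs, `[`, "", 2),
             diff = td[, "diff"], lwr = td[, "lwr"], upr = td[, "upr"],
             p_adj = td[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}
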