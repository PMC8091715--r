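#' Sloan neutral-model predicted occupancy
#'
#' Expected detection frequency of a taxon with metacommunity relative
#' abundance `p` in local communities of size `N` with migration rate `m`,
#' at detection limit `d`: `1 - pbeta(d, N m p, N m (1 - p))`. Under the
#' neutral model the stationary local relative abundance of the taxon is
#' Beta(N m p, N m (1 - p)); the taxon is detected when that abundance
#' exceeds `d`.
#'
#' @param p mean relative abundance(s). @param m migration rate in (0, 1].
#' @param N local community size (reads per sample). @param d detection
#'   limit (default 1/N).
#' @return predicted occupancy in \[0, 1\], non-decreasing in `p`.
#' @export
ncm_predict <- function(p, m, N, d = 1 / N) {
  stats::pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE)
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration rate `m` by bounded least squares of observed
#' occupancy (fraction of samples in which each OTU is detected) against
#' the neutral prediction [ncm_predict()] as a function of mean relative
#' abundance. The community size `N` is the rarefaction depth (rows must
#' have equal sums) and the detection limit is `1/N`. Fit quality is
#' reported as `R^2 = 1 - SSE/SStot` around the mean observed occupancy;
#' a 95% CI for `m` comes from bootstrap resampling of OTUs.
#'
#' OTUs with mean relative abundance below the detection limit are
#' excluded from the fit (the prediction is degenerate below detection).
#'
#' @param table a rarefied [otu_table()] with >= 20 OTUs.
#' @param n_boot bootstrap replicates for the `m` CI (default 1000; 0
#'   skips the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @param conf_level confidence level of the occupancy prediction band and
#'   bootstrap interval (default 0.95).
#' @return object of class `ncm_fit`: list with `m`, `N`, `d`,
#'   `r_squared`, `m_ci`, and `otus` — a data.frame (otu_id, p, freq,
#'   pred, lower, upper, partition) where the prediction band is the
#'   Wilson score interval at `n = n_samples` and partition is
#'   above/neutral/below (see [ncm_partition()]).
#' @export
fit_ncm <- function(table, n_boot = 1000, seed = NULL, conf_level = 0.95) {
  m0 <- unclass(table)
  depths <- rowSums(m0)
  if (max(depths) - min(depths) > 0)
    stop("table must be rarefied to equal depth before fitting")
  if (ncol(m0) < 20) stop("need >= 20 OTUs to fit the neutral model")
  N <- depths[1]
  d <- 1 / N
  p <- colMeans(m0) / N
  freq <- colMeans(m0 > 0)
  keep <- p >= d
  p_fit <- p[keep]
  freq_fit <- freq[keep]
  if (length(unique(freq_fit)) < 2)
    stop("no occupancy variation to fit (all OTUs at identical occupancy); ",
         "use a larger or less saturated community")
  sse <- function(m, pp, ff) sum((ff - ncm_predict(pp, m, N, d))^2)
  m_hat <- stats::optimize(sse, c(1e-6, 1), pp = p_fit, ff = freq_fit)$minimum
  r2 <- 1 - sse(m_hat, p_fit, freq_fit) / sum((freq_fit - mean(freq_fit))^2)
  m_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n_otu <- length(p_fit)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_otu, n_otu, replace = TRUE)
      stats::optimize(sse, c(1e-6, 1), pp = p_fit[idx],
                      ff = freq_fit[idx])$minimum
    }, numeric(1))
    a <- (1 - conf_level) / 2
    m_ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  pred <- ncm_predict(p, m_hat, N, d)
  band <- wilson_interval(pred, nrow(m0), conf_level)
  otus <- data.frame(otu_id = colnames(m0), p = p, freq = freq, pred = pred,
                     lower = band[, 1], upper = band[, 2],
                     partition = ifelse(freq > band[, 2], "above",
                                 ifelse(freq < band[, 1], "below", "neutral")),
                     in_fit = keep, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(m = m_hat, N = unname(N), d = d, r_squared = r2,
                 m_ci = m_ci, n_samples = nrow(m0), conf_level = conf_level,
                 otus = otus),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n",
      "  N = ", x$N, " (depth), m = ", signif(x$m, 4),
      if (!anyNA(x$m_ci)) paste0(" [", signif(x$m_ci[1], 4), ", ",
                                 signif(x$m_ci[2], 4), "]"),
      ", R^2 = ", signif(x$r_squared, 4), "\n",
      "  OTU partition: ", sum(x$otus$partition == "below"), " below / ",
      sum(x$otus$partition == "neutral"), " neutral / ",
      sum(x$otus$partition == "above"), " above the prediction band\n",
      sep = "")
  invisible(x)
}

#' Per-OTU neutrality partition
#'
#' Labels each OTU by where its observed occupancy falls relative to the
#' Wilson score confidence band around the neutral prediction: "above"
#' (over-represented across samples), "neutral" (within the band) or
#' "below".
#'
#' @param fit an [fit_ncm()] result.
#' @return named character vector of labels over OTUs.
#' @export
ncm_partition <- function(fit) {
  stats::setNames(fit$otus$partition, fit$otus$otu_id)
}

#' Wilson score interval
#'
#' Confidence interval for a binomial proportion `phat` observed over `n`
#' trials, by inverting the score test. Used for the occupancy prediction
#' band of the neutral model (occupancy is a proportion over `n` samples).
#'
#' @param phat proportion(s) in \[0, 1\]. @param n number of trials.
#' @param conf_level confidence level (default 0.95).
#' @return two-column matrix (lower, upper), clamped to \[0, 1\].
#' @export
wilson_interval <- function(phat, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}
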