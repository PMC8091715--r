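#' Levins' niche breadth per OTU
#'
#' `B_j = 1 / sum_i P_ij^2`, where `P_ij` is OTU j's count in community i
#' divided by its total count over all communities (so `sum_i P_ij = 1`).
#' B ranges from 1 (a specialist confined to one community) to the number
#' of communities (a generalist spread perfectly evenly); it depends only
#' on the OTU's proportional distribution across samples, not its total
#' abundance.
#'
#' @param table an [otu_table()]; all-zero OTUs are excluded with a
#'   message.
#' @return named numeric vector of B values over OTUs present in >= 1
#'   sample.
#' @export
levins_breadth <- function(table) {
  m <- unclass(table)
  tot <- colSums(m)
  if (any(tot == 0)) {
    message(sum(tot == 0), " all-zero OTU(s) excluded from niche breadth")
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  P <- sweep(m, 2, tot, "/")
  1 / colSums(P^2)
}

#' Community-level niche breadth (Bcom)
#'
#' The arithmetic mean of [levins_breadth()] over the taxa present
#' (count > 0) in each sample. High Bcom communities are dominated by
#' habitat generalists — a signature of weak selection / strong
#' stochasticity.
#'
#' @param table an [otu_table()].
#' @return named numeric vector of Bcom per sample.
#' @export
community_breadth <- function(table) {
  m <- unclass(table)
  if (any(rowSums(m) == 0))
    stop("empty sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  B <- levins_breadth(table)
  m <- m[, names(B), drop = FALSE]
  vapply(rownames(m), function(s) mean(B[m[s, ] > 0]), numeric(1))
}
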