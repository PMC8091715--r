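#' Construct an OTU table
#'
#' The universal input container of the package: a non-negative integer
#' count matrix with samples as rows and OTUs as columns. Row names are
#' sample identifiers, column names OTU identifiers; both must be unique.
#'
#' @param counts numeric matrix of non-negative integers, samples x OTUs,
#'   with unique row and column names.
#' @return An `otu_table` object (an integer matrix with class attribute).
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop("non-negative integer counts required; offending cell: sample '",
         rownames(counts)[bad[1]], "', OTU '", colnames(counts)[bad[2]], "'")
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x), " samples x ", ncol(x), " OTUs; ",
      "depth range [", min(rowSums(x)), ", ", max(rowSums(x)), "]\n", sep = "")
  invisible(x)
}

#' Read an OTU table from a tab-separated file
#'
#' The file must have one header row and one identifier column (the first).
#' On-disk orientation (samples-as-rows vs OTUs-as-rows) is auto-detected by
#' a header heuristic, or forced with `orientation`.
#'
#' The heuristic: if the first header field is (case-insensitively) one of
#' "otu", "otu_id", "otuid", "#otu id", "taxon", the file is taken as
#' OTUs-as-rows; the converse tokens ("sample", "sample_id", "sampleid")
#' force samples-as-rows; otherwise samples-as-rows is assumed.
#'
#' @param path file path.
#' @param orientation one of "auto", "samples_as_rows", "otus_as_rows".
#' @return An [otu_table()] oriented samples x OTUs.
#' @export
read_otu_table <- function(path, orientation = c("auto", "samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  header1 <- tolower(trimws(sub("^#", "", names(utils::read.delim(path, nrows = 1,
                                                                  check.names = FALSE))[1])))
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "auto") {
    otu_tokens <- c("otu", "otu_id", "otuid", "otu id", "taxon", "taxon_id")
    orientation <- if (header1 %in% otu_tokens) "otus_as_rows" else "samples_as_rows"
  }
  if (orientation == "otus_as_rows") m <- t(m)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric cell in OTU table at row '", rownames(m)[bad[1, 1]],
         "', column '", colnames(m)[bad[1, 2]], "'")
  }
  otu_table(m)
}

#' Write an OTU table to a tab-separated file
#'
#' Samples as rows, first column `sample_id`. [read_otu_table()] of the
#' result round-trips exactly.
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy an OTU table to a fixed depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw, via [vegan::rrarefy()]) so that every row sums to
#' `depth`. This removes sequencing-depth bias before occupancy- and
#' dissimilarity-based analyses.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample; every sample must have at least
#'   this many reads.
#' @param seed integer seed for the subsampling draw (bit-reproducible).
#' @param drop_empty drop OTU columns that are all-zero after rarefaction
#'   (default TRUE; they cannot contribute to any downstream statistic).
#' @return A rarefied [otu_table()] with identical row sums.
#' @export
rarefy_table <- function(table, depth, seed = NULL, drop_empty = TRUE) {
  stopifnot(depth > 0)
  depths <- rowSums(table)
  short <- depths < depth
  if (any(short))
    stop("samples below rarefaction depth ", depth, ": ",
         paste(rownames(table)[short], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- unclass(table)
  needs <- depths > depth
  if (any(needs))
    # depth feasibility is validated above; rrarefy's remaining warning is
    # a counts-look-transformed heuristic that misfires on small fixtures
    out[needs, ] <- suppressWarnings(
      vegan::rrarefy(unclass(table)[needs, , drop = FALSE], depth))
  if (drop_empty) out <- out[, colSums(out) > 0, drop = FALSE]
  otu_table(out)
}

#' Read sample metadata
#'
#' Tab-separated file with columns `sample_id`, `region`, `site`, `zone`.
#'
#' @param path file path.
#' @param table optional [otu_table()]; if given, every sample of the table
#'   must resolve to exactly one metadata row.
#' @return data.frame keyed by `sample_id`.
#' @export
read_metadata <- function(path, table = NULL) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "region", "site", "zone")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.null(table)) {
    absent <- setdiff(rownames(table), md$sample_id)
    if (length(absent))
      stop("samples without metadata: ", paste(absent, collapse = ", "))
  }
  md
}

#' Read a rooted phylogenetic tree of OTUs
#'
#' Thin wrapper over [ape::read.tree()] with validation: unique, non-empty
#' tip labels and non-negative branch lengths. Patristic (cophenetic)
#' distances are computed on demand by [patristic_distances()].
#'
#' @param path Newick file path.
#' @param otu_ids optional character vector; tips absent from it trigger a
#'   warning listing the mismatches.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path, otu_ids = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("malformed Newick file: ", path)
  if (any(is.na(tree$tip.label)) || any(tree$tip.label == ""))
    stop("tree contains unlabeled tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  if (!is.null(otu_ids)) {
    extra <- setdiff(tree$tip.label, otu_ids)
    if (length(extra))
      warning(length(extra), " tree tips match no OTU id: ",
              paste(utils::head(extra, 10), collapse = ", "),
              if (length(extra) > 10) " ..." else "")
  }
  tree
}

#' Patristic distance matrix of a tree
#'
#' @param tree an [ape::phylo] object.
#' @return symmetric matrix of tip-to-tip path lengths (sum of branch
#'   lengths), zero on the diagonal.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}
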