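#' Complete-linkage agglomeration of sample profiles
#'
#' Clusters the columns (sample profiles) of a matrix by agglomerative
#' hierarchical clustering with Euclidean distance and complete linkage: the
#' distance between two clusters is the maximum pairwise distance between
#' their members, which guarantees non-decreasing merge heights.
#'
#' @param z Numeric matrix, variables in rows and samples in columns
#'   (normally row-standardized; see [standardize_rows()]).
#' @param linkage Agglomeration rule; only `"complete"` is supported.
#' @param metric Dissimilarity; only `"euclidean"` is supported.
#' @return An [stats::hclust] object over the columns of `z`, with an
#'   `"n_v"` attribute recording the number of variable rows used.
#' @export
#' @examples
#' z <- cbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
#' hc <- agglomerate(z)
#' hc$height   # 5, 10
agglomerate <- function(z, linkage = c("complete"), metric = c("euclidean")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (!is.matrix(z) || !is.numeric(z)) {
    stop("z must be a numeric matrix (variables x samples)")
  }
  if (ncol(z) < 2L) {
    stop("need at least 2 sample columns to cluster")
  }
  hc <- stats::hclust(stats::dist(t(z), method = metric), method = linkage)
  attr(hc, "n_v") <- nrow(z)
  hc
}

#' Normalized merge heights of a dendrogram
#'
#' Divides the `n_s - 1` merge heights by `sqrt(n_v)` so that heights are on
#' a per-variable scale and comparable across profile dimensions, and sorts
#' them non-decreasingly. The normalized height between two standardized
#' profiles is the root-mean-square coordinate difference.
#'
#' @param hc An [stats::hclust] object (e.g. from [agglomerate()]).
#' @param n_v Number of variable rows used to build `hc`. Defaults to the
#'   `"n_v"` attribute recorded by [agglomerate()].
#' @return Sorted numeric vector of length `n_s - 1`.
#' @export
normalized_heights <- function(hc, n_v = attr(hc, "n_v")) {
  if (!inherits(hc, "hclust")) {
    stop("hc must be an hclust object")
  }
  if (is.null(n_v)) {
    stop("n_v is required when hc carries no 'n_v' attribute")
  }
  if (!is.numeric(n_v) || length(n_v) != 1L || n_v < 1) {
    stop("n_v must be a single count >= 1")
  }
  known <- attr(hc, "n_v")
  if (!is.null(known) && known != n_v) {
    stop("n_v = ", n_v, " does not match the ", known,
         " variable rows this tree was built from")
  }
  sort(hc$height) / sqrt(n_v)
}

#' Cut a dendrogram at a height
#'
#' Performs all merges with height `<= h` and returns flat cluster labels.
#' The number of clusters equals `1 + ` the number of merge heights strictly
#' above `h`. Labels are consecutive integers numbered by decreasing cluster
#' size (ties broken by first-appearing sample).
#'
#' @param hc An [stats::hclust] object. `h` must be on the same scale as
#'   `hc$height` (the caller normalizes consistently).
#' @param h Cut height. Below the smallest merge every sample is its own
#'   cluster; at or above the largest merge there is one cluster.
#' @return Integer label vector of length `n_s`, named by sample id.
#' @export
cut_at_height <- function(hc, h) {
  if (!inherits(hc, "hclust")) {
    stop("hc must be an hclust object")
  }
  if (!is.numeric(h) || length(h) != 1L || is.na(h)) {
    stop("h must be a single height")
  }
  relabel_by_size(stats::cutree(hc, h = h))
}

#' Export a dendrogram as a Newick string
#'
#' Converts the merge tree to Newick text via [ape::as.phylo()], in which a
#' leaf's depth below its first merge is half that merge's height (the usual
#' ultrametric rendering of an hclust tree).
#'
#' @param hc An [stats::hclust] object.
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
to_newick <- function(hc, file = NULL) {
  if (!inherits(hc, "hclust")) {
    stop("hc must be an hclust object")
  }
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
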