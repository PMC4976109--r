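#' Contingency table of true vs inferred cluster labels
#'
#' Cross-classifies objects by their true and inferred cluster membership.
#' All agreement metrics in the package are functions of this table.
#'
#' @param true_labels,inferred_labels Equal-length label vectors (any atomic
#'   type; values are treated as categorical).
#' @return An integer matrix with one row per true cluster and one column
#'   per inferred cluster; entry `[i, j]` counts the objects in true cluster
#'   `i` assigned to inferred cluster `j`.
#' @export
#' @examples
#' cluster_contingency(c("A", "A", "B", "B"), c(1, 1, 1, 2))
cluster_contingency <- function(true_labels, inferred_labels) {
  if (length(true_labels) != length(inferred_labels)) {
    stop("label vectors differ in length (", length(true_labels),
         " vs ", length(inferred_labels), ")")
  }
  if (length(true_labels) < 1L) {
    stop("need at least one labeled object")
  }
  tab <- table(true = true_labels, inferred = inferred_labels)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m
}

#' Proportion of wrong clusters (PWC)
#'
#' A signed error on the number of detected clusters, scaled by the number
#' of possible errors: `(n_detected - n_true) / (D - n_true)` with
#' `D = n_samples` (or `denominator_cap` when the search was capped, as in
#' the Beale scan over at most 500 clusters). PWC is 0 when the count is
#' exact, 1 when every sample is its own cluster, and negative when clusters
#' are under-detected, with minimum `(1 - n_true)/(D - n_true)` when
#' everything is merged into one cluster.
#'
#' @param n_detected Number of clusters detected.
#' @param n_true True number of clusters.
#' @param n_samples Number of sample profiles.
#' @param denominator_cap Optional cap `D` replacing `n_samples` in the
#'   denominator (e.g. 500 for the capped Beale scan).
#' @return A single number in `[(1 - n_true)/(D - n_true), 1]`.
#' @export
#' @examples
#' pwc(13, 13, 2000)  # 0
#' pwc(2000, 13, 2000)  # 1
pwc <- function(n_detected, n_true, n_samples, denominator_cap = NULL) {
  D <- if (is.null(denominator_cap)) n_samples else denominator_cap
  if (n_true < 1 || n_true > n_samples) {
    stop("n_true must be in [1, n_samples]")
  }
  if (n_detected < 1 || n_detected > max(n_samples, D)) {
    stop("n_detected must be in [1, ", max(n_samples, D), "]")
  }
  if (D == n_true) {
    stop("degenerate denominator: cap equals the true cluster count")
  }
  (n_detected - n_true) / (D - n_true)
}

#' Cramer's V dependency index between two partitions
#'
#' Measures the dependency between true and inferred cluster labels as
#' `(chi^2 / n) / min(r - 1, c - 1)` on the contingency table with `r` true
#' and `c` inferred clusters (the square of the classical Cramer's V; set
#' `classic = TRUE` for the square-root form). The index is 1 for perfect
#' dependency — note it stays 1 when true clusters are cleanly merged into
#' larger inferred clusters, an error [jaccard_similarity()] does detect.
#'
#' @param tab A contingency table/matrix (see [cluster_contingency()]), or a
#'   label vector paired with `inferred_labels`.
#' @param inferred_labels Optional; when given, `tab` is taken as the true
#'   label vector and the table is built internally.
#' @param classic If `TRUE` return the square root (the textbook V).
#' @return A number in \[0, 1\].
#' @details Undefined (an error) when either partition has a single cluster:
#'   `min(r - 1, c - 1)` would be zero.
#' @export
cramers_v <- function(tab, inferred_labels = NULL, classic = FALSE) {
  if (!is.null(inferred_labels)) {
    tab <- cluster_contingency(tab, inferred_labels)
  }
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  r <- nrow(tab)
  c <- ncol(tab)
  if (r < 2L || c < 2L) {
    stop("index undefined: both partitions need at least 2 clusters")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  v <- (chi2 / n) / min(r - 1, c - 1)
  if (classic) sqrt(v) else v
}

#' Average Jaccard similarity between two partitions
#'
#' Sums `|intersection| / |union|` over every (true cluster, inferred
#' cluster) pair and divides by `max(r, c)`, the larger of the two cluster
#' counts. Equals 1 only when the partitions are identical up to relabeling;
#' unlike [cramers_v()] it is penalized when clusters are merged or split,
#' so the two indices together separate composition errors from
#' count errors.
#'
#' @param true_labels,inferred_labels Equal-length label vectors.
#' @return A number in (0, 1\].
#' @export
#' @examples
#' jaccard_similarity(c("A", "A", "B", "B"), c(1, 1, 1, 2))  # 17/24
jaccard_similarity <- function(true_labels, inferred_labels) {
  tab <- cluster_contingency(true_labels, inferred_labels)
  union <- outer(rowSums(tab), colSums(tab), "+") - tab
  sum(tab / union) / max(nrow(tab), ncol(tab))
}
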