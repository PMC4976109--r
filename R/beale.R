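#' Beale's pseudo-F statistic for k clusters vs one cluster
#'
#' Tests whether a k-cluster partition of the sample profiles explains
#' significantly more variation than a single cluster holding all data.
#' With `S1` the total sum of squares about the grand mean profile and `S2`
#' the within-cluster sum of squares under the partition,
#' \deqn{F = \frac{(S_1 - S_2)/S_2}{\frac{n_s - 1}{n_s - k}\,k^{2/n_v} - 1}}
#' referred to an F distribution on `n_v (k - 1)` and `n_v (n_s - k)`
#' degrees of freedom.
#'
#' @param z Numeric matrix, variables in rows and samples in columns
#'   (normally row-standardized).
#' @param labels Cluster labels for the columns of `z`, defining `k >= 2`
#'   non-empty clusters.
#' @return A list with `statistic`, `df1`, `df2`, `p.value`, `k`, `S1`,
#'   `S2`. Perfectly tight clusters (`S2 = 0`) give `statistic = Inf`,
#'   `p.value = 0`.
#' @export
#' @examples
#' z <- matrix(c(0, 1, 9, 10), 1, 4)   # one variable, four samples
#' beale_f(z, c(1, 1, 2, 2))$statistic # 16.2
beale_f <- function(z, labels) {
  if (!is.matrix(z) || !is.numeric(z)) {
    stop("z must be a numeric matrix (variables x samples)")
  }
  n_s <- ncol(z)
  n_v <- nrow(z)
  if (length(labels) != n_s) {
    stop("labels must have one entry per sample column")
  }
  g <- factor(labels)
  k <- nlevels(g)
  if (k < 2L) {
    stop("labels must define at least 2 clusters")
  }
  sizes <- tabulate(g)
  if (any(sizes == 0L)) {
    stop("empty cluster in labels")
  }
  if (k >= n_s) {
    stop("need k < n_s for Beale's statistic")
  }
  gm <- rowMeans(z)
  S1 <- sum((z - gm)^2)
  # S2 = sum_j ||z_j||^2 - sum_c ||sum_{j in c} z_j||^2 / n_c
  cs <- rowsum(t(z), g)
  S2 <- sum(z^2) - sum(cs^2 / sizes)
  S2 <- max(S2, 0)   # guard tiny negative rounding
  denom <- ((n_s - 1) / (n_s - k)) * k^(2 / n_v) - 1
  df1 <- n_v * (k - 1)
  df2 <- n_v * (n_s - k)
  if (S2 == 0) {
    stat <- Inf
    p <- 0
  } else {
    stat <- ((S1 - S2) / S2) / denom
    p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
  }
  list(statistic = stat, df1 = df1, df2 = df2, p.value = p,
       k = k, S1 = S1, S2 = S2)
}

#' Select a number of clusters by scanning Beale's pseudo-F over tree cuts
#'
#' Cuts the dendrogram into exactly `k` groups for `k = 2, ...,
#' min(k_max, n_s - 1)` and computes [beale_f()] for each partition against
#' the single-cluster null. If the largest F over the scan is significant
#' (its p-value below `alpha`) the corresponding `k` is selected (ties
#' toward smaller `k`); otherwise one cluster is selected.
#'
#' @param hc Dendrogram of the columns of `z` ([stats::hclust] /
#'   [agglomerate()]).
#' @param z The matrix `hc` was built from.
#' @param alpha Significance level for the maximum F; 0.05 by default.
#' @param k_max Scan cap; default 500. The scan never exceeds `n_s - 1`
#'   (at `k = n_s` the within-cluster sum of squares is 0 and the statistic
#'   is undefined).
#' @return An object of class `"beale_scan"`: a list with `k_selected`,
#'   `k` (scanned values), `f`, `p.value` (vectors over the scan), `alpha`,
#'   `k_max`.
#' @export
beale_select <- function(hc, z, alpha = 0.05, k_max = 500) {
  if (!inherits(hc, "hclust")) {
    stop("hc must be an hclust object")
  }
  if (!is.matrix(z) || ncol(z) != length(hc$order)) {
    stop("z must be the variables x samples matrix hc was built from")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  n_s <- ncol(z)
  n_v <- nrow(z)
  ks <- seq(2L, min(k_max, n_s - 1L))
  cuts <- stats::cutree(hc, k = ks)
  if (length(ks) == 1L) {
    cuts <- matrix(cuts, ncol = 1L)
  }
  gm <- rowMeans(z)
  S1 <- sum((z - gm)^2)
  tot <- sum(z^2)
  tz <- t(z)
  S2 <- numeric(length(ks))
  for (i in seq_along(ks)) {
    g <- cuts[, i]
    sizes <- tabulate(g)
    S2[i] <- tot - sum(rowsum(tz, g)^2 / sizes)
  }
  S2 <- pmax(S2, 0)
  denom <- ((n_s - 1) / (n_s - ks)) * ks^(2 / n_v) - 1
  f <- ifelse(S2 == 0, Inf, ((S1 - S2) / S2) / denom)
  p <- ifelse(S2 == 0, 0,
              stats::pf(f, n_v * (ks - 1), n_v * (n_s - ks),
                        lower.tail = FALSE))
  best <- which.max(f)
  k_selected <- if (p[best] < alpha) ks[best] else 1L
  structure(
    list(k_selected = k_selected, k = ks, f = f, p.value = p,
         alpha = alpha, k_max = k_max),
    class = "beale_scan"
  )
}

#' @export
print.beale_scan <- function(x, ...) {
  best <- which.max(x$f)
  cat("Beale pseudo-F scan over dendrogram cuts\n")
  cat(sprintf("  scanned k = %d..%d (cap %d), alpha = %g\n",
              min(x$k), max(x$k), x$k_max, x$alpha))
  cat(sprintf("  max F = %.4g at k = %d (p = %.3g)\n",
              x$f[best], x$k[best], x$p.value[best]))
  cat(sprintf("  selected: %d cluster%s\n", x$k_selected,
              if (x$k_selected == 1L) "" else "s"))
  invisible(x)
}
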