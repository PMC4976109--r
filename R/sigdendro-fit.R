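#' Significance level implied by a reference percentile
#'
#' Clusters detected by cutting the observed dendrogram at the p-th
#' percentile of the permutation reference distribution carry significance
#' level `alpha = 1 - p/100`: the expected proportion of falsely detected
#' clusters when the data hold no real structure.
#'
#' @param p Percentile in (0, 100\].
#' @return The significance level, a single number in \[0, 1).
#' @export
#' @examples
#' alpha_from_percentile(95)    # 0.05
#' alpha_from_percentile(99.9)  # 0.001
alpha_from_percentile <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 100) {
    stop("p must be a percentile in (0, 100]")
  }
  1 - p / 100
}

#' Detect significant clusters in hierarchical clustering by resampling
#'
#' Fits the full resampling procedure for significant group detection:
#' \enumerate{
#'   \item standardize the rows of `x` (variables on a common scale);
#'   \item cluster the sample columns with complete linkage and Euclidean
#'     distance, and record the `n_s - 1` merge heights, normalized by
#'     `sqrt(n_v)`, as the observed vector `D_o`;
#'   \item build the reference distribution `D_e` from `r` replicates in
#'     which every row is reshuffled independently (no-cluster null);
#'   \item cut the observed dendrogram at the `percentile`-th percentile of
#'     `D_e`. Each split surviving the cut is a merge whose height exceeds
#'     what random data would produce, so the detected clusters carry
#'     significance level `alpha = 1 - percentile/100`.
#' }
#'
#' @param x Numeric matrix with variables in rows and sample profiles in
#'   columns (see [read_profile_matrix()]), or a data frame coercible to one.
#' @param percentile Percentile of the reference distribution used as the
#'   cut height, in (0, 100\]. 95 gives `alpha = 0.05`; use more extreme
#'   values (99-99.9) when the QQ plot shows only modest separation.
#' @param r Number of permutation replicates for the reference; default 10.
#' @param seed Optional integer seed controlling the permutations.
#' @param standardize Row standardization: `"mean_sd"` (default),
#'   `"trimmed"`, or `"none"` if `x` is already standardized.
#' @param trim_fraction Passed to [standardize_rows()] for
#'   `standardize = "trimmed"`.
#' @return An object of class `"sigdendro"`, a list with components
#'   `labels` (integer cluster labels named by sample, numbered by
#'   decreasing size), `n_clusters`, `threshold` (normalized cut height),
#'   `percentile`, `alpha`, `r`, `seed`, `D_o` (sorted observed normalized
#'   heights), `reference` (the `"dendro_reference"`), `hclust` (observed
#'   tree with normalized heights), `n_v`, `n_s`, and `call`.
#' @details If the threshold reaches the top of the observed dendrogram the
#'   fit returns a single cluster with a warning: the data show no
#'   significant structure at this `alpha`. To rescan several percentiles
#'   against the same reference use [recut()].
#' @seealso [recut()], [qq_table()], [plot.sigdendro()]
#' @export
#' @examples
#' sim <- generate_dataset(n_c = 2, n_v = 8, n_s = 60, sigma = 10, seed = 1)
#' fit <- sigdendro(sim$x, percentile = 95, r = 10, seed = 2)
#' fit
#' table(fit$labels, sim$labels)
sigdendro <- function(x, percentile = 95, r = 10, seed = NULL,
                      standardize = c("mean_sd", "trimmed", "none"),
                      trim_fraction = 0.05) {
  standardize <- match.arg(standardize)
  if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  validate_profile_matrix(x)
  alpha <- alpha_from_percentile(percentile)
  z <- if (standardize == "none") {
    x
  } else {
    standardize_rows(x, method = standardize, trim_fraction = trim_fraction)
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  n_v <- nrow(z)
  n_s <- ncol(z)
  hc <- agglomerate(z)
  hc$height <- hc$height / sqrt(n_v)
  D_o <- sort(hc$height)
  ref <- reference_heights(z, r = r)
  ref$seed <- seed
  threshold <- reference_percentile(ref, percentile)
  labels <- cut_at_height(hc, threshold)
  n_clusters <- max(labels)
  if (n_clusters == 1L) {
    warning("no significant structure at alpha = ", format(alpha),
            " (threshold ", format(threshold),
            " reaches the top of the dendrogram)")
  }
  structure(
    list(labels = labels, n_clusters = n_clusters, threshold = threshold,
         percentile = percentile, alpha = alpha, r = ref$r, seed = seed,
         D_o = D_o, reference = ref, hclust = hc, n_v = n_v, n_s = n_s,
         standardize = standardize, call = match.call()),
    class = "sigdendro"
  )
}

#' Re-cut a fitted dendrogram at a different percentile
#'
#' The permutation reference does not depend on the percentile, so scanning
#' several significance levels (e.g. 99, 99.1, ..., 99.9) reuses one fit.
#'
#' @param object A fitted [sigdendro] object.
#' @param percentile New percentile in (0, 100\].
#' @return A new `"sigdendro"` object sharing the data, tree and reference.
#' @export
recut <- function(object, percentile) {
  if (!inherits(object, "sigdendro")) {
    stop("object must be a sigdendro fit")
  }
  out <- object
  out$percentile <- percentile
  out$alpha <- alpha_from_percentile(percentile)
  out$threshold <- reference_percentile(object$reference, percentile)
  out$labels <- cut_at_height(object$hclust, out$threshold)
  out$n_clusters <- max(out$labels)
  if (out$n_clusters == 1L) {
    warning("no significant structure at alpha = ", format(out$alpha))
  }
  out
}

#' @export
print.sigdendro <- function(x, ...) {
  cat("Significant clusters by dendrogram resampling\n")
  cat(sprintf("  %d sample profiles of %d variables; r = %d permutation replicates\n",
              x$n_s, x$n_v, x$r))
  cat(sprintf("  cut at the %.4g-th percentile of the reference (height %.4g, alpha = %.4g)\n",
              x$percentile, x$threshold, x$alpha))
  cat(sprintf("  %d cluster%s detected\n", x$n_clusters,
              if (x$n_clusters == 1L) "" else "s"))
  invisible(x)
}

#' @export
summary.sigdendro <- function(object, ...) {
  sizes <- as.integer(table(object$labels))
  qq <- qq_table(object)
  structure(
    list(n_s = object$n_s, n_v = object$n_v, r = object$r,
         percentile = object$percentile, alpha = object$alpha,
         threshold = object$threshold, n_clusters = object$n_clusters,
         sizes = sizes,
         median_observed = stats::median(object$D_o),
         median_expected = stats::median(object$reference$values),
         max_departure = max(abs(qq$observed - qq$expected))),
    class = "summary.sigdendro"
  )
}

#' @export
print.summary.sigdendro <- function(x, ...) {
  cat("Significant clusters by dendrogram resampling\n\n")
  cat(sprintf("Data: %d profiles x %d variables (row-standardized)\n",
              x$n_s, x$n_v))
  cat(sprintf("Reference: r = %d row-permutation replicates\n", x$r))
  cat(sprintf("Median normalized height: observed %.3f, expected %.3f\n",
              x$median_observed, x$median_expected))
  cat(sprintf("Max QQ departure from diagonal: %.3f\n\n", x$max_departure))
  cat(sprintf("Cut: percentile %.4g (alpha = %.4g) -> height %.4g\n",
              x$percentile, x$alpha, x$threshold))
  cat(sprintf("Clusters: %d, sizes %s\n", x$n_clusters,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Plot a significant-cluster fit
#'
#' `type = "qq"` draws the rank-paired observed vs expected normalized merge
#' heights with the diagonal and the cut threshold; an S-shaped departure
#' from the diagonal indicates real cluster structure. `type = "dendrogram"`
#' draws the observed dendrogram (normalized heights) with the cut height.
#'
#' @param x A fitted [sigdendro] object.
#' @param type `"qq"` (default) or `"dendrogram"`.
#' @param ... Further arguments passed to the underlying plot.
#' @return `x`, invisibly.
#' @export
plot.sigdendro <- function(x, type = c("qq", "dendrogram"), ...) {
  type <- match.arg(type)
  if (type == "qq") {
    qq <- qq_table(x)
    graphics::plot(qq$expected, qq$observed,
                   xlab = "Expected normalized height (reference)",
                   ylab = "Observed normalized height",
                   main = "Observed vs expected merge heights", ...)
    graphics::abline(0, 1, col = "grey50")
    graphics::abline(v = x$threshold, lty = 2, col = "red3")
  } else {
    hc <- x$hclust
    graphics::plot(hc, labels = FALSE, hang = -1,
                   ylab = "Normalized height",
                   main = sprintf("%d clusters at alpha = %.4g",
                                  x$n_clusters, x$alpha), ...)
    graphics::abline(h = x$threshold, lty = 2, col = "red3")
  }
  invisible(x)
}

#' @export
as.hclust.sigdendro <- function(x, ...) {
  x$hclust
}
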