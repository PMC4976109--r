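#' Independently reshuffle each row of a matrix
#'
#' Permutes the entries of every row independently and uniformly at random,
#' destroying any column (sample) structure while preserving each variable's
#' marginal distribution exactly — the no-cluster null used to build the
#' reference distribution of merge heights. Row and column ids are kept.
#' Uses the current RNG stream; call `set.seed()` for reproducibility.
#'
#' @param z Numeric matrix, variables in rows.
#' @return Matrix of the same shape with each row permuted.
#' @export
permute_rows <- function(z) {
  if (!is.matrix(z) || !is.numeric(z)) {
    stop("z must be a numeric matrix")
  }
  out <- z
  for (i in seq_len(nrow(z))) {
    out[i, ] <- z[i, sample.int(ncol(z))]
  }
  out
}

#' Permutation reference distribution of merge heights
#'
#' Builds the null expectation of dendrogram merge heights under "no clusters
#' in the data": `r` times, each row of the standardized matrix is reshuffled
#' independently, the columns are re-clustered (complete linkage, Euclidean
#' distance), and the sorted `sqrt(n_v)`-normalized heights are recorded. The
#' reference is the element-wise mean of the `r` sorted replicate vectors.
#'
#' @param z Row-standardized numeric matrix (variables x samples).
#' @param r Number of permutation replicates; 10 is typically sufficient
#'   (going to 1000 changes little) and is the default.
#' @param seed Optional integer seed applied before the first replicate. One
#'   RNG stream drives all replicates.
#' @return An object of class `"dendro_reference"`: a list with `values`
#'   (sorted numeric vector of length `n_s - 1`), `r`, `seed`, `n_v`, `n_s`,
#'   and `replicates` (the r x (n_s - 1) matrix of sorted normalized
#'   replicate heights).
#' @seealso [reference_percentile()], [qq_table()], [sigdendro()]
#' @export
reference_heights <- function(z, r = 10, seed = NULL) {
  if (!is.matrix(z) || !is.numeric(z)) {
    stop("z must be a numeric matrix")
  }
  if (!is.numeric(r) || length(r) != 1L || r < 1) {
    stop("r must be a count >= 1")
  }
  r <- as.integer(r)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  n_v <- nrow(z)
  n_s <- ncol(z)
  reps <- matrix(NA_real_, r, n_s - 1L)
  for (k in seq_len(r)) {
    hc <- agglomerate(permute_rows(z))
    reps[k, ] <- normalized_heights(hc, n_v)
  }
  structure(
    list(values = colMeans(reps), r = r, seed = seed,
         n_v = n_v, n_s = n_s, replicates = reps),
    class = "dendro_reference"
  )
}

#' @export
print.dendro_reference <- function(x, ...) {
  cat("Permutation reference distribution of merge heights\n")
  cat(sprintf("  %d heights (n_s = %d, n_v = %d), r = %d replicates\n",
              length(x$values), x$n_s, x$n_v, x$r))
  cat(sprintf("  range [%.4g, %.4g], median %.4g\n",
              min(x$values), max(x$values), stats::median(x$values)))
  invisible(x)
}

#' Percentile of the reference distribution
#'
#' The p-th percentile of the reference heights under linear interpolation
#' between order statistics ([stats::quantile()] type 7). Cutting the
#' observed dendrogram at this height detects clusters at significance level
#' `alpha = 1 - p/100`.
#'
#' @param ref A `"dendro_reference"` object or a numeric vector of heights.
#' @param p Percentile in (0, 100\].
#' @return The percentile height (a single number).
#' @export
reference_percentile <- function(ref, p) {
  values <- if (inherits(ref, "dendro_reference")) ref$values else ref
  if (!is.numeric(values) || length(values) == 0L) {
    stop("ref must hold at least one height")
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 100) {
    stop("p must be a percentile in (0, 100]")
  }
  stats::quantile(values, p / 100, type = 7, names = FALSE)
}

#' Rank-paired observed vs expected heights for a QQ plot
#'
#' Pairs the sorted observed heights with the sorted reference heights rank
#' by rank. Plotted against the diagonal this is the main diagnostic for
#' cluster structure: points on the diagonal mean no detectable clusters,
#' while an S-shape (small heights below the diagonal, large heights above)
#' signals real groups.
#'
#' @param observed Numeric vector of observed normalized heights, or a
#'   fitted [sigdendro] object.
#' @param reference A `"dendro_reference"` object or numeric vector of the
#'   same length.
#' @return A data frame with columns `rank`, `expected`, `observed`.
#' @export
qq_table <- function(observed, reference) {
  if (inherits(observed, "sigdendro")) {
    reference <- observed$reference
    observed <- observed$D_o
  }
  expected <- if (inherits(reference, "dendro_reference")) {
    reference$values
  } else {
    reference
  }
  if (length(observed) != length(expected)) {
    stop("observed and expected height vectors differ in length (",
         length(observed), " vs ", length(expected), ")")
  }
  data.frame(rank = seq_along(observed),
             expected = sort(expected),
             observed = sort(observed))
}
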