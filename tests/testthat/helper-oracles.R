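# Independent oracles used across the suite. These deliberately avoid the
# package's own linkage path.

# Naive O(n^3) complete-linkage agglomeration over the columns of z:
# repeatedly merge the pair of clusters with the smallest maximum pairwise
# Euclidean distance. Returns the sorted merge heights.
naive_complete_heights <- function(z) {
  d <- as.matrix(stats::dist(t(z)))
  clusters <- as.list(seq_len(ncol(z)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA_integer_, NA_integer_)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# Complete-linkage merge heights of exactly 3 columns, by direct case
# analysis (no agglomeration loop): first height is the smallest pairwise
# distance, second is the larger of the two distances from the merged pair
# to the remaining point.
three_point_heights <- function(z) {
  d <- as.matrix(stats::dist(t(z)))
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  dd <- d[pairs]
  first <- which.min(dd)
  merged <- pairs[first, ]
  rest <- setdiff(1:3, merged)
  c(dd[first], max(d[merged, rest]))
}

PERMS3 <- rbind(
  c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
)

# Exact expectation of the sorted normalized merge-height vector of a
# 2 x 3 matrix under independent uniform row permutations: enumerate all
# 6 x 6 = 36 permutation combinations.
exact_reference_2x3 <- function(z) {
  stopifnot(nrow(z) == 2L, ncol(z) == 3L)
  acc <- c(0, 0)
  for (i in 1:6) {
    for (j in 1:6) {
      zp <- rbind(z[1L, PERMS3[i, ]], z[2L, PERMS3[j, ]])
      acc <- acc + sort(three_point_heights(zp)) / sqrt(2)
    }
  }
  acc / 36
}

# All set partitions of 1..n as label vectors in canonical (restricted
# growth string) form.
all_partitions <- function(n) {
  grow <- function(labels) {
    if (length(labels) == n) {
      return(list(labels))
    }
    k <- max(labels)
    out <- list()
    for (v in seq_len(k + 1L)) {
      out <- c(out, grow(c(labels, v)))
    }
    out
  }
  grow(1L)
}

# Canonical relabeling: clusters numbered by first appearance.
canonical_labels <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

rand_matrix <- function(n_v, n_s) {
  matrix(stats::rnorm(n_v * n_s), n_v, n_s,
         dimnames = list(paste0("v", seq_len(n_v)),
                         paste0("s", seq_len(n_s))))
}
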