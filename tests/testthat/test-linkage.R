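test_that("agglomerate reproduces the hand-worked 3-point tree", {
  z <- cbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
  hc <- agglomerate(z)
  # d(a,b) = 5, d(b,c) = 5, d(a,c) = 10; the a-b tie resolves to the
  # smallest-index pair, and the final complete-linkage height is max(10, 5)
  expect_equal(hc$height, c(5, 10))
  expect_identical(hc$merge[1, ], c(-1L, -2L))
  expect_equal(attr(hc, "n_v"), 2L)

  zz <- cbind(a = c(1, 2), b = c(1, 2), c = c(5, 5))
  expect_equal(agglomerate(zz)$height[1], 0)

  expect_error(agglomerate(cbind(a = c(1, 2))), "at least 2")
})

test_that("complete-linkage heights are non-decreasing in merge order", {
  set.seed(20)
  for (i in 1:5) {
    hc <- agglomerate(rand_matrix(5, 20))
    expect_true(all(diff(hc$height) >= 0))
  }
})

test_that("linkage heights match the naive O(n^3) oracle on random matrices", {
  set.seed(21)
  for (i in 1:60) {
    z <- rand_matrix(sample(2:6, 1), sample(2:12, 1))
    expect_identical(sort(agglomerate(z)$height), naive_complete_heights(z))
  }
})

test_that("the multiset of merge heights is invariant to column permutation", {
  set.seed(22)
  z <- rand_matrix(4, 15)
  h0 <- sort(agglomerate(z)$height)
  for (i in 1:5) {
    expect_equal(sort(agglomerate(z[, sample(15)])$height), h0)
  }
})

test_that("normalized_heights divides by sqrt(n_v) and inverts cleanly", {
  z <- cbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
  hc <- agglomerate(z)
  expect_equal(normalized_heights(hc), c(5, 10) / sqrt(2))
  expect_equal(normalized_heights(hc) * sqrt(2), sort(hc$height))
  expect_error(normalized_heights(hc, n_v = 3), "does not match")

  # without provenance the caller supplies n_v
  hc2 <- stats::hclust(stats::dist(t(z)), "complete")
  expect_equal(normalized_heights(hc2, n_v = 16), sort(hc2$height) / 4)
  expect_error(normalized_heights(hc2), "n_v is required")
})

test_that("cut_at_height performs merges at or below h and numbers labels by size", {
  z <- cbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
  hc <- agglomerate(z)
  lab <- cut_at_height(hc, 7)
  expect_identical(unname(lab), c(1L, 1L, 2L))      # {a,b} is the larger cluster
  expect_identical(max(cut_at_height(hc, max(hc$height))), 1L)
  expect_identical(max(cut_at_height(hc, min(hc$height) - 1)), 3L)
  # boundary: a merge exactly at h is performed
  expect_identical(max(cut_at_height(hc, 5)), 2L)

  set.seed(23)
  zr <- rand_matrix(3, 25)
  hcr <- agglomerate(zr)
  ks <- vapply(seq(-1, max(hcr$height) + 1, length.out = 40),
               function(h) max(cut_at_height(hcr, h)), integer(1))
  expect_true(all(diff(ks) <= 0))  # cluster count non-increasing in h
  expect_identical(ks[1], 25L)
  expect_identical(ks[40], 1L)
  # count identity: 1 + #{heights > h}
  for (h in c(-1, quantile(hcr$height, c(.2, .5, .9)), max(hcr$height))) {
    expect_identical(max(cut_at_height(hcr, h)),
                     1L + sum(hcr$height > h))
  }
})

test_that("newick export preserves leaves and the worked topology", {
  z <- cbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
  txt <- to_newick(agglomerate(z))
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  # a and b must be sisters: ((a,b),c)
  expect_true(ape::is.monophyletic(phy, c("a", "b")))

  z2 <- cbind(p = c(0, 0), q = c(1, 0))
  phy2 <- ape::read.tree(text = to_newick(agglomerate(z2)))
  expect_setequal(phy2$tip.label, c("p", "q"))

  tf <- withr::local_tempfile(fileext = ".nwk")
  to_newick(agglomerate(z), file = tf)
  expect_setequal(ape::read.tree(tf)$tip.label, c("a", "b", "c"))
})
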