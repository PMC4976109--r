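test_that("the pseudo-F matches a hand-worked 1-D example", {
  # points (0, 1, 9, 10), split {0,1} | {9,10}:
  # S1 = 25 + 16 + 16 + 25 = 82, S2 = 0.5 + 0.5 = 1,
  # F = (81 / 1) / ((3/2) * 2^2 - 1) = 81 / 5 = 16.2
  z <- matrix(c(0, 1, 9, 10), 1, 4)
  res <- beale_f(z, c(1, 1, 2, 2))
  expect_equal(res$S1, 82)
  expect_equal(res$S2, 1)
  expect_equal(res$statistic, 16.2)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 2)
  expect_equal(res$p.value, pf(16.2, 1, 2, lower.tail = FALSE))
})

test_that("perfectly tight clusters give infinite F with p = 0", {
  z <- matrix(rep(c(0, 10), each = 3), 1, 6)
  res <- beale_f(z, rep(1:2, each = 3))
  expect_identical(res$statistic, Inf)
  expect_identical(res$p.value, 0)
})

test_that("a split that explains nothing gives F = 0", {
  # both cluster means equal the grand mean
  z <- matrix(c(1, -1, 1, -1), 1, 4)
  res <- beale_f(z, c(1, 1, 2, 2))
  expect_equal(res$statistic, 0)
})

test_that("the pseudo-F is invariant to adding a constant to the data", {
  set.seed(70)
  z <- rand_matrix(4, 30)
  lab <- sample(1:3, 30, replace = TRUE)
  expect_equal(beale_f(z + 100, lab)$statistic, beale_f(z, lab)$statistic)
})

test_that("beale_f validates its inputs", {
  z <- rand_matrix(2, 6)
  expect_error(beale_f(z, rep(1, 6)), "at least 2 clusters")
  expect_error(beale_f(z, 1:3), "one entry per sample")
  expect_silent(beale_f(z, c(1, 1, 2, 2, 3, 3)))
  expect_error(beale_f(z, 1:6), "k < n_s")
})

test_that("within-cluster SS is non-increasing along nested dendrogram cuts", {
  set.seed(71)
  z <- standardize_rows(rand_matrix(5, 60))
  hc <- agglomerate(z)
  scan <- beale_select(hc, z, k_max = 59)
  # recompute S2 independently from each k-group cut
  ss <- vapply(scan$k, function(k) {
    g <- stats::cutree(hc, k = k)
    sum(vapply(split(seq_len(60), g), function(j) {
      sum((z[, j, drop = FALSE] - rowMeans(z[, j, drop = FALSE]))^2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ss) <= 1e-8))
  # the scan's F values rebuilt from the independent S2 agree
  S1 <- sum((z - rowMeans(z))^2)
  denom <- ((60 - 1) / (60 - scan$k)) * scan$k^(2 / 5) - 1
  expect_equal(scan$f, ((S1 - ss) / ss) / denom, tolerance = 1e-8)
})

test_that("the scan is deterministic and respects its cap", {
  set.seed(72)
  z <- standardize_rows(rand_matrix(4, 40))
  hc <- agglomerate(z)
  s1 <- beale_select(hc, z, alpha = 0.05, k_max = 10)
  s2 <- beale_select(hc, z, alpha = 0.05, k_max = 10)
  expect_identical(s1$f, s2$f)
  expect_identical(max(s1$k), 10L)
  s3 <- beale_select(hc, z, alpha = 0.05, k_max = 2)
  expect_true(s3$k_selected %in% c(1L, 2L))
  expect_output(print(s1), "Beale pseudo-F scan")
})

test_that("strong two-cluster structure yields a large significant F at k = 2", {
  set.seed(73)
  x <- cbind(matrix(rnorm(8 * 50, -5), 8), matrix(rnorm(8 * 50, 5), 8))
  z <- standardize_rows(x)
  scan <- beale_select(agglomerate(z), z, alpha = 0.05)
  i2 <- which(scan$k == 2L)
  expect_lt(scan$p.value[i2], 1e-6)
  # k = 2 dominates every moderate alternative; only the near-singleton
  # end of the scan (within-SS collapsing to 0) can exceed it
  expect_true(all(scan$f[i2] >= scan$f[scan$k <= 50]))
  expect_gt(scan$k_selected, 1L)
})

test_that("null data rarely supports a small significant cluster number", {
  set.seed(74)
  picks <- replicate(30, {
    z <- standardize_rows(generate_null(3, 80))
    beale_select(agglomerate(z), z, alpha = 0.001, k_max = 20)$k_selected
  })
  # with the scan capped well below n_s, most null datasets keep one cluster
  expect_gt(mean(picks == 1L), 0.5)
})
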