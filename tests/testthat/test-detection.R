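test_that("alpha is the complement of the percentile probability", {
  expect_equal(alpha_from_percentile(95), 0.05)
  expect_equal(alpha_from_percentile(99.9), 0.001)
  expect_equal(alpha_from_percentile(100), 0)
  expect_error(alpha_from_percentile(0), "percentile")
  expect_error(alpha_from_percentile(101), "percentile")
})

test_that("the fit is deterministic given (data, percentile, r, seed)", {
  set.seed(40)
  x <- rand_matrix(5, 40)
  f1 <- sigdendro(x, percentile = 95, r = 5, seed = 7)
  f2 <- sigdendro(x, percentile = 95, r = 5, seed = 7)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$threshold, f2$threshold)
  expect_identical(f1$D_o, f2$D_o)
  expect_identical(f1$alpha, 1 - 95 / 100)
  expect_identical(f1$n_clusters, 1L + sum(f1$D_o > f1$threshold))
})

test_that("cluster count is non-increasing in the percentile", {
  set.seed(41)
  sim <- generate_dataset(n_c = 4, n_v = 6, n_s = 120, sigma = 3, seed = 42)
  fit <- sigdendro(sim$x, percentile = 90, r = 10, seed = 8)
  ks <- vapply(c(90, 95, 97.5, 99, 99.9), function(p) {
    suppressWarnings(recut(fit, p)$n_clusters)
  }, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("two samples always form one cluster, with a warning", {
  x <- rbind(v1 = c(0, 3), v2 = c(1, -2), v3 = c(5, 0))
  expect_warning(fit <- sigdendro(x, percentile = 95, r = 4, seed = 1),
                 "no significant structure")
  expect_identical(fit$n_clusters, 1L)
})

test_that("well-separated clusters are recovered exactly at the 95th percentile", {
  set.seed(43)
  x <- cbind(matrix(rnorm(8 * 100, 0), 8), matrix(rnorm(8 * 100, 10), 8))
  colnames(x) <- paste0("s", 1:200)
  rownames(x) <- paste0("v", 1:8)
  truth <- rep(1:2, each = 100)
  fit <- sigdendro(x, percentile = 95, r = 10, seed = 44)
  expect_identical(fit$n_clusters, 2L)
  expect_equal(jaccard_similarity(truth, fit$labels), 1)
})

test_that("recut reuses the reference and preserves the alpha identity", {
  set.seed(45)
  sim <- generate_dataset(n_c = 3, n_v = 5, n_s = 90, sigma = 5, seed = 46)
  fit <- sigdendro(sim$x, percentile = 95, r = 5, seed = 47)
  re <- recut(fit, 97.5)
  expect_identical(re$reference$values, fit$reference$values)
  expect_identical(re$alpha, 1 - 97.5 / 100)
  expect_identical(recut(re, 95)$labels, fit$labels)
  expect_gte(reference_percentile(fit$reference, 97.5), fit$threshold)
})

test_that("print, summary, plot and label export work end to end", {
  set.seed(48)
  sim <- generate_dataset(n_c = 2, n_v = 6, n_s = 60, sigma = 8, seed = 49)
  fit <- sigdendro(sim$x, percentile = 95, r = 5, seed = 50)
  expect_output(print(fit), "clusters detected")
  s <- summary(fit)
  expect_output(print(s), "Median normalized height")
  expect_identical(sum(s$sizes), 60L)
  expect_s3_class(as.hclust(fit), "hclust")

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_labels(fit, tf)
  tab <- utils::read.delim(tf)
  expect_identical(nrow(tab), 60L)
  expect_identical(sort(unique(tab$cluster)), seq_len(fit$n_clusters))

  pf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(pf)
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, type = "dendrogram"))
  grDevices::dev.off()
  expect_true(file.exists(pf))
})

test_that("under the null the exceedance fraction tracks 1 - p/100", {
  set.seed(51)
  m <- 40
  frac <- vapply(seq_len(m), function(i) {
    z <- standardize_rows(generate_null(5, 150))
    D_o <- normalized_heights(agglomerate(z))
    thr <- reference_percentile(reference_heights(z, r = 10), 95)
    mean(D_o > thr)
  }, numeric(1))
  se <- sd(frac) / sqrt(m)
  expect_lt(abs(mean(frac) - 0.05), 3 * se + 0.01)
})
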