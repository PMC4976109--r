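#' Simulation study of the false-positive rate on one-cluster data
#'
#' Generates `n_datasets` datasets with no cluster structure (see
#' [generate_null()]), runs the detection procedure at each percentile, and
#' records the proportion of wrong clusters `PWC = (n_detected - 1) /
#' (n_s - 1)`. Under the null the mean PWC at percentile `p` should match
#' the nominal `alpha = 1 - p/100` — the calibration property of the method.
#' Optionally runs the Beale pseudo-F scan on every dataset.
#'
#' @param n_datasets Number of simulated datasets.
#' @param percentiles Reference percentiles at which to cut.
#' @param r Permutation replicates per dataset.
#' @param seed Master seed; per-dataset seeds are derived from it so the
#'   study is fully reproducible.
#' @param n_v_range,n_s_range Inclusive ranges from which each dataset's
#'   variable and sample counts are drawn uniformly. The defaults keep the
#'   study desk-sized; widen `n_s_range` for a heavier study.
#' @param sigma Common sd of the null draws (immaterial after
#'   standardization).
#' @param beale Run [beale_select()] per dataset?
#' @param beale_alphas Significance levels at which the Beale selection is
#'   evaluated (one scan; the max-F rule is applied at each level).
#' @param beale_k_max Beale scan cap.
#' @return An object of class `"sigdendro_study"`: a list with `detection`
#'   (one row per dataset x percentile: `dataset, seed, n_v, n_s,
#'   percentile, alpha, n_detected, pwc`) and `beale` (one row per dataset
#'   x alpha: `dataset, n_v, n_s, alpha, k_selected, one_cluster,
#'   pwc_capped`, or `NULL` when `beale = FALSE`).
#' @seealso [run_tpr_study()], [summarize_study()]
#' @export
run_fpr_study <- function(n_datasets = 200, percentiles = c(95, 97.5, 99, 99.5, 99.9),
                          r = 10, seed = NULL,
                          n_v_range = c(2, 20), n_s_range = c(300, 1500),
                          sigma = 1, beale = TRUE,
                          beale_alphas = c(0.05, 0.001), beale_k_max = 500) {
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ds_seeds <- sample.int(2147483647L, n_datasets)
  det <- vector("list", n_datasets)
  bea <- if (beale) vector("list", n_datasets) else NULL
  for (i in seq_len(n_datasets)) {
    set.seed(ds_seeds[i])
    n_v <- sample(n_v_range[1]:n_v_range[2], 1L)
    n_s <- sample(n_s_range[1]:n_s_range[2], 1L)
    x <- generate_null(n_v, n_s, sigma)
    z <- standardize_rows(x)
    hc <- agglomerate(z)
    hc$height <- hc$height / sqrt(n_v)
    D_o <- sort(hc$height)
    ref <- reference_heights(z, r = r)
    n_det <- vapply(percentiles, function(p) {
      1L + sum(D_o > reference_percentile(ref, p))
    }, integer(1))
    det[[i]] <- data.frame(
      dataset = i, seed = ds_seeds[i], n_v = n_v, n_s = n_s,
      percentile = percentiles,
      alpha = 1 - percentiles / 100,
      n_detected = n_det,
      pwc = (n_det - 1) / (n_s - 1)
    )
    if (beale) {
      scan <- beale_select(hc, z, alpha = min(beale_alphas),
                           k_max = beale_k_max)
      best <- which.max(scan$f)
      k_sel <- vapply(beale_alphas, function(a) {
        if (scan$p.value[best] < a) scan$k[best] else 1L
      }, integer(1))
      bea[[i]] <- data.frame(
        dataset = i, n_v = n_v, n_s = n_s, alpha = beale_alphas,
        k_selected = k_sel,
        one_cluster = k_sel == 1L,
        pwc_capped = (k_sel - 1) / (beale_k_max - 1)
      )
    }
  }
  structure(
    list(detection = do.call(rbind, det),
         beale = if (beale) do.call(rbind, bea) else NULL,
         mode = "fpr", seed = seed, r = r),
    class = "sigdendro_study"
  )
}

#' Simulation study of detection accuracy on clustered data
#'
#' Generates clustered datasets over a grid of scenarios — per dataset,
#' `n_c`, `n_v`, `n_s` drawn uniformly from their ranges and the profile
#' separation `sigma` drawn uniformly from `sigmas` — then runs the
#' detection procedure at each percentile and scores it against the
#' generating labels with the number of detected clusters, PWC, the
#' Cramer's V index and the average Jaccard similarity. Optionally also
#' selects a cluster number per dataset with the capped Beale scan.
#'
#' @inheritParams run_fpr_study
#' @param sigmas Candidate profile-separation sds.
#' @param n_c_range Inclusive range of true cluster counts.
#' @param min_cluster_size Minimum cluster size in the generator.
#' @param beale_alpha Significance level of the Beale selection.
#' @return A `"sigdendro_study"` list with `detection` (one row per dataset
#'   x percentile: scenario columns plus `n_detected, exact, pwc,
#'   cramers_v, jaccard`; `cramers_v` is `NA` when either partition has a
#'   single cluster, where the index is undefined) and `beale` (one row per
#'   dataset: `k_selected, exact, pwc_capped`).
#' @export
run_tpr_study <- function(n_datasets = 300, sigmas = c(2, 5, 10),
                          percentiles = c(95, 97.5, 99, 99.5, 99.9),
                          r = 10, seed = NULL,
                          n_c_range = c(2, 20), n_v_range = c(2, 20),
                          n_s_range = c(300, 1500),
                          min_cluster_size = 2L, beale = TRUE,
                          beale_alpha = 0.05, beale_k_max = 500) {
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ds_seeds <- sample.int(2147483647L, n_datasets)
  det <- vector("list", n_datasets)
  bea <- if (beale) vector("list", n_datasets) else NULL
  for (i in seq_len(n_datasets)) {
    set.seed(ds_seeds[i])
    n_c <- sample(n_c_range[1]:n_c_range[2], 1L)
    n_v <- sample(n_v_range[1]:n_v_range[2], 1L)
    n_s <- sample(n_s_range[1]:n_s_range[2], 1L)
    sigma <- sample(sigmas, 1L)
    sim <- generate_dataset(n_c, n_v, n_s, sigma,
                            min_cluster_size = min_cluster_size)
    z <- standardize_rows(sim$x)
    hc <- agglomerate(z)
    hc$height <- hc$height / sqrt(n_v)
    D_o <- sort(hc$height)
    ref <- reference_heights(z, r = r)
    rows <- lapply(percentiles, function(p) {
      thr <- reference_percentile(ref, p)
      labels <- cut_at_height(hc, thr)
      n_det <- max(labels)
      cv <- if (n_det >= 2L && n_c >= 2L) {
        cramers_v(sim$labels, labels)
      } else {
        NA_real_
      }
      data.frame(
        dataset = i, seed = ds_seeds[i], n_c = n_c, n_v = n_v, n_s = n_s,
        sigma = sigma, percentile = p, alpha = 1 - p / 100,
        n_detected = n_det, exact = n_det == n_c,
        pwc = pwc(n_det, n_c, n_s),
        cramers_v = cv,
        jaccard = jaccard_similarity(sim$labels, labels)
      )
    })
    det[[i]] <- do.call(rbind, rows)
    if (beale) {
      scan <- beale_select(hc, z, alpha = beale_alpha,
                           k_max = beale_k_max)
      bea[[i]] <- data.frame(
        dataset = i, n_c = n_c, n_v = n_v, n_s = n_s, sigma = sigma,
        alpha = beale_alpha, k_selected = scan$k_selected,
        exact = scan$k_selected == n_c,
        pwc_capped = pwc(scan$k_selected, n_c, n_s,
                         denominator_cap = beale_k_max)
      )
    }
  }
  structure(
    list(detection = do.call(rbind, det),
         beale = if (beale) do.call(rbind, bea) else NULL,
         mode = "tpr", seed = seed, r = r),
    class = "sigdendro_study"
  )
}

#' @export
print.sigdendro_study <- function(x, ...) {
  cat(sprintf("Simulation study (%s): %d dataset rows x %d percentiles\n",
              x$mode, length(unique(x$detection$dataset)),
              length(unique(x$detection$percentile))))
  if (!is.null(x$beale)) cat("  includes Beale pseudo-F selections\n")
  invisible(x)
}

#' Summarize simulation records
#'
#' Grouped means, Monte-Carlo standard errors, medians and quartiles of the
#' numeric columns of a study record table. Logical columns (e.g. `exact`,
#' `one_cluster`) are averaged into fractions.
#'
#' @param records A data frame of per-dataset records — e.g. the
#'   `detection` or `beale` component of a [run_fpr_study()] /
#'   [run_tpr_study()] result.
#' @param group_by Character vector of record columns to group on (empty for
#'   overall summaries).
#' @param columns Columns to summarize; defaults to all numeric/logical
#'   columns not used for grouping or bookkeeping (`dataset`, `seed`).
#' @return A data frame with one row per group x summarized column:
#'   grouping columns, `variable`, `n`, `mean`, `se`, `q25`, `median`,
#'   `q75`.
#' @export
summarize_study <- function(records, group_by = character(), columns = NULL) {
  if (inherits(records, "sigdendro_study")) {
    records <- records$detection
  }
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data frame")
  }
  if (!all(group_by %in% names(records))) {
    stop("unknown grouping column(s): ",
         paste(setdiff(group_by, names(records)), collapse = ", "))
  }
  if (is.null(columns)) {
    skip <- c(group_by, "dataset", "seed")
    columns <- names(records)[vapply(records, function(v) {
      is.numeric(v) || is.logical(v)
    }, logical(1))]
    columns <- setdiff(columns, skip)
  }
  groups <- if (length(group_by) == 0L) {
    list(`all` = records)
  } else {
    split(records, records[group_by], drop = TRUE)
  }
  out <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    do.call(rbind, lapply(columns, function(col) {
      v <- as.numeric(g[[col]])
      v <- v[!is.na(v)]
      stats_row <- data.frame(
        variable = col, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        q25 = if (length(v)) stats::quantile(v, 0.25, names = FALSE) else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_,
        q75 = if (length(v)) stats::quantile(v, 0.75, names = FALSE) else NA_real_,
        stringsAsFactors = FALSE
      )
      if (length(group_by)) {
        cbind(g[1L, group_by, drop = FALSE], stats_row, row.names = NULL)
      } else {
        stats_row
      }
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
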