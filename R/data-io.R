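#' Read a profile matrix from delimited text
#'
#' Reads a rectangular numeric table with one header row and one id column
#' into the variables-by-samples matrix used throughout the package: rows are
#' variables (e.g. biomarkers, genes), columns are sample units, and each
#' column is the profile of one sample.
#'
#' @param path Path to a delimited text file. The first column holds ids for
#'   the entities in rows; the header row holds ids for the entities in
#'   columns.
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @param samples_in Either `"columns"` (default; the file is already
#'   variables x samples) or `"rows"` (the file is samples x variables and is
#'   transposed on read).
#' @return A numeric matrix with variables in rows and samples in columns,
#'   with unique `rownames`/`colnames` and no missing values.
#' @details Missing values are rejected rather than imputed: callers must
#'   pre-impute. Non-numeric cells and duplicated ids are reported by name.
#' @seealso [standardize_rows()], [write_cluster_labels()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("v", 1:3), paste0("s", 1:4)))
#' write.table(data.frame(variable = rownames(m), m, check.names = FALSE),
#'             tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' x <- read_profile_matrix(tf)
#' dim(x)
read_profile_matrix <- function(path, delimiter = "\t",
                                samples_in = c("columns", "rows")) {
  samples_in <- match.arg(samples_in)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("expected an id column plus at least one data column in ", path)
  }
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  if (anyDuplicated(row_ids)) {
    stop("duplicated ids in first column: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicated ids in header: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  missing <- is.na(cells) | trimws(cells) %in% c("", "NA", "NaN")
  if (any(missing)) {
    idx <- which(missing, arr.ind = TRUE)[1L, ]
    stop("missing value at row '", row_ids[idx[1L]], "', column '",
         col_ids[idx[2L]], "'; impute missing data before analysis")
  }
  values <- suppressWarnings(as.numeric(cells))
  bad <- is.na(values)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(cells)), arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", cells[idx[1L], idx[2L]], "' at row '",
         row_ids[idx[1L]], "', column '", col_ids[idx[2L]], "'")
  }
  x <- matrix(values, nrow = nrow(cells),
              dimnames = list(row_ids, col_ids))
  if (samples_in == "rows") {
    x <- t(x)
  }
  validate_profile_matrix(x)
  x
}

#' @keywords internal
validate_profile_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("profile data must be a numeric matrix (variables x samples)")
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 variables and 2 samples; got ",
         nrow(x), " x ", ncol(x))
  }
  if (anyNA(x)) {
    stop("matrix contains missing values; impute before analysis")
  }
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x))) {
    stop("duplicated variable (row) ids")
  }
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) {
    stop("duplicated sample (column) ids")
  }
  invisible(x)
}

#' Standardize the rows of a profile matrix
#'
#' Centers and scales each variable (row) so that Euclidean distances between
#' sample profiles weight all variables equally. This is the mandatory first
#' step of the significant-cluster procedure.
#'
#' @param x Numeric matrix, variables in rows.
#' @param method `"mean_sd"` (default): subtract the row mean and divide by
#'   the sample standard deviation (divisor `n_s - 1`). `"trimmed"`: center
#'   by the symmetric trimmed mean and scale by the standard deviation of the
#'   retained (untrimmed) observations — a robust variant useful when
#'   profiles carry outliers.
#' @param trim_fraction Fraction trimmed from each tail for
#'   `method = "trimmed"`, in \[0, 0.25\]. Default 0.05.
#' @return The standardized matrix, with attribute `standardized = TRUE`.
#' @details Constant rows have no scale and are an error; remove or perturb
#'   zero-variance variables first. `mean_sd` standardization is idempotent.
#' @export
#' @examples
#' z <- standardize_rows(rbind(a = c(1, 2, 3), b = c(10, 20, 60)))
#' rowMeans(z)          # ~ 0
#' apply(z, 1, sd)      # 1
standardize_rows <- function(x, method = c("mean_sd", "trimmed"),
                             trim_fraction = 0.05) {
  method <- match.arg(method)
  validate_profile_matrix(x)
  if (method == "trimmed" &&
      (!is.numeric(trim_fraction) || length(trim_fraction) != 1L ||
       trim_fraction < 0 || trim_fraction > 0.25)) {
    stop("trim_fraction must be a single number in [0, 0.25]")
  }
  n <- ncol(x)
  if (method == "mean_sd") {
    ctr <- rowMeans(x)
    scl <- apply(x, 1L, stats::sd)
  } else {
    k <- floor(trim_fraction * n)
    ctr <- numeric(nrow(x))
    scl <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      kept <- sort(x[i, ])
      if (k > 0L) kept <- kept[(k + 1L):(n - k)]
      ctr[i] <- mean(kept)
      scl[i] <- stats::sd(kept)
    }
  }
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero)) {
    ids <- rownames(x)[zero]
    if (is.null(ids)) ids <- which(zero)
    stop("zero variance in row(s): ", paste(ids, collapse = ", "))
  }
  z <- (x - ctr) / scl
  attr(z, "standardized") <- TRUE
  z
}

#' Write cluster labels to a delimited file
#'
#' Writes a two-column tab-separated file (`sample_id`, `cluster`) with a
#' header row. Cluster labels are consecutive integers starting at 1,
#' numbered by decreasing cluster size with ties broken by the first sample
#' in which a cluster appears.
#'
#' @param labels A fitted [sigdendro] object, or an integer vector of cluster
#'   labels (optionally named by sample id).
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_cluster_labels <- function(labels, path) {
  if (inherits(labels, "sigdendro")) {
    labels <- labels$labels
  }
  if (length(labels) == 0L) {
    stop("no labels to write")
  }
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("s", seq_along(labels))
  out <- data.frame(sample_id = ids,
                    cluster = relabel_by_size(labels),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

# Renumber cluster labels 1..k by decreasing size; ties broken by the
# first-appearing sample of each cluster.
#' @keywords internal
relabel_by_size <- function(labels) {
  f <- factor(labels, levels = unique(labels))  # levels in appearance order
  sizes <- tabulate(f)
  ord <- order(-sizes, seq_along(sizes))
  new <- integer(nlevels(f))
  new[ord] <- seq_along(ord)
  out <- new[as.integer(f)]
  names(out) <- names(labels)
  out
}
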