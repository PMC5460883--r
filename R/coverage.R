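#' Per-site coverage matrix
#'
#' Container for per-site read depth on one chromosome across samples, the
#' observable substrate of the expression HMM. Positions are 1-based and
#' strictly increasing; depth holds one row per position and one column per
#' sample, all entries non-negative (raw or normalized reads).
#'
#' @param chrom Chromosome name (length-1 character).
#' @param positions Integer vector of 1-based site coordinates, strictly
#'   increasing.
#' @param depth Numeric matrix, `length(positions)` rows by one column per
#'   sample; all entries must be `>= 0`.
#' @param samples Character vector of sample identifiers (defaults to the
#'   column names of `depth`).
#' @return An object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(chrom, positions, depth, samples = colnames(depth)) {
  depth <- as.matrix(depth)
  positions <- as.integer(positions)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(depth)))
  stopifnot(length(chrom) == 1L, nrow(depth) == length(positions),
            length(samples) == ncol(depth))
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing within a chromosome")
  if (anyNA(depth) || !is.numeric(depth))
    stop("depth must be numeric with no missing values")
  if (any(depth < 0)) stop("depth entries must be non-negative")
  colnames(depth) <- samples
  structure(list(chrom = as.character(chrom), positions = positions,
                 samples = as.character(samples), depth = depth),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %s, %d sites x %d samples\n",
              x$chrom, length(x$positions), length(x$samples)))
  if (length(x$positions)) {
    cat(sprintf("  positions %d..%d\n", min(x$positions), max(x$positions)))
    cat("  samples:", paste(x$samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$depth)

#' Read a samtools-depth style TSV into coverage matrices
#'
#' Expects columns `chrom`, `pos`, then one depth column per sample, no
#' header (the layout `samtools depth` emits). Sites absent from the file
#' (samtools omits zero-depth sites by default) can be filled in as depth 0
#' over an explicit window via `fill_range`.
#'
#' @param path Path to the TSV.
#' @param sample_names Identifiers for the depth columns. If `NULL`, columns
#'   are named `sample1..k`.
#' @param fill_range Optional `c(start, end)`: positions inside this window
#'   missing from the file are inserted with depth 0 (only meaningful for a
#'   single-chromosome file).
#' @return A named list of [coverage_matrix] objects, one per chromosome, in
#'   order of first appearance. An empty file yields an empty list.
#' @export
read_depth_tsv <- function(path, sample_names = NULL, fill_range = NULL) {
  if (file.size(path) == 0) return(structure(list(), names = character()))
  probe <- utils::read.table(path, sep = "\t", header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE)
  if (ncol(probe) < 3L) stop("depth TSV needs at least chrom, pos and one depth column")
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "integer",
                                     rep("numeric", ncol(probe) - 2L)),
                      stringsAsFactors = FALSE),
    error = function(e) stop("non-numeric depth column in ", path))
  dep <- as.matrix(df[, -(1:2), drop = FALSE])
  k <- ncol(dep)
  if (is.null(sample_names)) sample_names <- paste0("sample", seq_len(k))
  if (length(sample_names) != k)
    stop("sample_names has length ", length(sample_names), " but file has ", k,
         " depth columns")
  chroms <- df[[1L]]
  out <- lapply(split(seq_len(nrow(df)), factor(chroms, levels = unique(chroms))),
                function(i) {
    pos <- df[[2L]][i]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions not strictly increasing within chromosome ", chroms[i[1L]])
    cm <- coverage_matrix(chroms[i[1L]], pos, dep[i, , drop = FALSE], sample_names)
    if (!is.null(fill_range)) cm <- fill_missing_sites(cm, fill_range) else cm
  })
  out
}

## samtools depth convention: absent site inside the window means depth 0
fill_missing_sites <- function(cm, range) {
  range <- as.integer(range)
  full <- seq.int(range[1L], range[2L])
  dep <- matrix(0, length(full), length(cm$samples))
  hit <- cm$positions >= range[1L] & cm$positions <= range[2L]
  dep[match(cm$positions[hit], full), ] <- cm$depth[hit, , drop = FALSE]
  coverage_matrix(cm$chrom, full, dep, cm$samples)
}

#' Write a coverage matrix as a depth TSV
#'
#' Inverse of [read_depth_tsv()]: chrom, 1-based pos, one depth column per
#' sample, tab-separated, no header.
#'
#' @param cm A [coverage_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(cm, path) {
  df <- data.frame(chrom = cm$chrom, pos = cm$positions, cm$depth,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Quantile normalize coverage across samples
#'
#' Forces every sample's per-site coverage distribution on one chromosome to
#' the common reference distribution (the cross-sample mean of order
#' statistics), so that coverage per site has the same mean and variance in
#' every sample — the normalization applied per chromosome and per tissue
#' before HMM decoding. Tied values within a sample receive the mean of the
#' order-statistic targets over their rank range, which keeps the transform
#' deterministic. `method = "zscore"` instead matches only mean and variance
#' (each column rescaled to the grand column mean and pooled variance), a
#' strictly weaker reading kept as an alternative.
#'
#' @param cm A [coverage_matrix] whose columns are all samples of one tissue
#'   (reference replicates included).
#' @param method `"quantile"` (default, full distribution matching) or
#'   `"zscore"` (mean/variance only).
#' @return A [coverage_matrix] of normalized depth. With a single sample the
#'   input is returned unchanged.
#' @export
quantile_normalize <- function(cm, method = c("quantile", "zscore")) {
  method <- match.arg(method)
  x <- cm$depth
  if (ncol(x) < 2L || nrow(x) == 0L) return(cm)
  if (method == "quantile") {
    target <- rowMeans(apply(x, 2L, sort.int, method = "quick"))
    norm <- apply(x, 2L, function(col) {
      v <- numeric(length(col))
      v[order(col)] <- target
      # ties: mean of the targets assigned across the tied rank range
      stats::ave(v, col, FUN = mean)
    })
  } else {
    m <- mean(colMeans(x))
    v <- mean(apply(x, 2L, stats::var))
    norm <- apply(x, 2L, function(col) {
      sdc <- stats::sd(col)
      if (sdc == 0) rep(m, length(col)) else (col - mean(col)) / sdc * sqrt(v) + m
    })
  }
  norm[norm < 0] <- 0
  coverage_matrix(cm$chrom, cm$positions, norm, cm$samples)
}

#' Summarize reference replicates per site
#'
#' Per-site mean and unbiased (n-1) variance of the reference replicate
#' columns, the baseline against which every sample strain is compared.
#'
#' @param cm A [coverage_matrix] restricted to the reference replicates
#'   (typically 3 columns; at least 2 unless a variance floor is supplied).
#' @param samples Optional subset of column names to treat as replicates.
#' @param var_floor Optional variance to assume when only one replicate is
#'   available (otherwise a single replicate is an error).
#' @return An object of class `reference_summary`: list with `chrom`,
#'   `positions`, `mu`, `sigma2`, `n_reps`.
#' @export
summarize_reference <- function(cm, samples = NULL, var_floor = NULL) {
  dep <- cm$depth
  if (!is.null(samples)) {
    miss <- setdiff(samples, cm$samples)
    if (length(miss)) stop("unknown reference samples: ", paste(miss, collapse = ", "))
    dep <- dep[, samples, drop = FALSE]
  }
  n <- ncol(dep)
  mu <- rowMeans(dep)
  if (n >= 2L) {
    sigma2 <- rowSums((dep - mu)^2) / (n - 1L)
  } else if (!is.null(var_floor)) {
    sigma2 <- rep(var_floor, nrow(dep))
  } else {
    stop("variance undefined with a single reference replicate; ",
         "supply var_floor or >= 2 replicates")
  }
  structure(list(chrom = cm$chrom, positions = cm$positions,
                 mu = mu, sigma2 = sigma2, n_reps = n),
            class = "reference_summary")
}

#' @export
print.reference_summary <- function(x, ...) {
  cat(sprintf("reference_summary: %s, %d sites, %d replicates\n",
              x$chrom, length(x$positions), x$n_reps))
  invisible(x)
}
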