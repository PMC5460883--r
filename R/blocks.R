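#' Call expression blocks from per-site state codes
#'
#' Maximal runs of identical non-stable state spanning at least `min_len`
#' contiguous bp. Contiguity is strict in genomic coordinates: a single
#' interrupting site of another state, or a gap in the site track, splits a
#' run (gaps in the depth table count as stable sites).
#'
#' @param states Integer state codes (0 = down, 1 = stable, 2 = up), or an
#'   `expr_hmm` fit / `state_track` from which states and positions are
#'   taken.
#' @param positions Site coordinates (required when `states` is a bare
#'   vector).
#' @param min_len Minimum block length in bp (default 50: a run of 50
#'   contiguous sites qualifies, 49 does not).
#' @param chrom Chromosome label for the output (taken from the fit when
#'   available).
#' @return A data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `state`, `length` (bp), one row per block, sorted by start.
#' @export
call_blocks <- function(states, positions = NULL, min_len = 50,
                        chrom = NA_character_) {
  if (inherits(states, "expr_hmm") || inherits(states, "state_track")) {
    positions <- states$positions
    if (!is.null(states$chrom)) chrom <- states$chrom
    states <- states$state
  }
  if (is.null(positions)) positions <- seq_along(states)
  stopifnot(length(states) == length(positions))
  if (!length(states))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      state = integer(), length = integer()))
  if (is.unsorted(positions, strictly = TRUE)) stop("positions must be sorted")
  ## new run whenever the state changes or the coordinate track has a gap
  brk <- c(TRUE, diff(positions) != 1L | diff(states) != 0L)
  grp <- cumsum(brk)
  st <- states[brk]
  start <- positions[brk]
  end <- positions[c(brk[-1L], TRUE)]
  len <- end - start + 1L
  keep <- st != 1L & len >= min_len
  data.frame(chrom = rep(chrom, sum(keep)), start = start[keep],
             end = end[keep], state = st[keep], length = len[keep],
             row.names = NULL)
}

#' Write expression blocks as BED6
#'
#' 0-based half-open intervals; the state name goes in the name column and
#' the block length in the score column.
#'
#' @param blocks Data.frame from [call_blocks()].
#' @param path Output path.
#' @param strand Strand character for column 6 (default ".").
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path, strand = ".") {
  nm <- c("down", "stable", "up")[blocks$state + 1L]
  df <- data.frame(blocks$chrom, blocks$start - 1L, blocks$end, nm,
                   blocks$length, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gene-level upregulation calls from expression blocks
#'
#' A gene (or gene fragment — for chimeras, the duplicated 5' or 3' segment)
#' is called upregulated when at least 50% of its annotated exon sequence
#' inside the evaluated region lies in qualifying up blocks.
#'
#' @param blocks Data.frame from [call_blocks()] (only up blocks, state 2,
#'   are used).
#' @param genes A [gene_model_set].
#' @param regions Optional data.frame `gene_id`, `start`, `end` restricting
#'   the evaluation interval per gene (e.g. the duplicated segment of a
#'   chimera); genes absent from `regions` are evaluated on the whole
#'   transcript. Genes with zero exonic bp in their region are excluded
#'   (with a message).
#' @param threshold Fraction of exonic bp required (default 0.5; the call is
#'   made at `fraction >= threshold`).
#' @return Data.frame with `gene_id`, `exonic_bp`, `up_bp`, `fraction`,
#'   `upregulated`, one row per evaluated gene.
#' @export
classify_gene_regions <- function(blocks, genes, regions = NULL,
                                  threshold = 0.5) {
  up <- blocks[blocks$state == 2L, , drop = FALSE]
  upr <- IRanges::IRanges(up$start, up$end)
  res <- lapply(genes$genes, function(g) {
    ex <- gene_exon_ranges(g)
    if (!is.null(regions) && g$id %in% regions$gene_id) {
      r <- regions[regions$gene_id == g$id, ]
      ex <- IRanges::intersect(ex, IRanges::IRanges(r$start, r$end))
    }
    total <- sum(IRanges::width(ex))
    if (total == 0L) {
      message("gene ", g$id, ": zero exonic bp in evaluated region, excluded")
      return(NULL)
    }
    covbp <- sum(IRanges::width(IRanges::intersect(ex, upr)))
    data.frame(gene_id = g$id, exonic_bp = total, up_bp = covbp,
               fraction = covbp / total,
               upregulated = covbp / total >= threshold)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), exonic_bp = integer(),
                      up_bp = integer(), fraction = numeric(),
                      upregulated = logical())
  rownames(out) <- NULL
  out
}

#' Aggregate gene calls across strains and tissues
#'
#' A gene is upregulated in a tissue if called in at least one strain, and
#' upregulated in aggregate if called in at least one tissue.
#'
#' @param calls Data.frame of per-(gene, strain, tissue) calls with columns
#'   `gene_id`, `strain`, `tissue`, `upregulated`.
#' @return Data.frame `gene_id`, `tissue` (including an `"aggregate"` row
#'   per gene), `upregulated`.
#' @export
aggregate_gene_calls <- function(calls) {
  per_tissue <- stats::aggregate(upregulated ~ gene_id + tissue, data = calls,
                                 FUN = any)
  agg <- stats::aggregate(upregulated ~ gene_id, data = calls, FUN = any)
  agg$tissue <- "aggregate"
  rbind(per_tissue, agg[, c("gene_id", "tissue", "upregulated")])
}

#' De novo transcription calls
#'
#' Retains upregulated blocks of at least `min_len` bp that (i) overlap no
#' annotated exon, (ii) have reference mean quantile-normalized coverage at
#' or below `max_ref_mu` at every site of the block (previously
#' untranscribed sequence), and (iii) intersect a tandem duplication span by
#' at least `min_dup_overlap` bp — the signature of previously silent
#' sequence activated by a duplicated 5' fragment.
#'
#' @param blocks Data.frame from [call_blocks()]; only up blocks are
#'   considered.
#' @param genes A [gene_model_set] providing the exon annotation.
#' @param duplications Data.frame with `start`, `end` columns (duplication
#'   spans, 1-based inclusive).
#' @param ref A `reference_summary` covering the block sites.
#' @param max_ref_mu Reference coverage ceiling, applied per site
#'   (default 2.0).
#' @param min_dup_overlap Minimum bp of overlap with a single duplication
#'   span (default 200).
#' @param min_len Minimum block length (default 50).
#' @return Data.frame `chrom`, `start`, `end`, `length`, `dup_overlap`,
#'   `max_ref_mu` per retained block.
#' @export
detect_de_novo <- function(blocks, genes, duplications, ref,
                           max_ref_mu = 2.0, min_dup_overlap = 200,
                           min_len = 50) {
  up <- blocks[blocks$state == 2L & blocks$length >= min_len, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), dup_overlap = integer(),
                      max_ref_mu = numeric())
  if (!nrow(up)) return(empty)
  exons <- do.call(c, c(lapply(genes$genes, gene_exon_ranges),
                        list(IRanges::IRanges())))
  keep <- lapply(seq_len(nrow(up)), function(i) {
    b <- IRanges::IRanges(up$start[i], up$end[i])
    if (length(exons) && sum(IRanges::width(IRanges::intersect(b, exons))) > 0L)
      return(NULL)
    sites <- ref$positions >= up$start[i] & ref$positions <= up$end[i]
    mmax <- if (any(sites)) max(ref$mu[sites]) else 0
    if (mmax > max_ref_mu) return(NULL)
    ov <- pmax(0L, pmin(up$end[i], duplications$end) -
                     pmax(up$start[i], duplications$start) + 1L)
    best <- if (length(ov)) max(ov) else 0L
    if (best < min_dup_overlap) return(NULL)
    data.frame(chrom = up$chrom[i], start = up$start[i], end = up$end[i],
               length = up$length[i], dup_overlap = best, max_ref_mu = mmax)
  })
  out <- do.call(rbind, keep)
  if (is.null(out)) empty else `rownames<-`(out, NULL)
}

#' Background rate of upregulated sites
#'
#' Fraction of sites decoded as upregulated genome wide (or over the given
#' track), the null proportion for enrichment testing. The study-scale value
#' on the real data is 5.26%.
#'
#' @param states Integer state codes (or an `expr_hmm` fit).
#' @param state Which state to count (default 2, upregulated).
#' @return Proportion in `[0, 1]`.
#' @export
background_rate <- function(states, state = 2L) {
  if (inherits(states, "expr_hmm") || inherits(states, "state_track"))
    states <- states$state
  if (!length(states)) stop("no sites: background rate undefined")
  mean(states == state)
}

#' Exact binomial enrichment test against a background rate
#'
#' Tests whether `k` upregulated calls out of `n` differ from the
#' genome-wide background proportion `p0`, by the exact binomial test
#' (two-sided by the minimum-likelihood convention: the sum of `P(x)` over
#' all outcomes no more likely than the observed one).
#'
#' @param k Upregulated count.
#' @param n Total count.
#' @param p0 Background proportion (default 0.0526, the study-scale
#'   genome-wide up-site rate).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return An object of class `enrichment_result`: list with `k`, `n`, `p0`,
#'   `p_value`, `alternative`.
#' @export
enrichment_binomial <- function(k, n, p0 = 0.0526,
                                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  p <- stats::binom.test(k, n, p = p0, alternative = alternative)$p.value
  structure(list(k = k, n = n, p0 = p0, p_value = p,
                 alternative = alternative),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("exact binomial test: %d/%d vs background %.4g (%s), P = %.4g\n",
              x$k, x$n, x$p0, x$alternative, x$p_value))
  invisible(x)
}
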