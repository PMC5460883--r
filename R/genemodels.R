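#' Gene model set
#'
#' Lightweight container for gene records: id, chromosome, strand, transcript
#' span (including UTRs where annotated), merged exon intervals, and 5'/3'
#' UTR intervals where present. All coordinates 1-based inclusive.
#'
#' @param genes List of gene records. Each record is a list with elements
#'   `id`, `chrom`, `strand` (`"+"` or `"-"`), `start`, `end`, `exons`
#'   (two-column matrix of start/end, merged on construction), and optionally
#'   `utr5`, `utr3` (two-column matrices, possibly with zero rows).
#' @return An object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes) {
  genes <- lapply(genes, function(g) {
    stopifnot(!is.null(g$id), !is.null(g$chrom), g$strand %in% c("+", "-"),
              g$start <= g$end)
    g$exons <- merge_intervals(g$exons)
    if (is.null(g$utr5)) g$utr5 <- matrix(integer(), 0, 2)
    if (is.null(g$utr3)) g$utr3 <- matrix(integer(), 0, 2)
    # exons are clamped to the transcript span; out-of-span exons indicate a
    # malformed annotation and are repaired rather than fatal
    if (nrow(g$exons) && (min(g$exons[, 1]) < g$start || max(g$exons[, 2]) > g$end)) {
      warning("gene ", g$id, ": exon outside transcript span, clamping")
      g$exons[, 1] <- pmax(g$exons[, 1], g$start)
      g$exons[, 2] <- pmin(g$exons[, 2], g$end)
      g$exons <- merge_intervals(g$exons)
    }
    g
  })
  names(genes) <- vapply(genes, `[[`, "", "id")
  structure(list(genes = genes), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("gene_model_set: %d genes\n", length(x$genes)))
  invisible(x)
}

#' @export
length.gene_model_set <- function(x) length(x$genes)

## merge overlapping/abutting intervals; m is a 2-column start/end matrix
merge_intervals <- function(m) {
  m <- matrix(as.integer(m), ncol = 2)
  if (nrow(m) <= 1L) return(m)
  ir <- IRanges::reduce(IRanges::IRanges(m[, 1], m[, 2]))
  cbind(IRanges::start(ir), IRanges::end(ir))
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 with `gene`/`mRNA`/`exon` features (and
#' `five_prime_UTR`/`three_prime_UTR` where annotated) into a
#' [gene_model_set]. Exons are merged across the transcripts of each gene so
#' that "annotated exon sequence" is the per-gene exon union; the transcript
#' span is the gene feature span (which includes the UTRs).
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_model_set]; empty file yields an empty set.
#' @export
read_gene_models <- function(path) {
  gff <- try(rtracklayer::import(path, format = "gff3"), silent = TRUE)
  if (inherits(gff, "try-error") || length(gff) == 0L)
    return(gene_model_set(list()))
  type <- as.character(gff$type)
  ids <- if (is.null(gff$ID)) rep(NA_character_, length(gff))
         else as.character(gff$ID)
  parent <- if (is.null(gff$Parent)) rep(NA_character_, length(gff))
            else vapply(gff$Parent, function(p)
              if (length(p)) as.character(p[1]) else NA_character_, "")

  genes_idx <- which(type == "gene")
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  mrna_gene <- stats::setNames(parent[mrna_idx], ids[mrna_idx])

  # map every child feature up to its gene
  feature_gene <- function(i) {
    p <- parent[i]
    ifelse(p %in% ids[genes_idx], p,
           ifelse(p %in% names(mrna_gene), unname(mrna_gene[p]), NA_character_))
  }

  recs <- lapply(genes_idx, function(gi) {
    gid <- ids[gi]
    child <- which(!is.na(parent) & type %in%
                     c("exon", "five_prime_UTR", "three_prime_UTR"))
    child <- child[feature_gene(child) == gid]
    take <- function(tt) {
      j <- child[type[child] == tt]
      cbind(GenomicRanges::start(gff)[j], GenomicRanges::end(gff)[j])
    }
    list(id = gid,
         chrom = as.character(GenomicRanges::seqnames(gff))[gi],
         strand = as.character(GenomicRanges::strand(gff))[gi],
         start = GenomicRanges::start(gff)[gi],
         end = GenomicRanges::end(gff)[gi],
         exons = take("exon"),
         utr5 = take("five_prime_UTR"),
         utr3 = take("three_prime_UTR"))
  })
  gene_model_set(recs)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and UTR features (one synthetic mRNA per gene) in
#' GFF3, so a [gene_model_set] round-trips through [read_gene_models()].
#'
#' @param gms A [gene_model_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  row <- function(chrom, type, s, e, strand, attr)
    paste(chrom, "covhmm", type, s, e, ".", strand, ".", attr, sep = "\t")
  for (g in gms$genes) {
    tid <- paste0(g$id, ".t1")
    writeLines(row(g$chrom, "gene", g$start, g$end, g$strand,
                   paste0("ID=", g$id)), con)
    writeLines(row(g$chrom, "mRNA", g$start, g$end, g$strand,
                   paste0("ID=", tid, ";Parent=", g$id)), con)
    emit <- function(m, type) {
      if (nrow(m)) for (i in seq_len(nrow(m)))
        writeLines(row(g$chrom, type, m[i, 1], m[i, 2], g$strand,
                       paste0("Parent=", tid)), con)
    }
    emit(g$exons, "exon")
    emit(g$utr5, "five_prime_UTR")
    emit(g$utr3, "three_prime_UTR")
  }
  invisible(path)
}

## exon union of a gene restricted to chromosome intervals, as an IRanges
gene_exon_ranges <- function(g) {
  if (nrow(g$exons)) IRanges::IRanges(g$exons[, 1], g$exons[, 2])
  else IRanges::IRanges(g$start, g$end)
}
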