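#' Mean fold change of a segment against the reference
#'
#' Ratio of mean sample coverage to mean reference coverage over the sites
#' of a segment (a gene, chimera segment or interval), with a lower bound of
#' one read on the reference coverage level so that silent reference
#' segments do not blow up the ratio. Segments are considered independently
#' because parental genes may differ in ancestral expression.
#'
#' @param sample_cov Sample per-site coverage over the segment sites.
#' @param ref_mu Reference per-site mean over the same sites.
#' @param floor Lower bound on reference coverage (default 1 read).
#' @param per_site_floor If TRUE, floor each site before averaging instead
#'   of flooring the segment mean (a sensitivity-analysis mode; default
#'   FALSE floors the denominator summary).
#' @return The mean fold change (non-negative scalar).
#' @export
mean_fold_change <- function(sample_cov, ref_mu, floor = 1,
                             per_site_floor = FALSE) {
  if (!length(sample_cov) || length(sample_cov) != length(ref_mu))
    stop("segment is empty or sample/reference sites differ")
  denom <- if (per_site_floor) mean(pmax(ref_mu, floor))
           else max(mean(ref_mu), floor)
  mean(sample_cov) / denom
}

#' Fisher's exact test for allele-specific expression at a SNP site
#'
#' Compares the reads supporting the reference and alternate allele at a
#' putatively heterozygous site between the genomic and the RNA library of
#' a strain (2x2 table, two-sided). Sites with fewer than `min_reads` in
#' either library are skipped (returned as `NA`): below that depth the test
#' is uninformative. A zero margin makes the table degenerate and returns
#' p = 1.
#'
#' @param dna_ref,dna_alt Genomic read counts for the two alleles.
#' @param rna_ref,rna_alt RNA read counts for the two alleles.
#' @param min_reads Minimum total reads required in each library
#'   (default 10).
#' @return Two-sided p-value, or `NA_real_` for a skipped site. Vectorized.
#' @export
fisher_allele_test <- function(dna_ref, dna_alt, rna_ref, rna_alt,
                               min_reads = 10) {
  stopifnot(all(c(dna_ref, dna_alt, rna_ref, rna_alt) >= 0))
  mapply(function(a, b, c_, d) {
    if (a + b < min_reads || c_ + d < min_reads) return(NA_real_)
    m <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
    stats::fisher.test(m)$p.value
  }, dna_ref, dna_alt, rna_ref, rna_alt)
}

#' Filter allele-specific-expression controls from candidate sites
#'
#' Sites showing significant allele-specific expression in a strain that
#' does not carry the duplication reflect ASE independent of duplication
#' and are removed; only sites significant exclusively in carrier strains
#' remain candidates for asymmetric expression of duplicate copies.
#'
#' @param tests Data.frame with columns `site` (site identifier), `strain`,
#'   `p_value` (from [fisher_allele_test()]; `NA` = skipped).
#' @param carriers Character vector of strains carrying the duplication.
#' @param alpha Per-site significance threshold of the screen
#'   (default 0.05, uncorrected).
#' @return Data.frame of retained candidate rows: carrier-strain rows at
#'   sites significant in at least one carrier and no non-carrier.
#' @export
filter_ase_controls <- function(tests, carriers, alpha = 0.05) {
  sig <- !is.na(tests$p_value) & tests$p_value < alpha
  bad_sites <- unique(tests$site[sig & !(tests$strain %in% carriers)])
  cand_sites <- setdiff(unique(tests$site[sig & tests$strain %in% carriers]),
                        bad_sites)
  out <- tests[tests$site %in% cand_sites & tests$strain %in% carriers &
                 sig, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test with the reference-implementation
#' statistic convention: `W` is the rank sum of the first sample minus its
#' minimum, so `W` ranges over `[0, n*m]`. Exact for small samples without
#' ties, normal approximation with tie correction otherwise.
#'
#' @param x,y Numeric samples, both nonempty.
#' @return List with `W` and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(W = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson chi-squared test on two proportions
#'
#' Compares `k1/n1` against `k2/n2` on the 2x2 table with 1 degree of
#' freedom and no continuity correction.
#'
#' @param k1,n1 Successes and trials in the first group.
#' @param k2,n2 Successes and trials in the second group.
#' @return List with `statistic` (X-squared), `df` (1) and `p_value`.
#' @export
chi2_proportion <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  exp_cells <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_cells == 0)) stop("expected cell count of zero")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L,
       p_value = unname(ct$p.value))
}

#' Resampling test of tissue-biased gene representation
#'
#' Tests whether genes captured by duplications are enriched (or depleted)
#' for a tissue-biased expression label, by drawing `set_size` genes
#' without replacement from the gene universe in each of `replicates`
#' resampling rounds and comparing the observed biased-gene count to the
#' resampled distribution. The empirical one-sided p-value uses an add-one
#' correction, `p = (1 + #{count >= observed}) / (1 + replicates)`, so a
#' result beyond every replicate reports `p < 1/(replicates + 1)` rather
#' than zero.
#'
#' @param observed Biased-gene count in the duplicated set.
#' @param bias_labels Logical vector over the gene universe (TRUE = biased
#'   toward the tissue).
#' @param set_size Number of genes in the duplicated set.
#' @param replicates Resampling rounds (default 10000).
#' @param alternative `"greater"` (excess, default) or `"less"` (deficit,
#'   tested with `<=`).
#' @param seed Optional seed for reproducibility.
#' @return List with `p_value`, `observed`, `expected` (mean resampled
#'   count) and `replicates`.
#' @export
resample_tissue_bias <- function(observed, bias_labels, set_size,
                                 replicates = 10000,
                                 alternative = c("greater", "less"),
                                 seed = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(replicates >= 1, set_size <= length(bias_labels))
  if (!is.null(seed)) set.seed(seed)
  bias_labels <- as.logical(bias_labels)
  counts <- vapply(seq_len(replicates), function(i)
    sum(bias_labels[sample.int(length(bias_labels), set_size)]), 1L)
  hits <- if (alternative == "greater") sum(counts >= observed)
          else sum(counts <= observed)
  list(p_value = (1 + hits) / (1 + replicates), observed = observed,
       expected = mean(counts), replicates = replicates)
}
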