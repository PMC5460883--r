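#' Simulation configuration
#'
#' Defines the synthetic study: a single chromosome carrying regularly
#' spaced gene models, three reference replicates plus a set of sample
#' strains at study-scale coverage, and a list of structural events with
#' known truth. Defaults mirror the study conditions: 61x mean
#' quantile-normalized exonic coverage, three reference replicates, and
#' negative-binomial site noise with gene-level random effects (raw
#' per-site Poisson noise would understate replicate variance and overstate
#' HMM power).
#'
#' @param seed Integer seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of genes, evenly spaced.
#' @param gene_length Transcript span per gene (bp), UTRs included.
#' @param utr_length 5' and 3' UTR length (bp).
#' @param n_exons Exons per gene (UTRs merged into terminal exons).
#' @param intron_length Intron length between exons (bp).
#' @param mean_exonic_coverage Mean coverage over all exonic sites
#'   (normalized reads; default 61, the study scale).
#' @param gene_level_sdlog Log-scale sd of per-gene base expression levels
#'   (default 0.8, a realistic inter-gene spread; levels are rescaled so
#'   the overall exonic mean stays exactly at `mean_exonic_coverage`).
#'   Without this spread the coverage distribution is unrealistically
#'   homogeneous and quantile normalization would compress genuine fold
#'   changes.
#' @param intron_mean Mean coverage at intronic sites (default 2).
#' @param background_mean Mean coverage at intergenic sites (default 0.05,
#'   essentially silent).
#' @param dispersion Negative-binomial size parameter (default 100; larger
#'   is closer to Poisson).
#' @param gene_effect_sd Log-normal sd of the per-(gene, library) random
#'   effect inducing site-level autocorrelation within genes
#'   (default 0.05).
#' @param n_strains Number of sample strains.
#' @param ref_reps Number of reference replicates (default 3).
#' @param tissue Tissue label carried through outputs.
#' @param events List of event descriptions, each a list with `type`
#'   (`"whole_gene"`, `"chimera"`, `"de_novo"` or `"dup_del"`), `fold`
#'   (multiplicative expression change in carriers; for `whole_gene`, 1
#'   encodes dosage sharing and 2 additive dosage), `carriers` (strain
#'   names), optionally `gene` (index of the first affected gene; assigned
#'   left-to-right when omitted) and for `de_novo` a `level` (mean coverage
#'   of the activated region, default 30).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, chrom = "2L", chrom_length = 100000,
                       n_genes = 10, gene_length = 2000, utr_length = 200,
                       n_exons = 3, intron_length = 100,
                       mean_exonic_coverage = 61, gene_level_sdlog = 0.8,
                       intron_mean = 2,
                       background_mean = 0.05, dispersion = 100,
                       gene_effect_sd = 0.05, n_strains = 5, ref_reps = 3,
                       tissue = "testes", events = list()) {
  stopifnot(chrom_length > 0, n_genes >= 0, ref_reps >= 2,
            mean_exonic_coverage >= 0, dispersion > 0)
  for (ev in events) {
    if (!ev$type %in% c("whole_gene", "chimera", "de_novo", "dup_del"))
      stop("unknown event type: ", ev$type)
    if (!is.null(ev$fold) && ev$fold <= 0) stop("event fold must be > 0")
  }
  structure(list(seed = as.integer(seed), chrom = chrom,
                 chrom_length = as.integer(chrom_length), n_genes = n_genes,
                 gene_length = gene_length, utr_length = utr_length,
                 n_exons = n_exons, intron_length = intron_length,
                 mean_exonic_coverage = mean_exonic_coverage,
                 gene_level_sdlog = gene_level_sdlog,
                 intron_mean = intron_mean, background_mean = background_mean,
                 dispersion = dispersion, gene_effect_sd = gene_effect_sd,
                 n_strains = n_strains, ref_reps = ref_reps, tissue = tissue,
                 events = events,
                 strains = paste0("S", seq_len(n_strains)),
                 ref_samples = paste0("ref", seq_len(ref_reps))),
            class = "sim_config")
}

## deterministic gene layout: evenly spaced plus-strand genes with UTRs
## merged into the terminal exons
sim_gene_layout <- function(config) {
  if (config$n_genes == 0L) return(gene_model_set(list()))
  spacing <- config$chrom_length %/% (config$n_genes + 1L)
  if (spacing <= config$gene_length)
    stop("chromosome too short for ", config$n_genes, " genes of length ",
         config$gene_length)
  genes <- lapply(seq_len(config$n_genes), function(i) {
    s <- (i - 1L) * spacing + spacing %/% 2L
    e <- s + config$gene_length - 1L
    u <- config$utr_length
    inner <- (e - u) - (s + u) + 1L
    k <- config$n_exons
    we <- (inner - (k - 1L) * config$intron_length) %/% k
    if (we < 1L) stop("gene too short for ", k, " exons")
    ex_start <- s + u + (seq_len(k) - 1L) * (we + config$intron_length)
    ex_end <- ex_start + we - 1L
    ex_end[k] <- e - u
    exons <- cbind(ex_start, ex_end)
    exons[1L, 1L] <- s      # merge 5' UTR into first exon
    exons[k, 2L] <- e       # merge 3' UTR into last exon
    list(id = sprintf("G%03d", i), chrom = config$chrom, strand = "+",
         start = s, end = e, exons = exons,
         utr5 = matrix(c(s, s + u - 1L), 1),
         utr3 = matrix(c(e - u + 1L, e), 1))
  })
  gene_model_set(genes)
}

## resolve event placements against the gene layout; returns the truth table
sim_truth <- function(config, genes) {
  cols <- data.frame(event_id = character(), type = character(),
                     chrom = character(), dup_start = integer(),
                     dup_end = integer(), expr_start = integer(),
                     expr_end = integer(), gene_ids = character(),
                     fold = numeric(), level = numeric(),
                     ase_skew = numeric(), carriers = character(),
                     expected_class = character())
  if (!length(config$events)) return(cols)
  gl <- genes$genes
  nextg <- 1L
  rows <- lapply(seq_along(config$events), function(i) {
    ev <- config$events[[i]]
    gi <- if (!is.null(ev$gene)) ev$gene else nextg
    nextg <<- gi + (if (ev$type == "chimera") 3L else 2L)
    fold <- if (!is.null(ev$fold)) ev$fold else 2
    level <- if (!is.null(ev$level)) ev$level else 30
    skew <- if (!is.null(ev$ase_skew)) ev$ase_skew else 0.5
    carriers <- paste(ev$carriers, collapse = ",")
    if (ev$type %in% c("whole_gene", "dup_del")) {
      g <- gl[[gi]]
      ds <- g$start - 300L; de <- g$end + 300L
      es <- if (ev$type == "dup_del") g$start + (g$end - g$start) %/% 2L else g$start
      data.frame(event_id = paste0("ev", i), type = ev$type,
                 chrom = config$chrom, dup_start = ds, dup_end = de,
                 expr_start = es, expr_end = g$end, gene_ids = g$id,
                 fold = fold, level = NA_real_, ase_skew = skew,
                 carriers = carriers, expected_class = "whole_gene")
    } else if (ev$type == "chimera") {
      ga <- gl[[gi]]; gb <- gl[[gi + 1L]]
      x <- ga$start + as.integer(0.6 * (ga$end - ga$start))  # interior of A
      y <- gb$start + as.integer(0.4 * (gb$end - gb$start))  # interior of B
      data.frame(event_id = paste0("ev", i), type = "chimera",
                 chrom = config$chrom, dup_start = x, dup_end = y,
                 expr_start = x, expr_end = y,
                 gene_ids = paste(gb$id, ga$id, sep = ","),  # 5' donor, 3' donor
                 fold = fold, level = NA_real_, ase_skew = NA_real_,
                 carriers = carriers, expected_class = "chimera")
    } else { # de_novo: dup captures the 5' part of the gene plus upstream
             # intergenic sequence, which the copied promoter activates
      g <- gl[[gi]]
      x <- g$start - 600L
      y <- g$start + as.integer(0.4 * (g$end - g$start))
      data.frame(event_id = paste0("ev", i), type = "de_novo",
                 chrom = config$chrom, dup_start = x, dup_end = y,
                 expr_start = x, expr_end = g$start - 1L, gene_ids = g$id,
                 fold = NA_real_, level = level, ase_skew = NA_real_,
                 carriers = carriers, expected_class = "recruited_noncoding")
    }
  })
  truth <- do.call(rbind, rows)
  if (any(truth$dup_start < 1L) || any(truth$dup_end > config$chrom_length))
    stop("event interval falls off the chromosome")
  truth
}

#' Simulate coverage tracks with known truth
#'
#' Generates per-site coverage for the reference replicates and all sample
#' strains on one chromosome. Exonic sites draw from a negative binomial at
#' the configured mean and dispersion; intergenic background is near zero;
#' a per-(gene, library) log-normal random effect induces the within-gene
#' correlation real replicate tracks show; reference replicates are i.i.d.
#' Carrier strains have each event's fold change applied multiplicatively
#' over the event's expressed interval (or, for de novo events, the
#' activated region set to the configured level).
#'
#' @param config A [sim_config].
#' @return List with `coverage` (a [coverage_matrix], reference columns
#'   first), `genes` (a [gene_model_set]), `truth` (the event truth table),
#'   `ref_samples`, `strains` and `config`.
#' @export
simulate_coverage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sim_gene_layout(config)
  truth <- sim_truth(config, genes)
  n <- config$chrom_length
  ## per-gene base expression levels, log-normal across genes, rescaled so
  ## the exonic-bp-weighted mean equals the configured coverage exactly
  ng <- length(genes$genes)
  lev <- if (ng && config$gene_level_sdlog > 0)
    exp(stats::rnorm(ng, 0, config$gene_level_sdlog)) else rep(1, ng)
  if (ng) {
    w <- vapply(genes$genes, function(g)
      sum(g$exons[, 2L] - g$exons[, 1L] + 1L), 1)
    lev <- lev * config$mean_exonic_coverage * sum(w) / sum(w * lev)
  }
  base <- rep(config$background_mean, n)
  for (i in seq_len(ng)) {
    g <- genes$genes[[i]]
    base[g$start:g$end] <- config$intron_mean
    for (j in seq_len(nrow(g$exons)))
      base[g$exons[j, 1L]:g$exons[j, 2L]] <- lev[i]
  }
  libs <- c(config$ref_samples, config$strains)
  depth <- matrix(0, n, length(libs), dimnames = list(NULL, libs))
  for (lib in libs) {
    mu <- base
    if (config$gene_effect_sd > 0) for (g in genes$genes) {
      f <- stats::rlnorm(1, -config$gene_effect_sd^2 / 2, config$gene_effect_sd)
      mu[g$start:g$end] <- mu[g$start:g$end] * f
    }
    if (nrow(truth)) for (k in seq_len(nrow(truth))) {
      if (!lib %in% strsplit(truth$carriers[k], ",")[[1L]]) next
      idx <- truth$expr_start[k]:truth$expr_end[k]
      if (truth$type[k] == "de_novo") mu[idx] <- truth$level[k]
      else mu[idx] <- mu[idx] * truth$fold[k]
    }
    depth[, lib] <- stats::rnbinom(n, size = config$dispersion, mu = mu)
  }
  list(coverage = coverage_matrix(config$chrom, seq_len(n), depth, libs),
       genes = genes, truth = truth, ref_samples = config$ref_samples,
       strains = config$strains, config = config)
}

#' Simulate divergent read pairs for the injected duplications
#'
#' Each duplication event emits `n_pairs` divergently oriented read pairs
#' per carrier strain, anchored at the true breakpoints with up to `jitter`
#' bp of uniform jitter; non-carriers emit none.
#'
#' @param sim Output of [simulate_coverage()].
#' @param n_pairs Pairs per (event, carrier) (default 4).
#' @param jitter Maximum anchor jitter in bp (default 50; 0 places anchors
#'   exactly at the breakpoints).
#' @param read_length Read length in bp (default 76).
#' @return Data.frame of read-pair records in the [read_read_pairs()]
#'   layout.
#' @export
simulate_read_pairs <- function(sim, n_pairs = 4, jitter = 50,
                                read_length = 76) {
  set.seed(sim$config$seed + 1L)
  truth <- sim$truth
  rows <- list()
  if (nrow(truth)) for (k in seq_len(nrow(truth))) {
    for (strain in strsplit(truth$carriers[k], ",")[[1L]]) {
      jl <- if (jitter > 0) sample.int(jitter + 1L, n_pairs, TRUE) - 1L else rep(0L, n_pairs)
      jr <- if (jitter > 0) sample.int(jitter + 1L, n_pairs, TRUE) - 1L else rep(0L, n_pairs)
      ls <- truth$dup_start[k] + jl
      re <- truth$dup_end[k] - jr
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain, chrom = truth$chrom[k],
        left_start = ls, left_end = ls + read_length - 1L,
        right_start = re - read_length + 1L, right_end = re,
        orientation = "divergent")
    }
  }
  if (!length(rows))
    return(data.frame(strain = character(), chrom = character(),
                      left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      orientation = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate SNP allele-count tables for dosage-sharing tests
#'
#' For each whole-gene (and dup-del) event, plants heterozygous SNP sites
#' inside the gene and draws genomic and RNA allele counts per strain.
#' Carrier strains of events flagged with `ase_skew` draw RNA counts at the
#' skewed ratio (asymmetric expression of duplicate copies); all other
#' libraries draw balanced counts.
#'
#' @param sim Output of [simulate_coverage()].
#' @param sites_per_event SNP sites planted per event (default 3).
#' @param depth_dna,depth_rna Total reads per site and library (default 40).
#' @return Data.frame `chrom`, `pos`, `strain`, `dna_ref`, `dna_alt`,
#'   `rna_ref`, `rna_alt`, `tissue`.
#' @export
simulate_snp_counts <- function(sim, sites_per_event = 3, depth_dna = 40,
                                depth_rna = 40) {
  set.seed(sim$config$seed + 2L)
  truth <- sim$truth[sim$truth$type %in% c("whole_gene", "dup_del"), ,
                     drop = FALSE]
  rows <- list()
  if (nrow(truth)) for (k in seq_len(nrow(truth))) {
    skew <- truth$ase_skew[k]
    carriers <- strsplit(truth$carriers[k], ",")[[1L]]
    g <- sim$genes$genes[[strsplit(truth$gene_ids[k], ",")[[1L]][1L]]]
    pos <- round(seq(g$start + 50L, g$end - 50L,
                     length.out = sites_per_event))
    for (p in pos) for (strain in sim$strains) {
      dr <- stats::rbinom(1L, depth_dna, 0.5)
      pr <- if (strain %in% carriers) skew else 0.5
      rr <- stats::rbinom(1L, depth_rna, pr)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = truth$chrom[k], pos = p, strain = strain,
        dna_ref = dr, dna_alt = depth_dna - dr,
        rna_ref = rr, rna_alt = depth_rna - rr,
        tissue = sim$config$tissue)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      strain = character(), dna_ref = integer(),
                      dna_alt = integer(), rna_ref = integer(),
                      rna_alt = integer(), tissue = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a fixture bundle to disk
#'
#' Writes the simulated study as plain-text files: depth TSV (samtools
#' layout), gene models as GFF3, duplication spans as BED (0-based
#' half-open), read pairs and SNP counts as TSV, and the truth table as
#' TSV. Re-reading the depth TSV and the GFF3 with the package readers
#' reproduces the in-memory objects; with a fixed seed the bundle is
#' byte-identical across runs.
#'
#' @param sim Output of [simulate_coverage()].
#' @param outdir Output directory (created if needed).
#' @param pairs Optional read-pair table (generated with defaults when
#'   omitted).
#' @param snps Optional SNP count table (generated with defaults when
#'   omitted).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, outdir, pairs = NULL, snps = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(pairs)) pairs <- simulate_read_pairs(sim)
  if (is.null(snps)) snps <- simulate_snp_counts(sim)
  paths <- c(depth = file.path(outdir, "depth.tsv"),
             gff = file.path(outdir, "genes.gff3"),
             dups = file.path(outdir, "duplications.bed"),
             pairs = file.path(outdir, "read_pairs.tsv"),
             snps = file.path(outdir, "snp_counts.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  write_depth_tsv(sim$coverage, paths["depth"])
  write_gene_models(sim$genes, paths["gff"])
  nev <- nrow(sim$truth)
  bed <- data.frame(chrom = sim$truth$chrom, start = sim$truth$dup_start - 1L,
                    end = sim$truth$dup_end, name = sim$truth$event_id,
                    score = rep(0L, nev), strand = rep(".", nev))
  utils::write.table(bed, paths["dups"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(pairs, paths["pairs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(snps, paths["snps"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
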