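test_that("block caller honors the 50 bp boundary exactly", {
  pos <- 1:200
  st <- rep(1L, 200)
  st[51:100] <- 2L                     # 50 contiguous up sites
  b <- call_blocks(st, pos)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, 51)
  expect_equal(b$end, 100)
  expect_equal(b$length, 50)

  st49 <- rep(1L, 200); st49[51:99] <- 2L  # 49 sites: below the floor
  expect_equal(nrow(call_blocks(st49, pos)), 0L)
})

test_that("a single interrupting site splits a run", {
  st <- c(rep(2L, 60), 1L, rep(2L, 55))
  b <- call_blocks(st, seq_along(st))
  expect_equal(nrow(b), 2L)
  expect_equal(b$length, c(60, 55))
})

test_that("a coordinate gap splits a run", {
  pos <- c(1:60, 62:121)   # site 61 missing from the track
  st <- rep(2L, 120)
  b <- call_blocks(st, pos)
  expect_equal(nrow(b), 2L)
  expect_equal(b$length, c(60, 60))
})

test_that("block caller matches a brute-force run-length scan", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    pos <- sort(sample.int(600, n))
    st <- sample(0:2, n, replace = TRUE, prob = c(0.2, 0.5, 0.3))
    ml <- sample(c(2, 5, 10), 1)
    got <- call_blocks(st, pos, min_len = ml)
    want <- blocks_bruteforce(st, pos, min_len = ml)
    expect_equal(got[c("start", "end", "state", "length")], want,
                 ignore_attr = TRUE)
  }
})

test_that("gene calls apply the 50% exon-coverage rule at the boundary", {
  genes <- gene_model_set(list(list(
    id = "g1", chrom = "2L", strand = "+", start = 1, end = 300,
    exons = rbind(c(1, 300)))))
  # 160 of 300 exonic bp upregulated -> called
  b <- data.frame(chrom = "2L", start = 1, end = 160, state = 2L, length = 160)
  call <- classify_gene_regions(b, genes)
  expect_equal(call$fraction, 160 / 300)
  expect_true(call$upregulated)
  # 149 bp -> not called; 150 bp (exactly half) -> called
  b$end <- 149; expect_false(classify_gene_regions(b, genes)$upregulated)
  b$end <- 150; expect_true(classify_gene_regions(b, genes)$upregulated)
})

test_that("gene-call fraction is invariant to exon splitting", {
  ex_whole <- rbind(c(101, 700))
  ex_split <- rbind(c(101, 300), c(301, 500), c(501, 700))
  blocks <- data.frame(chrom = "2L", start = c(150, 420), end = c(280, 650),
                       state = 2L, length = c(131, 231))
  g1 <- gene_model_set(list(list(id = "g", chrom = "2L", strand = "+",
                                 start = 101, end = 700, exons = ex_whole)))
  g2 <- gene_model_set(list(list(id = "g", chrom = "2L", strand = "+",
                                 start = 101, end = 700, exons = ex_split)))
  expect_equal(classify_gene_regions(blocks, g1)$fraction,
               classify_gene_regions(blocks, g2)$fraction)
})

test_that("region restriction evaluates only the duplicated segment", {
  genes <- gene_model_set(list(list(
    id = "g1", chrom = "2L", strand = "+", start = 1, end = 1000,
    exons = rbind(c(1, 1000)))))
  blocks <- data.frame(chrom = "2L", start = 1, end = 260, state = 2L,
                       length = 260)
  # whole transcript: 26% -> not called; 5' segment 1-400: 65% -> called
  expect_false(classify_gene_regions(blocks, genes)$upregulated)
  reg <- data.frame(gene_id = "g1", start = 1, end = 400)
  expect_true(classify_gene_regions(blocks, genes, regions = reg)$upregulated)
  # gene with no exonic bp in the region is excluded with a message
  reg2 <- data.frame(gene_id = "g1", start = 2000, end = 3000)
  expect_message(out <- classify_gene_regions(blocks, genes, regions = reg2),
                 "excluded")
  expect_equal(nrow(out), 0L)
})

test_that("aggregation calls a gene up if called in any strain, per tissue and overall", {
  calls <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2"),
    strain = c("S1", "S2", "S1", "S1"),
    tissue = c("ovary", "ovary", "testes", "ovary"),
    upregulated = c(FALSE, TRUE, FALSE, FALSE))
  agg <- aggregate_gene_calls(calls)
  expect_true(agg$upregulated[agg$gene_id == "g1" & agg$tissue == "ovary"])
  expect_false(agg$upregulated[agg$gene_id == "g1" & agg$tissue == "testes"])
  expect_true(agg$upregulated[agg$gene_id == "g1" & agg$tissue == "aggregate"])
  expect_false(agg$upregulated[agg$gene_id == "g2" & agg$tissue == "aggregate"])
})

make_denovo_fixture <- function(block_len = 250, ref_spike = NULL) {
  genes <- gene_model_set(list(list(
    id = "g1", chrom = "2L", strand = "+", start = 5000, end = 6000,
    exons = rbind(c(5000, 6000)))))
  start <- 1000L
  blocks <- data.frame(chrom = "2L", start = start,
                       end = start + block_len - 1L, state = 2L,
                       length = block_len)
  dups <- data.frame(start = 900, end = 1400)
  pos <- 900:1500
  mu <- rep(0.2, length(pos))
  if (!is.null(ref_spike)) mu[pos == 1100] <- ref_spike
  ref <- structure(list(chrom = "2L", positions = pos, mu = mu,
                        sigma2 = rep(0.1, length(pos)), n_reps = 3),
                   class = "reference_summary")
  list(blocks = blocks, genes = genes, dups = dups, ref = ref)
}

test_that("de novo calls require length, silence in the reference, and duplication overlap", {
  fx <- make_denovo_fixture()
  dn <- detect_de_novo(fx$blocks, fx$genes, fx$dups, fx$ref)
  expect_equal(nrow(dn), 1L)
  expect_equal(dn$dup_overlap, 250L)

  # a single reference site above the 2.0 ceiling rejects the block
  fx2 <- make_denovo_fixture(ref_spike = 5)
  expect_equal(nrow(detect_de_novo(fx2$blocks, fx2$genes, fx2$dups, fx2$ref)), 0L)

  # 180 bp of duplication overlap is below the 200 bp floor
  fx3 <- make_denovo_fixture(block_len = 180)
  expect_equal(nrow(detect_de_novo(fx3$blocks, fx3$genes, fx3$dups, fx3$ref)), 0L)
  # 200 bp exactly qualifies
  fx4 <- make_denovo_fixture(block_len = 200)
  expect_equal(nrow(detect_de_novo(fx4$blocks, fx4$genes, fx4$dups, fx4$ref)), 1L)

  # exon overlap disqualifies
  fx5 <- make_denovo_fixture()
  fx5$blocks$start <- 5900; fx5$blocks$end <- 6149
  fx5$dups <- data.frame(start = 5800, end = 6400)
  expect_equal(nrow(detect_de_novo(fx5$blocks, fx5$genes, fx5$dups, fx5$ref)), 0L)
})

test_that("de novo calling is monotone in its thresholds", {
  fx <- make_denovo_fixture(ref_spike = 1.8)
  base <- detect_de_novo(fx$blocks, fx$genes, fx$dups, fx$ref)
  # raising the coverage ceiling or lowering the span floor keeps the call
  more1 <- detect_de_novo(fx$blocks, fx$genes, fx$dups, fx$ref, max_ref_mu = 5)
  more2 <- detect_de_novo(fx$blocks, fx$genes, fx$dups, fx$ref,
                          min_dup_overlap = 100)
  expect_gte(nrow(more1), nrow(base))
  expect_gte(nrow(more2), nrow(base))
  # tightening removes it
  less <- detect_de_novo(fx$blocks, fx$genes, fx$dups, fx$ref, max_ref_mu = 1.0)
  expect_equal(nrow(less), 0L)
})

test_that("background rate counts the up-state fraction", {
  expect_equal(background_rate(rep(1L, 100)), 0)
  st <- c(rep(2L, 10), rep(1L, 190))
  expect_equal(background_rate(st), 0.05)
  expect_error(background_rate(integer()), "undefined")
})

test_that("exact binomial enrichment matches pmf enumeration for n <= 500", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.01, 0.5)
    got <- enrichment_binomial(k, n, p0)$p_value
    expect_equal(got, binom_minlik_p(k, n, p0), tolerance = 1e-12)
  }
  expect_equal(enrichment_binomial(0, 1, 0.0526)$p_value, 1)
})
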