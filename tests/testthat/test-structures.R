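make_pairs <- function(strain, chrom, starts, ends, orientation = "divergent",
                       rl = 76) {
  data.frame(strain = strain, chrom = chrom,
             left_start = starts, left_end = starts + rl - 1,
             right_start = ends - rl + 1, right_end = ends,
             orientation = orientation)
}

test_that("three divergent pairs within 25 kb form one call, two do not", {
  p3 <- make_pairs("S1", "2L", c(1000, 1100, 1050), c(3000, 2900, 2950))
  calls <- call_duplications(p3)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 1000)
  expect_equal(calls$end, 3000)
  expect_equal(calls$n_pairs, 3L)

  p2 <- make_pairs("S1", "2L", c(1000, 1100), c(3000, 2900))
  expect_equal(nrow(call_duplications(p2)), 0L)
})

test_that("reference-strain divergent pairs exclude overlapping calls", {
  p3 <- make_pairs("S1", "2L", c(1000, 1100, 1050), c(3000, 2900, 2950))
  ref <- make_pairs("ref", "2L", 1500, 2500)
  expect_equal(nrow(call_duplications(p3, reference_pairs = ref)), 0L)
  ref_far <- make_pairs("ref", "2L", 50000, 52000)
  expect_equal(nrow(call_duplications(p3, reference_pairs = ref_far)), 1L)
  # proper-orientation reference pairs do not exclude
  ref_proper <- make_pairs("ref", "2L", 1500, 2500, orientation = "proper")
  expect_equal(nrow(call_duplications(p3, reference_pairs = ref_proper)), 1L)
})

test_that("pair groups farther than 25 kb apart split into separate calls", {
  p <- make_pairs("S1", "2L", c(1000, 1200, 1100, 40000, 40100, 40200),
                  c(2000, 2100, 2050, 41000, 41100, 41050))
  calls <- call_duplications(p)
  expect_equal(nrow(calls), 2L)
  expect_true(all(calls$end - calls$start <= 25000))
})

test_that("duplication calling is invariant to input record order", {
  set.seed(31)
  p <- rbind(
    make_pairs("S1", "2L", c(1000, 1100, 1050), c(3000, 2900, 2950)),
    make_pairs("S1", "2L", c(40000, 40100, 40020), c(42000, 41800, 41900)),
    make_pairs("S2", "2L", c(990, 1080, 1110), c(3010, 2890, 2960)))
  base <- call_duplications(p)
  for (i in 1:5) {
    perm <- p[sample.int(nrow(p)), ]
    expect_equal(call_duplications(perm), base)
  }
})

test_that("cross-strain clustering merges within 200 bp and not beyond", {
  calls <- data.frame(strain = c("S1", "S2"), chrom = "2L",
                      start = c(1000, 1150), end = c(3000, 3150),
                      n_pairs = c(3L, 4L))
  m <- cluster_across_strains(calls)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1000)
  expect_equal(m$end, 3150)        # maximum extent across carriers
  expect_equal(m$frequency, 2L)
  expect_equal(m$strains, "S1,S2")

  calls2 <- calls; calls2$start[2] <- 1250; calls2$end[2] <- 3250
  m2 <- cluster_across_strains(calls2)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$frequency, c(1L, 1L))
})

test_that("clustering is idempotent and symmetric in strain order", {
  calls <- data.frame(strain = c("S2", "S1", "S3"), chrom = "2L",
                      start = c(1050, 1000, 30000), end = c(3080, 3000, 32000),
                      n_pairs = 3L)
  m1 <- cluster_across_strains(calls)
  m_rev <- cluster_across_strains(calls[3:1, ])
  expect_equal(m1, m_rev)
  # re-clustering the merged calls changes nothing
  m2 <- cluster_across_strains(
    data.frame(strain = m1$strains, chrom = m1$chrom, start = m1$start,
               end = m1$end, n_pairs = m1$n_pairs))
  expect_equal(m2[c("chrom", "start", "end")], m1[c("chrom", "start", "end")])
})

test_that("a duplication containing a full transcript is a whole-gene duplication", {
  dups <- data.frame(chrom = "2L", start = 900, end = 3100)
  cls <- classify_structures(dups, toy_genes())
  expect_equal(cls$class, "whole_gene")
  expect_equal(cls$gene_id, "gA")
  expect_equal(cls$junction, "3100|900")
})

test_that("breakpoints inside two plus-strand genes make a chimera with correct donors", {
  # dup start inside gA (3' donor), end inside gB (5' donor)
  dups <- data.frame(chrom = "2L", start = 2000, end = 6000)
  cls <- classify_structures(dups, toy_genes())
  expect_equal(cls$class, "chimera")
  expect_equal(cls$gene_id, "gB,gA")   # 5' donor first
})

test_that("a captured 5' fragment next to intergenic sequence is recruited non-coding", {
  # dup from intergenic (3500) into gB: carries gB's 5' end; junction
  # partner at 3500 is intergenic
  dups <- data.frame(chrom = "2L", start = 3500, end = 6000)
  cls <- classify_structures(dups, toy_genes())
  expect_equal(cls$class, "recruited_noncoding")
  expect_equal(cls$gene_id, "gB")
  expect_equal(cls$portion, "5prime")
})

test_that("minus-strand genes mirror the fragment orientation", {
  # gC is minus strand: dup start interior captures [start, gene end] which
  # holds gC's 5' end (at the right), junction partner y = 12000 intergenic
  dups <- data.frame(chrom = "2L", start = 10000, end = 12000)
  cls <- classify_structures(dups, toy_genes())
  expect_equal(cls$class, "recruited_noncoding")
  expect_equal(cls$portion, "5prime")
  # dup ending inside gC captures its 3' portion: a plain gene fragment
  dups2 <- data.frame(chrom = "2L", start = 8000, end = 9500)
  cls2 <- classify_structures(dups2, toy_genes())
  expect_equal(cls2$class, "gene_fragment")
  expect_equal(cls2$portion, "3prime")
})

test_that("gene-desert duplications are intergenic and every dup gets a class", {
  dups <- data.frame(chrom = "2L", start = 3300, end = 4500)
  cls <- classify_structures(dups, toy_genes())
  expect_equal(cls$class, "intergenic")

  # a duplication spanning several genes yields one record per gene
  dups2 <- data.frame(chrom = "2L", start = 900, end = 7500)
  cls2 <- classify_structures(dups2, toy_genes())
  expect_setequal(cls2$gene_id, c("gA", "gB"))
  expect_equal(sort(cls2$class), c("whole_gene", "whole_gene"))
})

test_that("a duplication internal to one gene is a gene fragment", {
  dups <- data.frame(chrom = "2L", start = 1500, end = 2500)
  cls <- classify_structures(dups, toy_genes())
  expect_equal(cls$class, "gene_fragment")
  expect_equal(cls$portion, "internal")
})

test_that("whole-gene and fragment assignments are mutually consistent", {
  # gA fully contained, gB cut: gA must not appear as a fragment donor
  dups <- data.frame(chrom = "2L", start = 900, end = 6000)
  cls <- classify_structures(dups, toy_genes())
  a <- cls[cls$gene_id == "gA", ]
  expect_equal(a$class, "whole_gene")
  b <- cls[grepl("gB", cls$gene_id), ]
  expect_true(all(b$class != "whole_gene"))
})

test_that("simulator round trip: caller recovers injected duplications and classes", {
  # distinct duplications must sit farther apart than the 25 kb
  # single-linkage radius, as segregating duplications do at genome scale
  cfg <- sim_config(seed = 33, chrom_length = 200000, n_genes = 8,
                    n_strains = 3,
                    events = list(
                      list(type = "whole_gene", fold = 2, carriers = "S1"),
                      list(type = "chimera", fold = 3, carriers = c("S1", "S2")),
                      list(type = "de_novo", carriers = "S3")))
  sim <- simulate_coverage(cfg)
  pairs <- simulate_read_pairs(sim, jitter = 40)
  calls <- call_duplications(pairs)
  merged <- cluster_across_strains(calls)
  expect_equal(nrow(merged), nrow(sim$truth))
  ord <- order(merged$start)
  tru <- sim$truth[order(sim$truth$dup_start), ]
  expect_true(all(abs(merged$start[ord] - tru$dup_start) <= 40))
  expect_true(all(abs(merged$end[ord] - tru$dup_end) <= 40))
  expect_equal(merged$frequency[ord],
               lengths(strsplit(tru$carriers, ",")))
  # zero jitter recovers breakpoints exactly
  pairs0 <- simulate_read_pairs(sim, jitter = 0)
  calls0 <- cluster_across_strains(call_duplications(pairs0))
  expect_equal(sort(calls0$start), sort(sim$truth$dup_start))
  expect_equal(sort(calls0$end), sort(sim$truth$dup_end))
  # classification recovers every injected class
  cls <- classify_structures(
    data.frame(chrom = merged$chrom, start = merged$start,
               end = merged$end)[ord, ], sim$genes)
  for (k in seq_len(nrow(tru))) {
    got <- cls[cls$start == merged$start[ord][k], ]
    expect_true(tru$expected_class[k] %in% got$class)
  }
})
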