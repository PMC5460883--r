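---
title: "Methods: site-level expression-change detection from coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-level expression-change detection from coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covhmm)
```

## Why site-level testing

Gene-level differential expression testing presumes the transcript being
tested exists in the annotation. Structures created by tandem duplication
— chimeric fusions, duplicated gene fragments, promoters copied next to
untranscribed DNA — do not, and their breakpoints are usually imprecise.
`covhmm` therefore tests each genomic site: per-site read depth in one
sample strain is compared to a panel of reference replicates, and a
three-state hidden Markov model segments the chromosome into regions of
decreased, stable and increased expression. Everything downstream (block
calls, gene calls, de novo transcription calls, enrichment statistics)
consumes those per-site states.

## Normalization

Coverage differs between libraries for technical reasons, so each
chromosome is quantile normalized across all strains of a tissue,
reference replicates included: every sample's per-site coverage
distribution is mapped onto the cross-sample mean of order statistics.
Tied values receive the mean of the order-statistic targets over their
rank range, which keeps the transform deterministic; on tie-free input the
map is idempotent. Full quantile normalization is stronger than matching
only mean and variance; because the two readings differ, a z-score mode
(`quantile_normalize(..., method = "zscore")`) that matches first and
second moments only is kept as a configuration alternative, but the full
distributional match is the default and is what every result in this
package uses.

Reference replicates are summarized per site by their mean `mu` and their
unbiased (n−1) sample variance `sigma2`. With three replicates the choice
of denominator matters; the unbiased estimator is used because `sigma2`
feeds a variance formula, not a likelihood. A single replicate leaves the
variance undefined and is an error unless an explicit variance floor is
supplied.

## Emission model

For a site with reference mean `mu >= 0.5`, the natural-log fold change
`L = ln(max(x, 0.5) / mu)` is scored under three normal models with common
sd `s = sqrt(2 * sigma2 / mu^2)` (the delta-method approximation to the
sd of `L` under no change) and means `-c`, `0`, `+c`, where
`c = qnorm(1 - alpha/2) * s`:

* stable: `2 * (1 - pnorm(|L| / s))` — the two-sided tail probability
  under no change;
* up: `pnorm((L - c) / s)`;
* down: `1 - pnorm((L + c) / s)`.

Three numerical choices deserve comment.

**Orientation.** Describing each state's emission as "the probability of a
statistic at least as extreme" is direction-ambiguous for the shifted
states: read literally as an upper tail under the up-state's own
distribution it *decreases* in `L`, which misranks states for exactly the
sites that matter most. The package fixes the orientation so that each
state's score is the tail probability increasing toward that state's side
— the unique monotone assignment consistent with the state means
`(-c, 0, +c)`. This makes the up score nondecreasing and the down score
nonincreasing in sample coverage, with the stable score peaked at
`x = mu`, properties the test suite asserts. The literal reading is kept
behind `emission_params(orientation = "literal")` for comparison only.

**The critical shift.** `alpha` defaults to 0.05 two-sided
(`z = 1.959964`), the conventional significance level; it is exposed as a
parameter because nothing in the model pins it down.

**Degeneracies.** Zero sample coverage would give `L = -Inf`; flooring `x`
at `epsilon = 0.5` (half a normalized read, matching the low-coverage
threshold below) keeps it finite while still strongly favoring the down
state. Zero reference variance (constant replicate tracks) would give
`s = 0`; `sigma2` is floored at `1e-6`.

Where the reference is essentially silent (`mu < 0.5`), the fold-change
model carries no information, and a categorical rule applies: sample
coverage of at least 5 reads is clear activation and scores up at 0.95;
anything less scores stable at 0.95. The remaining 0.05 splits equally
between the other two states. Emissions are scores, not normalized
densities: the HMM uses them unnormalized, so only within-site relative
magnitudes matter.

## Chain and decoding

Initial probabilities are `pi0 = (0.05, 0.9, 0.05)` and the transition
matrix has 0.8 on the diagonal, 0.1 off: stable expression is a priori
most likely and states persist across adjacent sites. Very sticky chains
could bias against detecting changes, so `baum_welch = TRUE` re-estimates
`pi0` and the transition matrix by EM on the chain being decoded
(emissions stay fixed — they are the statistical model of the data). Both
quantities are re-estimated together; the transition matrix is what
changes materially in practice. The EM log-likelihood trace is attached to
the result and is nondecreasing, a property the tests assert on arbitrary
inputs.

Decoding is by forward-backward with per-site scaling (stable for chains
of 10^7+ sites), and the per-site state is the posterior argmax, which
maximizes the expected number of correctly called sites — the correct
target when each site is a separate test. Viterbi would optimize the joint
path instead and is intentionally absent. Exact posterior ties decode to
stable, the conservative no-change call. The forward-backward
implementation is checked against exhaustive enumeration over all `3^L`
paths on short chains.

## From states to calls

**Blocks.** Expression blocks are maximal runs of one non-stable state
spanning at least 50 contiguous bp. Contiguity is strict in genomic
coordinates: one interrupting site splits a run, and positions absent from
the depth table count as stable (the depth format omits zero-coverage
sites, and absent evidence should not join blocks). The 50 bp floor is
inclusive: a 50-site run qualifies, a 49-site run does not.

**Gene calls.** A gene — or, for chimeras, the duplicated 5' or 3' segment
of a gene, supplied via `regions` — is upregulated when at least 50% of
its annotated exonic bp inside the evaluated region lies in qualifying up
blocks. The fraction is computed on interval intersections, so splitting
an exon into abutting pieces cannot change it. Genes with zero exonic bp
in the region are excluded and logged. Calls are made per strain and
tissue; `aggregate_gene_calls()` unites them (a gene is upregulated if
called in at least one strain, and in aggregate if called in any tissue).

**De novo transcription.** An up block is a de novo call when it overlaps
no annotated exon, the reference mean coverage is at most 2.0 at *every*
site of the block (per-site, the stricter reading of "not above 2.0" —
a block mean would let single expressed sites hide), and it overlaps a
single tandem-duplication span by at least 200 bp in total. The overlap
floor is interpreted as the block∩duplication intersection length, the
only measurable reading. Raising the ceiling or lowering the floor can
only add calls; the tests assert this monotonicity.

**Enrichment.** Whether `k` upregulated genes out of `n` exceed the
genome-wide background up-site proportion is an exact binomial test,
two-sided by the minimum-likelihood convention (all outcomes no more
likely than the observed one), with a one-sided option. The default
background of 0.0526 is the study-scale genome-wide rate;
`background_rate()` recomputes it from any state track, either per tissue
or pooled — both are exposed because the choice is not forced by the
method.

## Duplications and structural classes

Tandem duplications are called from divergently oriented read pairs: at
least three whose anchors lie within 25 kb form a call, the span being the
outermost anchor extent (which also matches the 25 kb ceiling on
duplication sizes). Grouping uses a single-linkage scan over
coordinate-sorted pairs, so results are order-invariant; how to split
overlapping groups with 3–25 kb internal spread is genuinely
underdetermined, and single linkage within the span cap is the choice
made here. Calls overlapping any divergent pair in the reference strain
are dropped — the reference carries none of the segregating duplications,
so such loci indicate technical artifacts. Across strains, calls merge
when both breakpoints agree within 200 bp (start-to-start *and*
end-to-end; comparing only one breakpoint would fuse distinct nearby
events); the merged span is the maximum extent and the frequency the
carrier count.

A duplication of `[x, y]` inserts its copy head-to-tail, creating the
junction `y|x`. Classification per affected gene: a full transcript
(including both UTRs) inside the span is `whole_gene`; breakpoints
interior to a gene truncate it, carrying its 5' or 3' portion depending on
strand and side; a captured 5' fragment fused at the junction to another
same-strand gene's 3' fragment is a `chimera` (recorded as "5' donor, 3'
donor"); a captured 5' fragment whose junction partner is intergenic is
`recruited_noncoding` (the copied promoter can activate previously silent
sequence); other partial captures are `gene_fragment`; spans touching no
gene are `intergenic`. A duplication spanning several whole genes emits
one `whole_gene` record per gene, since the unit of counting is the gene.
When UTRs are missing from the annotation, whole-gene status falls back to
the transcript span with a logged caveat.

## Dosage statistics

Mean fold change over a segment is the ratio of mean sample coverage to
mean reference coverage with the *segment-level* reference mean floored at
one read — the floor modifies the denominator summary, not each site; a
per-site-floor mode exists for sensitivity analysis. Allele-specific
expression at putatively heterozygous SNPs is tested per strain by a
two-sided Fisher exact test of genomic vs RNA ref/alt counts, applied only
where both libraries have at least 10 reads; the screen is per-site at
0.05 without multiplicity correction because it feeds a filter, not an
inference: candidate sites significant in any strain *not* carrying the
duplication show duplication-independent ASE and are removed. Proportions
are compared by Pearson's chi-squared on the 2×2 table with 1 df and no
continuity correction (the uncorrected statistic matches the standard
closed form `n(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`). Tissue-bias
overrepresentation among duplicated genes is tested by resampling
same-sized gene sets 10,000 times without replacement; the one-sided
empirical p uses the add-one correction `(1 + hits) / (1 + replicates)`,
so the smallest reportable value is `1/(replicates + 1)` rather than an
impossible zero.

## The synthetic-data generator

`sim_config()` / `simulate_coverage()` emulate the data the pipeline
consumes: one chromosome of evenly spaced plus-strand genes, three
reference replicates and a set of sample strains, and a list of structural
events (whole-gene duplication at fold 1 — dosage sharing — or fold 2 —
additive dosage; chimera with configurable fold; de novo activation of
intergenic sequence; duplication-deletion with the change confined to the
modified interval). Defaults are the study conditions: 61× mean exonic
coverage, three replicates, negative-binomial site noise (size 100) with a
log-normal per-(gene, library) random effect (sd 0.05) that induces the
within-gene correlation real replicate tracks show — independent Poisson
noise per site would understate replicate variance and overstate the HMM's
power. Per-gene base expression levels are log-normal across genes
(log-sd 0.8, rescaled so the overall exonic mean is exactly the configured
value): real transcriptomes span orders of magnitude of expression, and
without that spread the coverage distribution is so homogeneous that
quantile normalization would compress genuine fold changes into the bulk.
Events are applied multiplicatively to coverage rather than via read-level
simulation, because the HMM consumes coverage, not reads; accordingly the
generator emits coverage on the *normalized* scale, and fits on simulated
tracks run with `normalize = FALSE`.

What the generator does not emulate: alignment and mappability artifacts,
strand- or isoform-structure in the reads, GC and positional coverage
bias, and biological variation between strains beyond the gene-level
random effect. Passing the recovery tests therefore demonstrates that the
algorithms implement their rules correctly at realistic coverage and
noise, not that the pipeline is robust to every artifact of real
libraries.

Divergent read pairs for injected duplications are emitted at the true
breakpoints with configurable uniform jitter (default anchors within
50 bp), at least three per carrier, and none for non-carriers; SNP count
tables plant heterozygous sites inside duplicated genes with balanced
genomic draws and RNA draws skewed only in carriers of events flagged with
`ase_skew`. `write_fixture_bundle()` writes the whole study as plain-text
files (depth TSV, GFF3, BED, TSVs) that round-trip exactly through the
package readers and are byte-identical under a fixed seed.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run the exhaustive
forward-backward cross-check on 200 chains of length ≤ 8 (6561 paths at
most), Baum-Welch recovery on a 10^5-site chain, detection on a 60 kb
chromosome with a 2,000-site doubled region, dosage buffering over 15
replicate 50 kb simulations, and duplication round trips on a 200 kb
chromosome whose events sit farther apart than the 25 kb linkage radius,
as segregating duplications do at genome scale. These sizes give stable
Monte-Carlo estimates (the Baum-Welch diagonal recovers within ±0.01 at
10^5 sites) while keeping a full run in tens of seconds; the
forward-backward core processes about 1.5×10^5 sites per second in pure
R, so whole-chromosome fits at real scale are minutes, not hours.

## Known limitations

* Emissions are scores rather than a generative likelihood, so the chain's
  "log-likelihood" is comparable across parameter settings on the same
  data but not across data sets.
* The 5'/3' fragment logic assumes collinear gene models; trans-splicing
  and nested genes are not handled.
* Duplication calling from read-pair records inherits the 25 kb
  single-linkage ambiguity for overlapping events; breakpoint-level
  assembly is out of scope.
* Gene-level calls use exon unions per gene, not per transcript, so
  isoform-specific changes are blended.
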