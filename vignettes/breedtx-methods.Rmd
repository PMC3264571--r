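---
title: "Comparing pooled RNA-seq transcriptomes: methods and design notes"
author: "breedtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing pooled RNA-seq transcriptomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedtx)
```

# The problem

When RNA from many animals of one population is pooled before sequencing,
each aligned base is a draw from the pool's allele-frequency distribution
rather than from a genotype.  `breedtx` compares such pooled transcriptomes
between populations ("breeds" throughout) at three levels:

1. **Sequence** — which transcribed bases are effectively fixed within each
   pool, which differ *between* pools, and what those differences do to
   protein sequence.
2. **Expression** — isoform and gene abundance (FPKM), upper-quartile
   normalized, with fold-change differential-expression calls.
3. **Splicing** — alternative-splicing event classes and a test of
   differential isoform usage based on the square-root Jensen–Shannon
   divergence.

Every stage is exercised end to end against a synthetic cohort with known
truth, generated by the package itself.

# Site calling from pooled pileups

`build_pileup()` tallies, per (breed, contig, position), read counts split
by base, strand, and whether the base quality reaches Q20.  Only primary,
uniquely mapped (`NH:i:1`), non-duplicate records contribute; spliced
alignments contribute nothing inside N-skipped introns; and the two mates
of a fragment are deduplicated so one cDNA molecule is counted once — ties
keep the higher-quality call.

`call_site()` classifies each site:

* **uncallable** — fewer than `min_coverage = 10` fragments;
* **polymorphic** — all three filters hold: (1) the second-most frequent
  base carries at least `minor_frac = 10%` of reads, (2) each of the top
  two bases is seen on *both* strands with quality ≥ `min_qual = 20`,
  (3) the top two bases jointly account for ≥ `top2_frac = 90%` of reads;
* **monomorphic** — the minor fraction is below 10%, the top base alone
  reaches the 90% dominance bound and has two-strand quality support; its
  base becomes the site's consensus;
* **ambiguous** — everything else.

The explicit `ambiguous` state is a design choice: "does not vary within
the pool" needs a positive definition, otherwise low-quality or
strand-biased sites would leak into the between-breed comparison as fake
fixed differences.  The quality filter applies to base quality only;
mapping uniqueness is already enforced by the `NH` filter.  Ties among
equally frequent bases are broken in the fixed order A < C < G < T so
calls are deterministic.

A consequence worth knowing: under FR paired-end geometry (forward-strand
read on the genomic-left end of each fragment, reverse on the right), the
genomic-leftmost `read_len` transcribed bases of a locus can only ever
receive forward-strand reads.  The two-strand criterion therefore abstains
there.  This is the filter working as intended — such sites genuinely lack
strand-independent evidence — and the synthetic generator accounts for it
(below).

# Between-breed divergence and coding effects

`cross_breed_differences()` restricts to sites called monomorphic in
*every* breed (the "determinable" base set) and reports each site whose
consensus bases differ between at least one breed pair.  Effects are
annotated by locating the position in the CDS of a transcript, rebuilding
the codon on the transcript strand, and translating reference versus
alternate codon with the standard genetic code: synonymous,
nonsynonymous, stop_gained or stop_lost.  When several transcripts' CDS
overlap a position, the longest CDS wins, ties broken by transcript id —
one deterministic effect per site.

Two auxiliary filters mirror common practice in this kind of survey: a
gene passes `genes_with_cds_coverage()` when at least half of its CDS
bases (union over isoforms) are covered by ≥ 10 deduplicated fragments
(boundary inclusive), and `flag_intergenic()` marks intervals at least
1,000 bp from any annotated gene on either strand (inclusive; overlap is
distance zero).

# Expression

Fragments are assigned to isoforms by compatibility: every aligned block
must fall inside the isoform's exons and every used splice junction must
match an exon-exon junction of that isoform.  Ambiguity classes (sets of
compatible isoforms) are resolved by a small per-gene EM on the isoform
origin proportions; the log-likelihood is non-decreasing by construction
and iteration stops at a relative change of `1e-8` or 1,000 iterations.
FPKM uses the isoform's exonic length: `count / (l/1e3 * N/1e6)` with `N`
the library's mapped fragments.

Between-library scaling uses the upper quartile (75th percentile, linear
interpolation at rank `1 + 0.75 (n - 1)`) of the library's nonzero gene
values, rescaled by the geometric mean of all libraries' factors.

With a single library per breed there is no replicate-based dispersion to
estimate, so differential expression is tested with a two-sided Poisson
likelihood-ratio test with library-size offsets — an intentionally simple
model whose calibration under its own assumptions is verified in the test
suite (type-I error 5% ± 1.5% at 2,000 null genes).  The fold change is
`log2((countB/NB)/(countA/NA))`; a 0.5-fragment pseudocount enters only
when a count is zero and only for display — inference always uses raw
counts.  Genes are significant at |log2FC| ≥ 1 and Benjamini–Hochberg
q < 0.05.  Detection for breed-specific calls defaults to FPKM > 0 (any
evidence), deliberately configurable because breed-specific transcripts
tend to sit near the detection limit, where the rule matters.

# Splicing

The analysis is restricted to genes whose isoforms all share one
transcription start site (strict coordinate equality) and that express at
least two isoforms; within such a TSS group, alternative first exons
cannot occur, and the remaining differences fall into six classes:
exon skipping, alternative 5′ splice site, alternative 3′ splice site,
intron retention, mutually exclusive exons, and alternative last exon.
Classification compares intron chains of isoform pairs in
transcript-strand orientation, with containment/retention patterns claimed
first, then mutually exclusive and terminal-exon patterns, and shared-end
intron pairs last — this precedence keeps, say, the two introns flanking a
skipped exon from being double-reported as splice-site alternatives.
Events are deduplicated across isoform pairs by (category, sorted
coordinates).

Differential usage between two breeds is measured on the isoform-usage
distributions (EM expected counts, normalized) with the square root of
the Jensen–Shannon divergence, entropy in bits, which is a metric bounded
in [0, 1].  Significance comes from a multinomial bootstrap: pool both
breeds' counts, redraw pairs of samples of the original totals from the
pooled proportions `n_boot` times, and report
`p = (1 + #{null ≥ observed}) / (n_boot + 1)`.  The analytic variance
approximation used by assembly-based pipelines is deliberately replaced by
this bootstrap: it is calibrated under stated assumptions and directly
testable (type-I error 5% ± 1.6% at 1,000 null genes in the suite).
EM expected counts, rather than raw unambiguous counts, feed the test so
that all fragments inform relative abundance.

# The synthetic cohort

`sim_config()` + `simulate_genome_annotation()` + `spike_variants()` +
`simulate_fragments()` generate a complete study: a reference contig with
gene loci (every CDS starts ATG, ends with a stop, no internal stop, and
length divisible by 3), a configurable fraction of genes with a second
isoform sharing the TSS and skipping one internal exon, per-breed
haplotypes with spiked variants, and spliced paired-end SAM alignments
with qualities and `NH` tags.  Truth tables record every variant (with
its expected coding effect, verified in tests against an independent
codon table) and every isoform's fragment count.

Default conditions describe a small pooled study: 3 breeds, 20 genes,
75-bp reads on 150-bp fragments, 50× fragment coverage, 30 fixed
differences (half in CDS, including one premature stop that truncates the
final five amino acids of a gene, when a suitable codon exists), 30
within-breed SNPs per breed with minor fractions
{0.05, 0.08, 0.15, 0.2, 0.3, 0.5} straddling the 10% filter bound, and
base qualities 30/15 straddling Q20.

Choices that matter for interpreting test results:

* **Two fragment-placement modes.** `random` draws Poisson fragment counts
  and uniform starts, and samples minor alleles Bernoulli(`minor_frac`)
  per fragment — this is the mode whose allele fractions are binomially
  calibrated.  `tiling` places fragment starts deterministically at every
  multiple of a stride (clipped at transcript ends), giving *exactly*
  `frag_len / stride` coverage at every transcribed base, and assigns
  minor alleles by even spacing over the fragments covering a site, so the
  realised fraction is `round(n·f)/n`.  Tiling exists to separate filter
  logic from sampling noise: recovery claims ("every spiked variant is
  found") are only falsifiable when binomial fluctuation cannot push a
  true 15% site under the 10% filter by chance.
* **Two error modes.** `lowqual` gives every erroneous base quality
  `qual_low`, so the Q20 filter provably removes all errors — clean
  recovery tests; `realistic` draws quality independently of error
  status — robustness tests.
* **Strand-balanced placement.** Because of the FR dead zone described
  above, spiked variants are preferentially placed at positions reachable
  by both strands, and every truth record carries a `well_covered` flag;
  recovery is asserted on well-covered truth.  Variants a user places in
  the dead zone are not "lost" — they are visibly abstained from as
  `ambiguous`, never miscalled.
* Errors substitute uniformly among the three alternative bases; there
  are no indels, no PCR duplicates, no GC or positional bias, and a pool
  is one allele-frequency distribution per site rather than a set of
  individual animals.  Passing recovery tests therefore demonstrates the
  correctness of the calling logic, not robustness to every artefact of
  real libraries.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full chain at 20 genes ×
3 breeds × 50× coverage across 10 (tests) or 3 (acceptance script) seeds,
calibration at 2,000 null gene pairs (expression) and 1,000 null genes ×
2,000 bootstrap draws (splicing), and power screens at 200 genes (4-fold
shifts, 30× coverage) and 100 genes (usage (0.9, 0.1) → (0.4, 0.6) at 200
fragments per breed).  These sizes were chosen so that the slowest
property completes in minutes on one core while keeping Monte-Carlo
standard errors well inside the asserted bands.

Printed percentages round half-up at the printed precision (one decimal
for alignment rates, three for divergence rates), with a 1e-9 guard
against binary-representation ties.  Threshold comparisons in the caller
use a 1e-9 tolerance so that boundary cases (a minor fraction of exactly
10%, dominance of exactly 90%, 50% CDS coverage) fall on the inclusive
side, as the filter definitions state.  The EM treats a gene with no
fragments as all-zero abundance rather than an error, and
`diff_splicing_test()` refuses (flags, and excludes from FDR) genes with
an all-zero breed.

# Known limitations

* The Poisson DE test understates biological variance; with one library
  per breed this is explicit and unavoidable, and fold-change plus FDR
  thresholds should be read as descriptive, not inferential, for real
  cohorts.
* TSS assignment comes from the annotation; the package does not infer
  TSSs from read data, so "single-TSS" means single annotated TSS.
* The simulator emits alignments directly; read mapping, assembly and
  junction discovery are outside the package's scope, and their error
  modes are not emulated.
* Multi-gene-compatible fragments are counted for every compatible gene;
  overlapping gene models are not resolved by the EM across genes.
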