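---
title: "Methods: differential basecall error and 3' end statistics for nanopore DRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential basecall error and 3' end statistics for nanopore DRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Nanopore direct RNA sequencing (DRS) reads native RNA 3'→5' through a pore,
so covalent base modifications that the basecaller was never trained on —
above all N6-methyladenosine (m6A) — perturb the ionic current and surface
as systematic basecalling errors. Comparing per-position basecall profiles
between a condition in which the modification is present (e.g. a wild type
or complemented line) and a writer-mutant condition lacking it turns those
errors into a transcriptome-wide modification map, without antibodies and
on the same reads that carry poly(A) tail estimates, 3' end positions and
splice structure. `nanodrs` implements this differential-error test and the
downstream long-read analyses it enables.

# The differential error model

At every reference position with pooled coverage above the floor in each
condition, each covering read contributes exactly one of five basecall
categories: the called base (A, C, G, U) or *indel*. A deletion spanning
the position, or an insertion immediately following it, maps the position
to *indel* — the insertion overrides the base call, so the five categories
partition the reads. Intron gaps leave positions uncovered. This contract
is deliberate: it makes the per-position table a clean multinomial with
coverage-sum margins, which samtools-style pileups (which count insertions
*in addition to* the base call) do not.

The test at each position is a likelihood-ratio (G) statistic on the
2 x 5 table of condition-aggregated category counts:

$$G = 2\sum_{ij} O_{ij}\,\ln(O_{ij}/E_{ij}),$$

with expectations from the row/column marginals, zero-total columns dropped
(reducing the degrees of freedom), and the p-value from the upper
chi-square tail. No Williams or Yates correction is applied. Positions
where all counts fall in one category are untestable.

**Replicate homogeneity.** A position can differ between conditions merely
because one replicate misbehaves (RNA degradation, pore artefacts). For
positions passing a p < 0.05 prefilter, a within-condition G statistic is
computed on the replicate x 5 table of each condition; if the sum of these
homogeneity statistics exceeds the between-condition G, the between-signal
is weaker than the replicate noise and the position is dropped. Conditions
with a single replicate contribute zero.

**Multiple testing.** Benjamini–Hochberg correction is applied across *all*
G-tested positions; the prefilter and homogeneity filter then gate which
corrected positions may be called. Correcting only the prefiltered
survivors — a reading the method description also admits — destroys false
discovery control entirely: under a complete null the surviving p-values
are uniform on [0, 0.05], and the step-up over that subset flags nearly all
of them. The package therefore corrects over the full tested universe; a
null experiment with four replicates per condition and >50 kb of tested
positions yields a q < 0.05 fraction at or below the nominal level (this is
asserted by the test suite).

**Effect size and direction.** The mismatch:match ratio change is reported
as a Haldane-corrected log2 fold change,

$$\mathrm{log_2FC} = \log_2\frac{(mm_R + 0.5)/(m_R + 0.5)}{(mm_M + 0.5)/(m_M + 0.5)},$$

where *R* is the modification-positive condition, *M* the mutant, *m* the
reference-base count and *mm* everything else including indels. The 0.5 is
added unconditionally, so the value is finite for every count configuration
and antisymmetric under swapping conditions. Values above 1 mean the error
rate is at least two-fold reduced in the mutant — the signature of a lost
modification. Significant sites require q < 0.05 and |log2FC| > 1.

Called sites are padded by 5 nt, unioned, and reported with their genomic
sequence for motif analysis; the expected m6A context (AAACU/AAACA-like)
can be confirmed by PWM scanning.

# Phasing with poly(A) site choice

Because each read carries both its basecalls at a site and its own 3' end,
modification state can be tested for association with poly(A)-site choice
*per molecule*. Reads overlapping a called site are clustered by 3' end:
the single-base end histogram is convolved with a Gaussian kernel
(sigma = 13 nt, the measured 3' alignment error of DRS; kernel truncated at
±4 sigma), cut at strict local minima of the smoothed density (plateau ties
cut at their leftmost base), and clusters with fewer than 10 reads are
discarded. The cluster x 5 basecall table at the site is then tested with
the same G machinery, BH-corrected across sites; pairwise 2 x 5 follow-ups
identify which clusters differ.

# 3' end and poly(A) tail statistics

**Differential 3' usage.** Per gene, the two conditions' 3' end coordinate
samples are compared with a two-sample Kolmogorov–Smirnov test (asymptotic
p; single-base data are heavily tied, for which the asymptotic tail is
conservative). The *location* of the change comes from the difference of
the conditions' probability-normalised single-base histograms: its maximum
is the position of most increased usage, its minimum the most reduced, and
the strand-aware signed distance between them (negative = proximal) is the
shift. The difference profile is Gaussian-smoothed (default sigma 5 nt)
before taking extrema: unsmoothed single-base argmax is dominated by count
noise, while large bandwidths bias the extrema outward (for two sites
30 nt apart under 13 nt end noise the asymptotic extrema already sit
~2 nt outside the true sites, growing with the bandwidth). This is also why
a gene is only *called* shifted when |shift| > 13 nt, the 3' alignment
error range: localisation below that scale is not meaningful for this
platform. Ties in the extrema are broken toward the reference condition's
modal end, then toward the smaller coordinate. Genes are BH-corrected
jointly; enrichment of modified genes among shifted genes uses the
upper-tail hypergeometric test against all expressed genes.

**Tail lengths.** Per-read poly(A) tail estimates are consumed as numeric
BAM tags (default tag `pa`); per gene, conditions are compared with the
same KS test (default floor: 20 tagged reads per condition) and
BH-corrected.

**3' peaks, priming, over-splitting, collapsing.** Peaks are single-base
end positions with >= 3 supporting reads; nearest-peak distances are signed
(target − query). The internal-priming screen locates runs of six or more
adenosines (transcribed-strand sense, runs longer than six anchored at
their first base) in annotated CDS and counts reads terminating within
20 nt. Over-splitting — one molecule's signal split into consecutive reads
— is flagged when consecutive reads from the same pore channel align with
a gap of −10 to +1000 nt on the same strand. Isoform collapsing groups
reads by exact intron chain and subdivides by 3' end with the same
clustering at sigma = 100 nt, keeping the longest read as representative.

# Chimeric readthrough RNAs

A read overlapping two or more *adjacent* same-strand gene loci, each by
more than 20% of its aligned length, is chimeric and attributed to the most
upstream gene; reads touching user-excluded loci (e.g. tandem duplicates,
which alignment cannot distinguish from readthrough) are dropped, as are
multi-gene reads whose loci are not adjacent. Per gene, 50 subsamples of
75% of each condition's reads (without replacement) give Haldane-corrected
chimeric:non-chimeric ratios; since reads are exchangeable given their
binary label, the subsampled chimeric count is drawn from the
hypergeometric distribution, which is exactly equivalent to resampling
reads. The two ratio distributions are KS-tested, all 2500 cross-condition
bootstrap pairs estimate the fraction with a strictly >2-fold increase, and
a gene is flagged only if it has more than one mutant chimeric read, >50%
of bootstrap pairs exceed 2-fold, and the BH-corrected KS p is below 0.05.

A caveat the user should understand: the bootstrap samples are resamples of
the *same* data, so the KS p-value is strongly anticonservative whenever
the observed counts differ — a null gene with 0 reference and 2 mutant
chimeric reads is nearly always "significant". The three-part rule
controls false flags only because chimeras are rare: the null flag rate is
bounded by the probability of >= 2 chimeric reads arising by chance, which
stays below 5% for background readthrough rates up to roughly 0.5% at
typical per-gene depths. At substantially higher background rates the rule
is anticonservative by construction.

# Motifs and junctions

PWMs are additive score matrices (tab-delimited files or minimal MEME
motif files, converted to log2 odds); scanning reports per-offset sums,
ambiguous bases scoring the position mean, with a default threshold of 60%
of the maximum attainable score. The poly(A)-signal family is AAUAAA plus
all 18 single-substitution hexamers minus AAAAAA (18 total). Positional
enrichment around modification motifs counts hexamer starts per offset in
equal-length windows and compares with the median count over
dinucleotide-preserving shuffles, as
log2((observed + 0.5)/(median expected + 0.5)); the 0.5 guards zero
medians. Shuffles are random Eulerian paths on the dinucleotide transition
multigraph (edge lists randomly permuted, dead ends retried), which
preserves the dinucleotide multiset and both terminal nucleotides exactly;
like the classic Altschul–Erickson construction it is not exactly uniform
over Eulerian paths, which is immaterial for a median-based null.

Splice junctions are unique (donor, acceptor, strand) triples from read
intron chains, opposite strands counted independently. Classification
scores the donor window (3 exonic + 10 intronic nt) and acceptor window
(14 intronic + 3 exonic nt) against user-supplied U2 and U12 donor/acceptor
PWMs; positive raw scores are normalised to 50–100 by linear scaling
against the PWM's maximum attainable score (the one interpretive step in
this module — the normalisation used by the published matrices is cited,
not specified), non-positive scores are left unnormalised, U12 (donor > 75
and acceptor > 65) is tested before U2 (both > 60), and GT..AG borders
define canonicity. The frameshift screen keeps reads covering both
annotated start and stop codons, measures the ORF interval's spliced length
along the read blocks, and flags lengths not divisible by three — splice
events that shift the stop codon out of frame and are candidate
nonsense-mediated decay substrates.

# The synthetic-data generator

All statistics are validated against seeded simulations with planted
truth. The generator works at the pileup level — per read, per covered
position, a basecall category is drawn — because everything under test
consumes pileups; raw current is out of scope. Defaults describe the study
conditions used throughout the tests: 20 genes of 1–3 kb on one
chromosome, 4 replicates x 2 conditions, 100–300 reads per gene per
sample, background per-base error of 3% mismatch / 1.5% insertion / 2.5%
deletion (DRS-like), one planted AAACU-motif site per gene with mismatch
probability 0.30 in the modification-positive condition vs 0.05 in the
mutant, 3' ends jittered with sd 13 nt, poly(A) tails from a 20/40/60 nt
mixture, and configurable planted 3' shifts, chimera rates, over-split
pairs and intron chains, each recorded in truth tables.

Two generator choices deserve emphasis:

* **Neighbourhood signature.** Roughly five nucleotides occupy the pore at
  once, so a modified adenosine perturbs basecalls of surrounding
  positions, not just its own. Planted sites therefore elevate mismatch
  probability at the modified base and, with multipliers 0.5 and 0.25 on
  the excess, at its ±1 and ±2 neighbours. This is why called positions
  are matched to planted truth within a ±2 nt window, and it reproduces
  the qualitative behaviour of real constructs where several positions at
  the motif fire. With a strictly single-base effect, single-replicate
  detection at 60 reads per condition is only ~30–60% (one position must
  survive BH across the whole construct); detection power at moderate
  depth is genuinely a function of how widely the modification disrupts
  basecalling, and of stoichiometry.

* **Sharp vs noisy poly(A) sites.** For the planted 3'-shift experiments
  the two poly(A) sites are tight (sd 3 nt). Under the platform's 13 nt
  end noise, ±3 nt localisation of a 30 nt shift is asymptotically
  impossible (the difference-profile extrema are biased outward by the
  noise itself) — which is precisely the argument for the >13 nt call
  threshold.

What the generator does **not** emulate: basecaller-specific error motifs,
k-mer-dependent background error, raw signal, coverage biases along
transcripts beyond exponential 5' truncation, and genuinely novel splice
isoforms. Passing tests therefore demonstrate the statistics are correct
and calibrated under their stated model, not that the defaults match any
particular flow cell or basecaller version.

# Numerical and design notes

* Coordinates are 0-based half-open internally; 1-based only at file
  boundaries (BED/BAM conventions). A single-base site is a width-1
  half-open interval.
* The coverage floor (>10 reads, i.e. >= 11) applies to each condition's
  pooled replicates.
* Read-to-gene assignment uses aligned-block overlap with the gene *locus
  span* (not exon-restricted), strand-matched, strictly greater than 20%
  of the read's aligned length; reads may be assigned to several genes.
* Annotation flattening: exon outranks intron, CDS outranks UTR; UTR side
  is strand-aware relative to the transcript's CDS span; exons of CDS-less
  transcripts fall in the 3UTR class; ±200 nt flanks are
  upstream/downstream.
* `g_test` errors on tables with fewer than two positive rows; positions
  with a single populated category are untestable (no p) rather than
  zero-p.
* KS p-values are asymptotic in production; exact only on request for
  small untied samples.
* All stochastic stages (bootstraps, subsampling, shuffles, the generator)
  take explicit seeds and are reproducible; subsampling is without
  replacement.
* Problem sizes in the test suite (tens of kb of positions, hundreds of
  reads per gene, 200-repeat simulations) were chosen so the statistics
  under test are in their operating regime while the whole suite runs on a
  single CPU in minutes.

# Limitations

The method detects *differential* error: a modification present equally in
both conditions is invisible, and any systematic difference between
conditions other than the modification (basecaller version, flow cell
chemistry, RNA integrity) will surface as sites. The homogeneity filter
guards against single-replicate artefacts but not condition-confounded
batch effects. Fold-change orientation assumes the first condition carries
the modification; swapping conditions flips every sign. The chimera test's
bootstrap KS p-value is anticonservative (see above) and its three-part
rule should not be applied to backgrounds where multi-gene reads are
common for technical reasons. Poly(A) tail lengths are consumed as tags
and inherit whatever bias their estimator carries.
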