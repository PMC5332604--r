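---
title: "Methods: from virome assemblies to genome-based viral ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from virome assemblies to genome-based viral ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and numerical
choices: what each stage computes, which parameters matter, why defaults
are what they are, and what the synthetic-community tests do and do not
demonstrate about real data.

## The genome-wide similarity score

Viral taxonomy below the family level is effectively genome-based: two
phages belong together when their proteomes align over most of their
length. The package's central statistic, the genome-wide score
$S_G \in [0,1]$, reduces a six-frame translated all-against-all comparison
to a single normalized number per genome pair:

1. **HSPs.** A seed-and-extend local aligner compares all $6 \times 6$
   frame translations under BLOSUM62. HSPs below an E-value cutoff
   (default $10^{-3}$) are dropped.
2. **Tiling.** Per search ordering, HSPs are selected greedily by
   descending bit score; a candidate overlapping an already selected HSP
   on the query by more than 50% of its own length is discarded. This
   prevents repeated domains and near-duplicate frame hits from inflating
   the score while letting adjacent gene hits accumulate. The tiling rule
   is our choice; published descriptions of normalized-bit-score methods
   leave HSP aggregation open.
3. **Normalization.** With $\mathrm{raw}_{AB}$ the mean of the two
   orderings' tiled bit sums,
   $S_G = \mathrm{raw}_{AB} / \min(\mathrm{raw}_{AA}, \mathrm{raw}_{BB})$,
   clipped to $[0,1]$. The $\min$ denominator guarantees both quoted
   endpoints: an identical pair scores exactly 1 and a pair with no HSPs
   exactly 0. A geometric-mean denominator is available
   (`method = "geomean"`); both satisfy the endpoints, and averaging the
   two search directions makes the matrix symmetric by construction.

### The internal aligner

The aligner is deliberately desk-scale and is not output-identical to any
external search tool (which can substitute through the 12-column tabular
format at the `sg_from_hsps()` stage):

- seeds: exact 4-mer peptide words with a two-hit rule (second
  non-overlapping hit on the same diagonal within 40 residues triggers
  extension); nucleotide mode uses exact 11-mers, one-hit;
- extension: ungapped, X-drop 20 (raw units; 16 for nucleotide), stopping
  at stop codons and frame boundaries — stops are chain-breaking, so
  translated alignments never read through a stop;
- statistics: ungapped Karlin–Altschul parameters, BLOSUM62
  $\lambda = 0.3176$, $K = 0.134$; nucleotide $+1/-2$ with
  $\lambda = 1.3327$, $K = 0.621$; bit $= (\lambda R - \ln K)/\ln 2$,
  $E = mn\,2^{-\mathrm{bit}}$ with $m, n$ the translated residue counts.

No gaps are modelled. The synthetic communities evolve by substitution
only (below), so ungapped extension recovers the planted homology in full;
on real data, indels fragment HSPs and $S_G$ between distant relatives
will be conservatively low. Within-pair determinism is exact: the same
inputs give byte-identical HSP tables.

## Genome catalog

**Circularity.** An assembler emits a circular genome as a linear contig
whose 3' end repeats its 5' start. `detect_circular()` seeds exact 15-mers
from the first 50 bp of the contig inside a terminal window of
$\min(5\,\mathrm{kb}, 20\%)$ at each end, evaluates each implied ungapped
suffix–prefix overlap without end gaps, and calls circular when the best
overlap is at least 50 bp with identity strictly above 94%. Both
inequality directions are deliberate: a 49-bp exact repeat and a 94.0%
overlap are rejected. The duplicated terminus is trimmed and both lengths
reported — whether to trim is not standardized, so we report both. The
call is invariant to rotation of the underlying circular genome and to
reverse complement (property-tested).

**Size filter.** Strictly greater than 10 kb, the size regime where a
dsDNA virus contig can plausibly be a complete genome.

**Redundancy.** Nucleotide HSPs between a pair are projected on the
shorter genome; coverage uses the interval union (overlaps not double
counted) while mean identity is the alignment-length-weighted mean over
all unmerged HSPs — weighting is our determinate reading of "average
identity". Redundant pairs (coverage ≥ 80%, identity ≥ 95%) are collapsed
by single-linkage; the representative is the longest member (ties by id),
a choice that is configurable because nothing in the procedure forces it.

## Read quality control

Order is fixed: (i) exact-duplicate pair removal (both mates identical,
qualities ignored), (ii) pair merging, (iii) quality filter, (iv)
complexity filter. Merged reads are kept reads, so they pass through
(iii)–(iv) like any other read — the most consistent reading of "merged
and unmerged reads were kept". A pair losing one mate in (iii) or (iv)
keeps the other as a single read.

- Merging: best 3' overlap ≥ 10 bp with mismatch density ≤ 0.25 (the
  published defaults of the common merger); disagreements resolve to the
  higher-quality base, ties to the forward mate.
- Quality: a position is high-quality when Phred > 30 (strictly); a read
  is removed when the high-quality fraction is below 80% (exactly 80%
  passes). These boundary semantics follow the stated inequality
  directions verbatim.
- Complexity: a DUST-style scan scores each 64-base window by
  $10 \sum_t c_t(c_t-1)/2 \,/\, (k-1)$ over triplet counts $c_t$
  ($k$ = triplets per window) and masks windows scoring above 20; masked
  intervals are unioned with ambiguous bases, and a read is removed when
  the union exceeds 40% of its length. A homopolymer masks completely;
  random sequence scores ≈ 5, far below threshold.

The QC report counts in reads (a merged unit stands for its two inputs),
so conservation — every input read ends up kept or removed exactly once —
is an exact identity, and QC is idempotent on its own output.

## SNPs and nucleotide diversity

Pileups count only aligned bases with Phred > 30, the same guard against
sequencing error used for the filters above. A position is evaluable at
coverage ≥ 5. The six criteria apply to the count $n_2$ of the
second-most-frequent base (ties broken in fixed order A < C < G < T, a
determinate convention the procedure itself leaves open): (i) $n_2 \ge 1$,
(ii) $n_2 \ge 2$, (iii) $n_2 > 10\%$ of coverage, (iv) $n_2 > 20\%$,
(v) = (iii) ∨ (ii), (vi) = (iii) ∧ (ii), with "more than" strict. The
implication lattice (vi ⇒ ii ∧ iii ⇒ i; v = ii ∨ iii) and the induced
rate orderings are property-tested on random pileups.

Nucleotide diversity uses the unbiased per-site estimator
$\pi_{\mathrm{site}} = \frac{C}{C-1}\bigl(1 - \sum_b (c_b/C)^2\bigr)$,
which equals the all-pairs mismatch fraction of the reads at that site
(verified to $10^{-12}$ against explicit pair enumeration); the genome
value is the mean over evaluable sites, reported in percent. The exact
equation is in cited prior work rather than printed in the source study,
so the estimator is pinned by the all-pairs property instead. π shares
the ≥5× denominator with the SNP rates so the two statistics are
comparable per genome; the source text states the floor only for SNPs,
and we flag this as an interpretation.

## Proteomic tree

Distances are $d = 1 - S_G$. `bionj_tree()` implements BIONJ: the
neighbor-joining $Q$ criterion, with reduction weights
$\lambda = \tfrac12 + \sum_k (v_{jk} - v_{ik}) / (2(n-2)v_{ij})$ clamped
to $[0,1]$ and variance propagation
$v_{uk} = \lambda v_{ik} + (1-\lambda)v_{jk} - \lambda(1-\lambda)v_{ij}$.
Ties in the $Q$ minimization break at the lowest index pair, for
reproducibility. Negative branch estimates are clamped to zero with the
deficit moved to the sibling so path lengths are preserved (standard NJ
practice). On additive matrices the true topology and branch lengths are
recovered exactly (tested on random trees, $n \le 12$, error $< 10^{-9}$,
and cross-checked against an independent BIONJ implementation).
`midpoint_root()` places the root at the midpoint of the longest
leaf-to-leaf path, splitting the containing edge; displayed log-scaled
branch lengths are a rendering concern only (`write_tree(log_branches =)`),
stored lengths are untransformed.

## Genomic OTUs

Average-linkage agglomeration on $1 - S_G$, cut at height $1 - c$, so
cluster members are linked at average $S_G \ge c$; the boundary is
inclusive. Raising the cutoff only refines the partition (tested).
`scan_cutoffs()` evaluates a 0.01-step grid by adjusted Rand index against
a labeled reference; the argmax (ties to the smallest cutoff) is the
operating genus-level cutoff. Coarser grids (e.g. 0.1–0.9) are supported
through the `grid` argument. Richness uses bias-corrected Chao1
($S_{obs} + f_1(f_1-1)/(2(f_2+1))$, robust when $f_2 = 0$; classical form
optional) and analytic hypergeometric rarefaction with a percentile
bootstrap band (100 replicates, 95%).

## Host inference

For each labeled reference genome with at least one same-host-group and
one different-group partner, the best $S_G$ against each class is
recorded — two scores per eligible genome, which is how 1,285 eligible
genomes yield exactly 2,570 scores. The precision curve slides a cutoff
in $10^{-4}$ steps (matching the 4-decimal granularity at which operating
cutoffs are conventionally reported); precision is undefined, not zero,
above all scores. The operating cutoff is the smallest grid value whose
precision strictly exceeds the target and stays above it wherever defined
at larger cutoffs; predictions then inherit the best labeled partner's
host group strictly above the cutoff. BBH orthology uses protein best
hits at $E < 10^{-5}$, mutual-best pairs, ties broken by longer alignment
then id; $B_g$ is the percentage of query genes with an ortholog, with
≥60% read as nearly complete colinearity.

## Abundance

Fragments (a merged read or a read pair each count once) go to their
single best-scoring genome, ties split equally — the counting unit is our
choice, as the source procedure does not state one. FPKM is
$c / ((L/10^3)(N/10^6))$. gOTU abundance sums member FPKMs per sample,
first averaging any declared sample group (e.g. nine local replicates)
into one pseudo-sample to avoid regional bias, then averages across the
resulting samples; normalized abundances scale to sum to 100. Recruitment
applies the E-value filter first, then identity ≥ 60% and query coverage
≥ 80%; recruited fractions are monotone in the target set.

## The synthetic community generator

The generator defines the conditions under which the pipeline is tested.
A community root genome (default G+C 0.45, lengths drawn per genus from
15–60 kb) carries non-overlapping ORFs (default 0.7 genes/kb, 150–400
codons, either strand, stop-free bodies) placed once on the root so
orthology is traceable by descent. Each genus ancestor receives half the
between-genus divergence (default 0.5 substitutions/site between
ancestors) from the root; each genome receives the within-genus divergence
(default 0.05) from its ancestor. Substitutions are uniform; there are no
indels by design, keeping alignment oracles exact. Host groups label
consecutive genera; redundant pairs are near-copies at 2% divergence;
circular artifacts append the first `repeat_bp` bases after an arbitrary
rotation; reads are drawn uniformly with Gaussian insert sizes, optional
planted biallelic sites carried per fragment at a set frequency,
per-base substitution errors, position-decaying Phred qualities, and
exact duplicate pairs. A fixed seed gives byte-identical output.

What passing tests therefore show: the statistics, thresholds and
clustering behave exactly as specified on substitution-divergent,
uniformly covered, indel-free communities. What they do not show:
robustness to indels and rearrangements, chimeric assembly, instrument-
specific error profiles, skewed abundances, or contamination — none of
which the generator emulates.

## Problem sizes and numerics

The test suite exercises the genus-cutoff recovery at the calibration
scale of 345 genomes in 82 genera (15-kb genomes; the all-against-all
translated search takes well under a minute in compiled code), host
precision over 20 seeded communities (12 genera, 6 host groups), BIONJ on
200 random additive matrices, the SNP lattice on 10,000 random columns,
and π against brute-force pair enumeration at coverage ≤ 30. Degenerate
inputs are signalled rather than silently handled: zero self-score,
all-ambiguous sequences, genomes without evaluable sites, unreachable
precision targets, and all-zero abundances each raise a condition.

Known limitations: ungapped alignment only; E-values use simple length
products rather than finite-size corrections; the DUST scan masks whole
windows rather than minimal intervals; FPKM assumes the best-hit fragment
assignment; and the aligner's sensitivity below ~30% amino-acid identity
is limited by exact 4-mer seeding, which is precisely why distant-pair
$S_G$ values are conservative.
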