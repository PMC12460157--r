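---
title: "Models and methods behind karyoburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyoburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoburst)
```

karyoburst packages five inference stages used to characterise fast-evolving
animal genomes — macrosynteny and chromosome fusions, duplication-burst
dating, Hi-C centromere inference, trans-splicing/operon annotation, and
gene-family gain/loss — together with seeded generators that produce inputs
with planted truth for each stage. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not establish about real data.

## Macrosynteny and fusion calling

**Model.** Orthology is reduced to mutual best hits: pair `(a, b)` is kept
iff `b` is the unique top-scoring target of `a` in the forward similarity
table and vice versa. Ties for best hit drop the gene — a conservative
choice, since a tied best hit usually reflects a recent duplication for
which 1:1 orthology is ill-defined. Score-descending ranking is assumed;
whether the scores are bitscores or transformed E-values is up to the
caller, as only the ranking enters.

Shared-ortholog counts per chromosome pair form an Oxford grid. Each cell is
tested one-sided (greater) with the Fisher exact test: enrichment, not
depletion, is the biological question when transferring ancestral linkage
groups. The p-value is the exact hypergeometric upper tail, computed with
`phyper` and verified in the test suite against an independent
log-binomial tail summation to 1e-12 on every 2x2 table with total at most
60. Cells with a zero margin are reported with p = 1 rather than an error,
so empty chromosomes do not break the grid.

**Multiple testing.** The correction applied across all grid cells is
Benjamini–Hochberg. A per-genome-pair BH at `alpha = 0.05` is the field
default for linkage-group analyses; family-wise corrections would be
needlessly conservative for grids with hundreds of cells, most of them
deeply non-significant.

**Reciprocity.** A cell is "reciprocal" when it is significant after BH and
is the lowest-q cell (ties broken toward the higher odds ratio) in its row
or its column. A fused chromosome legitimately hosts several significant
reference partners, so reciprocity cannot demand uniqueness in both margins;
requiring primacy in at least one margin keeps multi-BLG chromosomes intact
while discarding one-off noise cells dominated in both directions. The odds
ratio reported is the sample cross-product ratio (infinite when an off-cell
is empty), which is only used for tie-breaking and display.

**Mixing test.** Whether a fusion is "with mixing" is decided by a runs
test: genes on a multi-BLG chromosome are ordered by start coordinate and
labelled by their linkage group, and the number of label runs is compared
with a permutation null (label shuffles, default 1000). The chromosome is
called unmixed only when the observed run count falls in the lower 5% tail
— significantly blockier than random. This operationalisation is a design
choice of this package: mixing status is often asserted in the literature
without a quantitative criterion. Chromosomes with fewer than 10 labelled
genes are reported indeterminate (`mixed = NA`) because the runs null is
too coarse there.

**Filters.** Chromosomes with fewer than `min_genes = 5` orthologs are
dropped from the grid, suppressing scaffold noise; the threshold is
configurable.

## Duplication-burst dating (FDTv)

**Pair selection.** To avoid over-weighting large families, every gene is
counted in at most one pair: within each family, pairs are taken greedily in
descending score order. Greedy matching carries a 1/2-approximation
guarantee and in practice sits within a few percent of the exact
maximum-weight matching (checked in the suite against an exhaustive oracle);
`exact = TRUE` switches to the exhaustive search for families up to about a
dozen genes.

**FD sites and transversions.** A codon column is a fourfold-degenerate site
iff both codons are ungapped, encode the same amino acid, share an identical
two-base prefix, and that prefix is one of the eight fourfold boxes. This is
the strictest synonymous criterion; it deliberately excludes sites where
first- or second-position changes could confound third-position counting.
A transversion is a third-base difference across the purine/pyrimidine
boundary. FDTv is the ratio of transversions to FD sites, reported raw —
no multiple-hit correction is applied, because the quantity of interest is
the position of distribution peaks, not absolute time, and transversion
saturation is slow.

**Burst profiles.** Gaussian kernel densities (`stats::density`, default
bandwidth) are fitted per copy-number stratum; modes are local maxima above
10% of each stratum's maximum, and the "shared mode" verdict holds when the
primary modes of all strata lie within 0.05 of each other. Strata need at
least 20 defined FDTv values; in our experience kernel mode counting is
reliable from roughly a hundred pairs per stratum, and the bundled checks
use 100–500 pairs.

**Placement test.** The chromosome-pair matrix places each pair at
(chromosome of gene 1, chromosome of gene 2) — intentionally asymmetric,
since each pair is a single observation. Off-diagonal cells are tested with
the same Fisher machinery as the synteny stage and BH-corrected among
themselves. The decision rule "whole-genome duplication iff some chromosome
pair is mutually enriched and the intra-chromosomal fraction is below 0.1"
is deliberately blunt; it is meant for genome-scale bursts, where the two
signatures are essentially categorical. Separations of intra-chromosomal
pairs are measured midpoint-to-midpoint — at the 10 kb to 10 Mb scales of
interest the difference from start-to-start is negligible.

**Intron test.** Retrotransposed copies lack introns, so the intron counts
(`exon_count - 1`) of duplicated genes are compared with the remaining genes
by a two-sided Mann–Whitney test. This requires the annotation to carry
exon counts; the function refuses to guess.

## Hi-C architecture

**Map resolution** follows the standard rule: the smallest bin size at which
strictly more than 80% of bins collect strictly more than 1,000 contacts.
Both inequalities are strict; a ladder where every size sits exactly at 80%
returns no resolution.

**Eigenvectors.** Matrices are normalised observed/expected per diagonal
(each diagonal divided by its mean) before Pearson correlation of columns
and symmetric eigendecomposition. O/E-then-correlation is the standard
treatment; it makes every downstream statistic invariant to uniform scaling
of the matrix (the raw-count resolution rule is scale-dependent by design).
All-zero bins are masked before correlation and carry NA in the profiles;
a constant or degenerate correlation yields a zero-column result rather
than an arbitrary vector.

**Centromere calling.** Published workflows often select "the eigenvector
that best captures centromere information" by eye. For testability the
selection is automated: among the leading eigenvectors (default 5), choose
the one with the fewest sign changes along the chromosome (at least one),
breaking ties toward the larger `|eigenvalue|` — the closest realisation of
a two-block arm bipartition. The centromere interface is the adjacent-bin
pair with the largest `|dEV|`, and the reported interval spans the two
flanking bins. A profile with no sign change yields an explicit no-call
(acrocentric or undetectable), not a forced interval. A manual
`eigen_rank` override is available for curated analyses.

**Permutation test.** The null relocates each repeat interval of a family
independently and uniformly along the chromosome, preserving lengths and
permitting overlaps — the simplest null consistent with randomising repeats
over a chromosome; preserving inter-interval spacing is a possible
alternative that is not implemented. Empirical p-values use the add-one
rule `(1 + #(null >= obs)) / (n_perm + 1)`, which guarantees p > 0 and is
standard permutation practice. Given the same seed and `n_perm`, results
are bit-identical. Only families that overlap at least one called
centromere are tested by default (`require_overlap = TRUE`); calibration
analyses disable the filter, because conditioning on positive overlap
biases the null p-value distribution.

**Insulation and saddle.** The insulation score at a bin is the log2 of the
mean contact count in the `w x w` diamond upstream-by-downstream of the bin,
normalised by the chromosome-mean diamond score; boundaries are local
minima, with strength measured as the smaller rise to the nearest flanking
local maxima, retained strictly above 0.5 by default. These definitions
reproduce the qualitative behaviour of the standard toolkits; exact
numerical parity with any one toolkit's insulation formula is not promised.
Saddle plots orient the eigenvector so that bins with above-median
open-chromatin peak counts have positive mean value, rank bins into
eigenvector quantile classes (default 50), and average O/E between classes;
orientation is idempotent under sign flips of the input, and with no peaks
on the chromosome the profile is returned unoriented and flagged.
Matrix balancing (KR) is out of scope — inputs are taken as provided.

## Trans-splicing and operons

**Splice-leader detection** mirrors k-mer read trimming practice: a read
matches when any 25-mer of any leader aligns to any 25-wide window of the
stored 5' sequence with Hamming distance at most 3 (ambiguous bases count
as mismatches); the best match wins, with ties resolved toward earlier
window position and leader order. Matching is anchored to the stored 5'
window (first 30 nt) because trans-splicing modifies only the 5' end. The
implementation is verified against an exhaustive Hamming scan.

**Thresholds.** A gene is trans-spliced with at least 5 leader-bearing
reads (inclusive). Operons chain consecutive same-chromosome genes whenever
the gap `next start - previous end` is strictly below 250 bp in 0-based
half-open coordinates (abutting genes have gap 0; overlapping genes have
negative gaps and are chained with a warning). Chaining is strand-aware by
default — operons are polycistronic and hence co-oriented — with
`require_same_strand = FALSE` available since published gene-distance rules
do not always state strandedness. Candidates have two or more genes;
validation requires at least one trans-spliced member. Cell QC keeps
boundary values: "fewer than 500 UMIs" removes 499 and keeps 500, and
likewise for the 20,000-UMI, 200-gene and 20%-mitochondrial rules.

**Specificity.** From cell-type-averaged expression, `cv = sd/mean` and
`tau = sum(1 - x_i/max(x)) / (n - 1)`; both are scale-invariant and
undefined (flagged) for all-zero genes. Open-chromatin peaks are assigned
to the gene with the nearest TSS within 10 kb, ties to the earlier gene in
coordinate order — a deterministic rule standing in for the various
"relative location toward genes" conventions.

## Gene-family events

**Dollo parsimony** is used for gain/loss inference: each family originates
exactly once — at the MRCA of the species carrying it — and may only be
lost thereafter. This matches the single-origination framing of gene-family
evolution and forbids convergent family birth; general (Fitch-style)
parsimony, which allows regain, is deliberately not offered. Losses are
placed on every branch leading to a maximal empty subtree within the gain
subtree, which is the minimal placement. Root-origin gains are counted on a
synthetic pre-root branch named `"root"` so they remain countable. The
implementation is checked against an exhaustive minimal-labelling oracle on
all presence patterns of 6-leaf trees. Dollo systematically undercounts
multiple hits on the same family (a deep loss plus independent shallow
losses collapse), so recovery against simulated truth is scored by rank
correlation, not equality.

**Lineage-specific families** are those present in at least `min_focal = 2`
focal species and absent from every non-focal species — requiring two focal
occurrences guards against annotation artefacts in a single genome.
**Phylostratum enrichment** is the exact hypergeometric upper tail of the
marker/stratum overlap given the universe, BH-corrected across the full
cluster-by-stratum grid.

## The synthetic-data generators

All generators draw from sub-streams derived deterministically from one
root seed and a task label, so adding a call to a scenario never perturbs
unrelated outputs, and a fixed seed gives byte-identical results.
Coordinates are 0-based half-open throughout. Gene lengths and intergenic
gaps are log-normal (defaults ~2 kb genes, ~1 kb gaps, sdlog 0.5), matching
compact invertebrate genomes.

* **Ortholog genomes** place one chromosome per linkage group in the
  reference genome and realise a fusion plan in the query: fused
  chromosomes carry all genes of their group set, interleaved at random
  when mixed, as contiguous blocks otherwise; a noise fraction of genes is
  relocated uniformly. The default study condition used in the bundled
  checks is eight groups of 40 genes, three two-group fusions and 5%
  relocation noise.
* **Duplication bursts** support wgd (partner on the homeologous
  chromosome), tandem (same chromosome, separations drawn from a
  log-normal mixture at ~10 kb and ~10 Mb scales) and retro (intronless
  partners placed at random). Divergence at fourfold third positions uses a
  per-copy class-flip process: each copy's third base switches
  purine/pyrimidine class with probability `c` solving `2c(1-c) = r` for
  the planted pairwise rate `r`, with within-class transitions added at
  rate `2c`. This gives every pair in a family — not just a designated
  pair — an exact expected FDTv of `r`, at the price that attainable rates
  are below 0.5 (the process saturates at `c = 0.5`); the generator
  validates `r < 0.5` accordingly.
* **Contact maps** draw Poisson counts around a power-law distance decay
  (exponent -1), attenuating cross-arm contacts by a configurable factor —
  the simplest model exhibiting the two-block arm correlation structure.
  Repeat families are placed with a stated centromere enrichment factor;
  factor 1 is exactly uniform. Recovery checks use 100 bins, the centromere
  at bin 40 and attenuation 0.3 over 50 seeds.
* **Splice-leader libraries** attach a uniformly chosen leader to a
  configurable fraction of reads of trans-spliced genes with per-base
  substitution noise; checks use 20 reads per gene, a 0.6 leader fraction
  and 1% error.
* **Family evolution** plants Poisson(`gain_rate`) gains and
  Poisson(`loss_rate`) losses per branch (each loss removing one family
  present at the parent). Rates are event counts per branch, not per-family
  probabilities; the bundled recovery check uses 200 root families and
  rates of 0.5 on an 8-leaf tree.

**What the generators do not emulate.** Sequence composition and codon
usage are uniform random; read quality strings, alignment artefacts,
mapping ambiguity and assembly errors are absent; Hi-C matrices carry no
balancing biases, no compartment checkerboard beyond what is planted and no
trans contacts; similarity scores are noiseless identity fractions.
Passing the bundled checks therefore establishes the correctness of the
inference logic under its stated model, not robustness to the full error
structure of real libraries — on real data, upstream QC and alignment
quality still dominate.

## Numerical notes and degenerate inputs

* Strict-versus-inclusive boundaries follow the stated rules everywhere:
  map resolution (strict >1,000 and >80%), operon gaps (strictly < 250),
  trans-splicing (>= 5 reads), Hamming distance (<= 3), QC bounds
  (boundary values kept), boundary strength (strictly > 0.5).
* Fisher p-values come from `phyper` (exact), not from a normal
  approximation; equality with brute-force tail sums is asserted at 1e-12.
* Eigenvector sign is arbitrary; all consumers (centromere interface,
  saddle orientation) are sign-aware.
* Degenerate inputs return flagged results rather than errors where the
  spec of the quantity allows it: constant contact matrices (no informative
  eigenvector), all-zero expression profiles (undefined tau/cv),
  chromosomes with too few labelled genes (indeterminate mixing), zero
  FD-site alignments (undefined FDTv).
* Permutation and simulation results are reproducible bit-for-bit given
  the seed; the acceptance script derives all its sub-seeds from the single
  `--seed` argument.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
desk scale, chosen to finish in minutes on one CPU while keeping the
statistical checks well-powered: 20 fusion scenarios of 320 orthologs; 500
paralogue pairs per planted rate; 40 duplication simulations of 150
families; 50 contact maps of 100 bins; 200 permutation-calibration labels
at 200 permutations; 200 gene models for the operon stage; 200 root
families on an 8-leaf tree. Chromosome-scale real datasets are larger by
two to three orders of magnitude but exercise identical code paths.

## Known limitations

* The mixing runs test and the WGD/tandem decision rule are calibrated for
  clear-cut cases; partial or ancient signals need judgement.
* FDTv carries no multiple-hit correction and saturates for old bursts.
* The Hi-C stage assumes cis matrices, one chromosome at a time, and does
  not balance matrices.
* Dollo parsimony cannot see regain and undercounts repeated losses.
* The operon caller trusts the gene models; fragmented annotations will
  split operons.
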