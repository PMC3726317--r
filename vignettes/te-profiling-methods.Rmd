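---
title: "Methods: TE profiling from low-coverage shotgun reads"
author: "teshot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE profiling from low-coverage shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the tunable parameters and their defaults,
the numerical choices made where the design was genuinely open, and what
the simulation-based validation does and does not demonstrate.

## 1. The model

The pipeline treats short-read coverage of a reference contig as a
copy-number meter. If reads sample the genome uniformly at single-copy
depth $d$, then a TE family present in $c$ near-identical copies
contributes about $c \cdot d$ coverage to its reference contig, because
reads from every genomic copy map onto the one family consensus. The
relative copy number

$$\widehat{c}_f \;=\; \frac{\overline{\mathrm{cov}}_f}{\frac{1}{U}\sum_{u=1}^{U}\overline{\mathrm{cov}}_u}$$

divides the family contig's mean per-position coverage by the mean over
$U$ ultra-conserved orthologous sequences (UCOS), single-copy genes that
estimate $d$ from the data itself. This cancels library size, read length
and (to first order) mappability, and requires no genome assembly.

Assumptions worth keeping in view:

* *Uniform sampling.* Fragment starts are taken as uniform; GC bias and
  library artefacts in real data will propagate into $\widehat{c}_f$.
* *Within-species mapping.* The meter only works when reads can actually
  reach the mismatch ceiling of the mapper. Raising per-copy divergence
  degrades coverage long before it degrades the underlying truth — this
  mapping bias is a central, deliberately reproduced phenomenon (section
  7.2), and the reason the de novo clustering route exists.
* *Copies are full-length.* Coverage converts to genome fraction via
  $\widehat{c}_f \cdot L_f / G$ with $L_f$ the consensus length; truncated
  or nested insertions in real genomes blur this.
* *Edge ramps.* A contig's first and last read-length of positions are
  reachable by fewer read placements, so mean coverage under-measures depth
  by roughly $(1 - \ell/L)$ for read length $\ell$ and contig length $L$.
  The ratio of a long TE contig to short UCOS contigs therefore carries a
  small upward bias (a few percent for 60 bp reads on 1.5 kb UCOS). The
  validation panel uses 1.5 kb UCOS genes; users with shorter baseline
  contigs should expect a correspondingly larger bias.

## 2. Read preparation

`trim_reads()` removes terminal bases with phred quality below
`q_min = 20`, iteratively from both ends — the maximal low-quality prefix
and suffix are removed; interior low-quality bases remain. This is the
plain reading of fixed-threshold end-trimming; it is *not* BWA's
error-sum heuristic, and results compared against BWA-trimmed data will
differ slightly at read ends.

`equalize_libraries()` builds the reduced, equalized datasets used by the
diversity and PCA stages: every read hard-clipped to its first
`target_length = 60` bases (3' clipping, since that is the low-quality end
on this platform generation; shorter reads dropped), every library
subsampled without replacement down to the smallest library's post-clip
count, the smallest library passed through intact, `n_replicates = 49` by
default. Subsampling is per-read; mate pairing is not preserved, because
all downstream mapping is single-end. Each replicate's random draw is
keyed on (seed, replicate index), so replicate $r$ is reproducible in
isolation.

## 3. Mapping

`build_index()` hashes every k-mer (default `k = 13`) of both strands of
every contig. `map_reads()` seeds each read at `n_seeds = 4` evenly spaced
offsets, extends every candidate placement ungapped across the whole read,
and accepts the fewest-mismatch placement if its mismatch count is at most
$\lceil 0.08 \cdot L \rceil$ (the `relaxed` preset raises this to 0.15 with
6 seeds, for mapping divergent reads to conserved element regions). Among
equal-best placements one is chosen uniformly at random under R's RNG —
discarding multi-mappers would systematically erase exactly the reads the
method is about, whereas random placement distributes them and preserves
family-level coverage. Such records carry `mapq = 0`.

Numerical notes: ungapped extension was chosen because coverage-based copy
number at these divergences is insensitive to the rare short indel, and it
keeps the mapper exactly analyzable; a seeded read is missed only when
every seed overlaps a mutation (probability $(1-(1-p)^k)^{n_\mathrm{seeds}}$,
about 6% at $p = 0.05$ — the test suite asserts both mismatch-count
agreement with an exhaustive sliding-window oracle and > 95% recall).
Alignments can be exported to and imported from minimal SAM text for
interoperability with external mappers; coordinates are 0-based half-open
internally and 1-based at the SAM and GFF3 boundaries.

`pileup()` accumulates, per contig position, total coverage (all aligned
bases) and A/C/G/T tallies restricted to bases with phred ≥ 20. Keeping
counts above the quality threshold rather than full per-read quality lists
is sufficient for every downstream rule and keeps memory linear in contig
length.

## 4. Variable sites, diversity, and feature partitioning

A site is **variable** iff its quality-filtered depth is at least
`min_depth = 7` (strictly more than 6 reads), some non-reference base has
at least `min_alt_support = 2` qualifying reads, and that base reaches
`min_alt_fraction = 0.2` of the filtered depth. The support/fraction pair
replaces legacy consensus-quality scores with two explicit, reproducible
knobs. A variable site may be a heterozygous SNP or divergence between
element copies; the pipeline makes no attempt to separate the two — that
ambiguity is intrinsic to mapping a repeat family onto one consensus.

Per-contig **nucleotide diversity** is the variable-site count divided by
contig length. For log-scale summaries, zero-variant contigs are floored
at $1/(2L)$ — half the smallest observable non-zero value — and the floor
is recorded alongside the value.

**Partitioning** assigns each variant on an annotated class I contig to
exactly one class by position, with precedence internal ORFs (GAG, AP, RT,
RH, IT, other) > LTR > outside; unannotated span is "outside". The report
carries counts, percentages of total (they sum to 100 by construction) and
per-bp rates (count / summed feature length). Only annotated contigs enter
the partition — families without recognizable features are excluded
entirely rather than lumped into "outside".

## 5. Fingerprinting by PCA

`assemble_fingerprint()` builds the samples × superfamilies matrix of
relative copy numbers. Superfamily totals sum member families' relative
copy numbers unweighted by length (a count-like quantity); genome
fractions, a base-pair quantity, use length weighting — both are exposed.
Zero cells are floored at half the smallest positive value in their column
so the log transform is defined; the floors are recorded in an attribute.

`run_pca()` applies the natural log, centers and scales columns to unit
variance, and decomposes with `prcomp`. Zero-variance columns are dropped
with a warning. Each component's sign is fixed so its largest-magnitude
loading is positive; with that convention, replicate PCAs can be compared
by plain score correlations without Procrustes rotation
(`replicate_pca()` reports sign-aligned |r| on PC1/PC2 against the
full-data PCA).

## 6. UCOS phylogeny

`consensus_sequences()` calls one base per site per sample: qualifying
depth at least `min_depth = 6` ("6 or more"), top allele at least 80% of
the filtered depth, otherwise N — heterozygous and thin positions become
missing data rather than guesses. Note the deliberate asymmetry with the
diversity stage: consensus building accepts depth 6 while variant calling
requires more than 6; each rule follows its own stage's definition and
both are configurable.

`filter_columns_and_loci()` converts N to gap, removes every column
containing any gap (nogap semantics), drops loci shorter than 50 retained
columns, and concatenates the survivors with a partition table (NEXUS
output with a character-set block).

Gene trees are neighbor joining on Jukes–Cantor-corrected p-distances
(p ≥ 0.75 is a saturation error). The species tree is **STAR**: each gene
tree is rooted on the outgroup; the root gets rank equal to the taxon
count and each internal child the parent's rank minus one (non-binary
nodes give all children equal rank); the distance between two taxa is
twice their MRCA's rank; distances are averaged over gene trees containing
both taxa; neighbor joining on the averaged matrix gives the topology.
Rank distances of concordant trees are ultrametric, which is why NJ
recovers the common topology exactly (asserted exhaustively on all 15
five-taxon topologies). Branch lengths are in rank units and are labelled
as such — they are not substitution estimates, and no model-based branch
length optimization is attempted.

The **multilocus bootstrap** resamples loci with replacement, keeping
sites within a locus intact: the locus, not the site, is the exchangeable
unit under coalescent variation among gene trees. Each locus's gene tree
(equivalently its rank-distance matrix) is computed once and reused across
replicates; supports are the percentage of replicate STAR trees containing
each bipartition of the point estimate, and a majority-rule consensus of
the replicates is returned too.

## 7. De novo clustering

### 7.1 Graph and communities

`build_read_graph()` finds candidate pairs through shared 17-mers (both
orientations), scores each pair's best ungapped overlap at the k-mer
diagonal, and adds an edge when identity ≥ 0.90 over ≥ 0.55 of the shorter
read; the weight is identity × overlap fraction. Two caps keep dense
satellite neighborhoods tractable: per-k-mer occurrence lists and
candidate partners per read are bounded, and candidates are collected in
both directions with global pair de-duplication so late-indexed reads of a
dense cluster still acquire edges. If the read set exceeds
`vertex_budget` (default 50,000), a seeded subsample is used and all
genome percentages are ratios of the reads actually used.

`louvain_clusters()` runs Louvain modularity optimization, then merges
communities whose total connecting edge weight reaches
`min_bridge_weight = 2`. The merge exists because modularity slices the
linear tiling graph of a long repeat into positional segments; a reported
repeat cluster should span the family, while two clusters joined by a
single incidental weak edge should stay apart. Setting
`min_bridge_weight = Inf` recovers the raw Louvain partition.

### 7.2 Reports, annotation, and the mapping-bias contrast

`cluster_report()` sorts clusters by size, reports genome percentage
(reads in cluster / reads used; the `cutoff = 0.01`% rule is boundary
inclusive) and annotates each cluster by k-mer containment of
representative reads against a user-supplied repeat library, falling back
to "low complexity" when a DUST-style triplet score exceeds its threshold
and "unknown" otherwise. Annotation is against a user library rather than
any licensed external database; at high consensus divergence k-mer
containment fades, which is expected — planted-truth evaluation in the
validation study attributes clusters by the majority origin of their
member reads instead.

The package's central methodological contrast is asserted on simulations:
with family consensus drifted 25% from the mapping reference (plus 5%
per-copy divergence), mapping-based genome fractions collapse essentially
to zero while cluster-based fractions stay within one percentage point of
the planted truth. This is the quantitative form of "mapping works within
the reference species; de novo methods work across species boundaries".

## 8. The synthetic-data generator

`build_reference()` draws an i.i.d. uniform A/C/G/T background and splices
in, at random non-overlapping points, one copy of each UCOS gene and
`copy_number` mutated copies of each family consensus (random strand).
Insertion rather than overwriting means genome size grows with TE content
— mirroring TE expansion driving genome size — and leaves the single-copy
space intact, making UCOS normalization exact by construction. Copies
differ from their consensus at Binomial($L$, divergence) sites,
substitutions only; an indel-free divergence model keeps mapping-based
recovery analytically predictable. Satellite consensus sequences are
tandem tilings of a short random monomer (12 bp default), which both the
overlap graph and the DUST detector treat the way real satellites behave.
Class I consensus layouts place two equal-length LTRs (12% of the element
each) around GAG/AP/RT/RH/IT ORFs with unannotated spacers; class II
layouts place a transposase between two TIRs.

`simulate_reads()` generates `round(depth × G / (2ℓ))` read pairs:
fragment starts uniform, insert sizes Gaussian (300 ± 30 bp, clamped),
forward mate from the fragment 5' end, reverse mate the reverse complement
of the 3' end, errors i.i.d. at `base_error_rate = 0.01`. The default
quality model is constant Q35 with a linear decay to Q14 over the last 8
cycles — a stand-in chosen to exercise the Q20 end-trimming rule, not a
calibrated platform error model; qualities and the error process are
deliberately independent. Everything is deterministic given the profile
seed, to the byte, in FASTA/FASTQ output.

What the generator does *not* emulate: platform-specific error spectra,
nested or truncated insertions, heterozygous genomes, GC bias. Passing
tests therefore demonstrate the pipeline's internal correctness and its
behavior under the stated statistical model — not robustness to every
artefact of real libraries.

## 9. The validation study (acceptance experiments)

All experiment recipes live in `tests/testthat/helper-experiments.R` and
are run both by the test suite and by `scripts/acceptance.R`. Problem
sizes were chosen as the smallest at which each effect is comfortably
measurable:

* **Copy-number recovery** — ~2 Mb genome (1.2 Mb background), 20 UCOS ×
  1.5 kb, six families at copy numbers 1/5/20/100 and divergences 0–5%,
  6× depth. Median relative error of recovered copy number is required
  below 10%; residual error is dominated by the edge-ramp bias (section 1)
  and mapping loss at 5% divergence.
* **Divergence contrast** — the same families re-simulated after 25%
  consensus drift; mapping fraction must drop by more than half (it drops
  to ~0: a 60 bp read at ~28% divergence essentially never passes an 8%
  mismatch ceiling) while cluster-attributed fractions stay within 3
  points of truth (clustering on a 25,000-read subsample).
* **Diversity ratio** — ten 5 kb families, five copies each: class I at 5%
  inter-copy divergence vs class II at 0.5%, 6× depth. With five copies,
  a single divergent copy sits exactly at the 20% allele-fraction
  threshold, so detection is approximately linear in divergence and the
  called ratio lands near 10× (asserted within [5, 20]).
* **Partition uniformity** — under uniform divergence, per-bp rates of
  LTR/GAG/AP/RT/RH/IT must agree within 3σ binomial bounds of the pooled
  rate; percentages must sum to 100 ± 0.1.
* **PCA** — eight accessions sharing one reference, the second group of
  four carrying 2× LTR/Copia and DNA/hAT; 80 bp libraries at 3× depth, a
  30-gene UCOS panel (with few short UCOS contigs, baseline noise becomes
  a common-mode axis that can outweigh planted structure), 49 equalized
  replicates. Full-data PC1 must separate the groups, as must ≥ 90% of
  replicates; scores/loadings are also checked against an independent
  eigen-decomposition at 1e-8.
* **Phylogeny** — NJ exactness on additive matrices; STAR concordance on
  all 15 five-taxon topologies; a planted six-taxon tree with 20%
  NNI-perturbed gene trees recovered with bootstrap support ≥ 90 on the
  planted clade at B = 100.
* **Filter boundaries** — depth-6 sites never variable but consensus-
  callable; 49-column loci dropped and 50-column loci kept; any-gap
  columns removed; clusters at exactly 0.01% reported.
* **Determinism** — identical configuration and seed produce byte-identical
  pipeline outputs (md5 over every file).

## 10. Known limitations

* Relative copy numbers are relative to single-copy depth; absolute
  calibration (flow cytometry, ploidy, heterozygosity) is out of scope.
* The mapper is a deliberately simple seed-and-extend aligner: no gapped
  alignment by default, no quality-aware scoring, no BAM parsing. External
  alignments can be imported as SAM text instead.
* The clustering module is a functional analogue of graph-based repeat
  clustering, validated against planted truth — not a re-implementation of
  any specific external tool, whose exact scoring is not public.
* Branch lengths on species trees are rank-based, non-substitutional.
* Equalized subsampling breaks mate pairing by design.
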