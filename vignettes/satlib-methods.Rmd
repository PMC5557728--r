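---
title: "Methods: mining and comparing a satellite DNA library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and comparing a satellite DNA library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satlib)
```

## The problem

Satellite DNA (satDNA) families are organised as long arrays of tandemly
repeated monomers, typically in pericentromeric heterochromatin. Under the
*library hypothesis*, related species inherit a common set of monomer
variants from their ancestor and amplify different variants independently;
under *concerted evolution*, homogenization (unequal crossing-over, gene
conversion) makes monomers within a species more similar to each other than
to those of other species. Testing either idea requires an unbiased sample
of monomer haplotypes per species with abundances — which PCR cannot give,
because primers filter the variants they can anneal to. satlib therefore
mines full-length monomers **directly from whole-genome paired-end short
reads**, quantifies within-species variation, and relates species through a
haplotype network.

The pipeline is: subsample read pairs → merge mates by overlap → select
merged reads homologous to the family consensus → cut full monomer units at
consensus origins → collapse to haplotypes and discard singletons → per
species summaries (N, size range, Hap, Hd, π, sequence logos) → greedy
identity clustering → global alignment → pairwise-difference distances →
abundance-weighted minimum spanning tree (MST) with explicit mutational-step
nodes.

## Statistics

Haplotype diversity uses Nei's unbiased estimator, the form DnaSP reports:

$$H_d = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big),$$

with $p_i = n_i/n$ the haplotype frequencies. It is the probability that two
sequences drawn without replacement are different haplotypes; $H_d = 0$ iff
a single haplotype is present, and $H_d = 1$ when all $n$ sequences differ.

Nucleotide diversity is the average per-site pairwise difference,

$$\pi = \binom{n}{2}^{-1} \sum_{i<j} n_i n_j \, d_{ij} / L_{ij},$$

summing over haplotype pairs weighted by their counts. Two indel policies
are provided. The default, `gap_as_event`, counts each maximal gap run
present in exactly one sequence of a pair as a single difference, with its
columns counting toward the compared length $L_{ij}$ — an indel of any
length is one mutational event, which is also how the MST distances count
it. `complete_deletion` drops every column containing a gap anywhere in the
alignment, for comparison with alignment programs that do the same.
Ambiguous bases (N) are never compared: columns with N in either sequence of
a pair are excluded from both $d_{ij}$ and $L_{ij}$. Which of the two
policies a given published π value used is generally not recoverable from
the value alone, so both are first-class options.

Sequence-logo information content per alignment column is $R = 2 - H$ bits,
with $H$ the Shannon entropy of the count-weighted base frequencies computed
on non-gap symbols; all-gap columns are reported as missing rather than 0.

**Reporting convention.** Published satellite clone tables truncate rather
than round: a sample of 3 clones with 2 haplotypes has $H_d = 2/3 = 0.6667$
yet is printed as 0.66, and a 19-clone sample with $H_d = 0.988$ prints as
0.98. `trunc_digits()` (used by `format_diversity()`) reproduces this
truncation at report time; all internal computation keeps full precision.

## Alignment choices

All pairwise alignment uses one scoring scheme: match $+1$, mismatch $-1$,
gap open $-2$, gap extension $-1$ per gap base, with identity defined as
matches / alignment columns (gaps count as columns, N never counts as a
match). The scheme is deliberately simple so every alignment-dependent
result can be checked against a small dynamic-programming oracle in the
tests.

Tandem repeats have a circular coordinate system: a read's monomer can
straddle the arbitrary consensus start. Homology selection and monomer
extraction therefore align against a **doubled (tiled) consensus**, and
every extracted segment is **rotation-canonicalized**: among all rotations
of the segment, the one with the maximal global alignment score against the
consensus is kept. Score ties are broken by the lexicographically smallest
rotated string (then smallest offset) — content-based tie-breaking keeps the
canonical form invariant to the phase of the input, which an offset-based
rule alone would not for perfectly periodic segments.

The multiple alignment behind π, logos and distances is a
consensus-anchored **star alignment**: each monomer is globally aligned to
the anchor and columns are merged, padding insertions at the same anchor
position to a common width. For monomers that are all minor variants of one
consensus this is essentially as good as a progressive aligner, fully
deterministic, and exactly invertible (ungapping any row recovers the input
monomer). It is not a general-purpose MSA: for sequence sets without a
sensible common reference a progressive aligner would be preferable.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| `min_overlap` (merge) | 20 nt | short enough to merge 2×101 libraries at ~180 nt fragments, long enough that random 20-mers don't align |
| `max_mismatch_frac` (merge) | 0.10 | tolerates sequencing error without joining unrelated mates |
| `min_identity` / `min_aligned` (selection) | 0.70 / 50 | permissive enough to catch variants diverged up to π ≈ 0.18 while keeping the false-positive rate on random sequence below 1% |
| `min_identity` (extraction) | 0.60 | more permissive than selection so relictual, highly diverged monomers survive the final cut |
| `length_tol` | ±10% of unit | brackets observed monomer size ranges (166–186 bp around a 177 bp unit) |
| singleton filter | on, Illumina only | variants seen once in reads are indistinguishable from sequencing error; Sanger clones are few and individually verified, so they are kept |
| cluster threshold | 0.99 | reduces haplotype inflation from 1–2 substitution variants before network building |
| subsample size | configurable | the per-species read budget is a property of the study, not of the method |

## The simulator

`simulate_library()` draws a root monomer (default 177 nt) and derives the
other library haplotypes by i.i.d. substitution at a chosen divergence —
the shared ancestral variant pool. `species_profile()` +
`amplify_species()` express the library hypothesis directly: each species
draws its monomer copies from the ancestral haplotypes with its own
amplification weights, then accumulates post-amplification substitutions
and 1–9 nt indels. Low weights concentration + low mutation emulates a
recently amplified, efficiently homogenized satellite (low π); uniform
weights over diverged variants + higher mutation emulates a relictual
satellite (high π, up to the ~0.18 regime). `build_tandem_array()`
concatenates the pool in seeded shuffled order, and `generate_reads()`
samples fragments **on the circularized array** (edge monomers are not
under-covered; real arrays are far longer than simulated ones) with
substitution-only read errors and constant Q37 qualities — the pipeline
uses qualities only to resolve merge mismatches, and monomer-level indels
are injected at the amplification stage where they belong biologically.

What the simulator does *not* emulate: coalescent genealogies,
unequal-crossing-over dynamics, higher-order repeat structure, PCR
chimeras, read-level indels, quality-dependent error profiles, or
non-satellite genomic background. Passing tests on simulated data therefore
validate the bookkeeping and the estimators under the library model's
statistical structure, not robustness to every artifact of real libraries.

Seeds are explicit everywhere; the pipeline derives per-stage,
per-species seeds from one master seed by fixed offsets, so a single
integer reproduces a run bit-for-bit.

## Clustering and the MST

Greedy clustering is CD-HIT-style: sequences sorted by abundance, then
length, then lexicographically, each joining the first representative at
identity ≥ threshold, else founding a new cluster. At threshold 1.0 this
reduces to exact deduplication. Cluster abundance is the summed member
count and becomes the MST node weight.

The MST is built with Kruskal's algorithm over pairwise differences
(mismatches + indel events). MSTs are not unique under tied distances, so
ties are broken deterministically by (weight, lexicographic node pair);
every edge of weight $k$ is expanded with $k-1$ step nodes so each drawn
edge is one mutational step. `mst_species_coherence()` quantifies concerted
evolution as the fraction of edges joining same-species haplotypes against
a species-label permutation null.

## Degenerate inputs and failure modes

* Fewer than 2 sequences: Hd and π are undefined and raise a typed error;
  the per-species summary reports `NA` instead of a fabricated 0.
* Unmergeable pairs return a typed no-merge record, not an exception;
  individually homologous unmerged mates count toward homology accounting
  but are never used for monomer extraction.
* Reads with >10% N are dropped; N never counts as a match anywhere.
* An empty FASTQ aborts the pipeline with an error naming the stage.

**Known limitation — periodicity-shifted merges.** When the true fragment
length exceeds `2·read_length − min_overlap`, the mates' true overlap is
shorter than the minimum and the merger can instead lock onto an overlap
shifted by one repeat unit, producing a chimeric merged read (this affects
any overlap-based merger on tandem repeats). In practice such chimeras are
haplotype singletons and are removed by the singleton filter; end-to-end
recovery tests keep fragment lengths within the mergeable range by design.

**PCR clones in the network.** Published analyses are ambiguous about
whether Sanger-derived haplotypes were clustered together with read-derived
ones before network building; `cluster_pcr` exposes both behaviours
(default: clones pass through unclustered).

## Validation scale

The test-suite and acceptance checks run the full pipeline at desk scale:
libraries of 3–8 haplotypes of 120–177 nt, pools of 40–100 monomer copies,
arrays of 10–20 kb, and 250–400 read pairs per species at 2×250 — enough
coverage that every amplified variant is recovered while each end-to-end
run completes in seconds. Estimator properties are checked against
brute-force oracles on 100 random small alignments, exhaustive
spanning-tree enumeration up to 7 nodes, all rotations of 50 random
monomers, and 10,000 random queries for the homology false-positive rate.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  species = list(
    list(name = "homogenized", weights = c(8, 1, 1, 0, 0), copies = 80,
         n_pairs = 300),
    list(name = "relictual", weights = c(1, 1, 1, 1, 1), copies = 80,
         mutation_rate = 0.01, n_pairs = 300)
  ),
  simulate = list(n_haplotypes = 5, unit_length = 177, divergence = 0.05),
  seed = 1
)
report <- run_pipeline(cfg)
format_diversity(report$diversity)
glance(report$mst)
autoplot(report$mst)
```
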