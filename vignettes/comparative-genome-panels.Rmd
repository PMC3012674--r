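---
title: "Methods: inventories, combined scores, assembly QC and 16S trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inventories, combined scores, assembly QC and 16S trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genopanel)
```

`genopanel` implements the comparative-genomics workflow used to
characterize a newly sequenced bacterial genome: functional gene
inventories, two-component-system (TCS) topology, panel-wide standardized
count statistics, assembly reconciliation and coverage QC, repeat
catalogues and distance-based 16S phylogenetics. This vignette is the
package's account of the underlying models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Rule-driven classification

Classification is data-driven: each category (TCS, transcription factors,
transporters, defense genes) is defined by a YAML rule list of Pfam
domain accessions, COG ids and COG single-letter categories
(`read_category_rules()`). The lists shipped with the package are a
curated approximation of the commonly used family sets — the receiver
domain (PF00072) and the histidine-kinase core domains (HisKA variants
and the HATPase ATPase domain) for TCS, widespread helix-turn-helix
families for transcription factors, ABC/MFS transporter COGs for
transport, and restriction-modification/beta-lactamase COGs plus COG
category V for defense. They are *stand-ins*: a study with its own
curated lists should substitute them via `read_category_rules(path)`;
every downstream computation is independent of the particular list
content.

TCS role logic is structural and deterministic: receiver domain only
gives a response regulator (RR), kinase core only a histidine kinase
(HK), both a hybrid kinase. Consequently the identity
`TCS = RR + HK + hybrid` is enforced by construction, not by counting
twice. A design choice the source methodology leaves open is whether a
TCS gene carrying a DNA-binding output domain also counts as a
transcription factor; `genopanel` excludes TCS genes from the TF count so
the four categories entering the combined score do not double-weight
signal-transduction genes. Domain hits are filtered at a full-sequence
E-value of `1e-5` by default; the threshold is a reader argument because
no canonical value exists for this kind of inventory.

## TCS organization and neighborhoods

Organization is decided on *runs*: TCS genes are ordered along each
replicon and consecutive genes at most `pair_gap_bp` apart (default
200 bp, a typical operon-internal intergenic distance; strand is
ignored) belong to one run. A run of exactly two genes consisting of one
HK-like gene (HK or hybrid — hybrids carry the kinase core, so they pair
as kinases) and one RR is *paired*; runs of three or more are *complex*;
everything else is *orphan*. The three labels partition the TCS set.
The neighborhood profile collects all non-TCS genes within
`window_genes` (default 5) positions of any TCS gene, de-duplicated
across overlapping windows, and maps their COG category letters to
coarse classes (default: P to transport, K to regulatory, C and G to
energy metabolism, everything else to other); fractions are reported
over classified neighbors and sum to one.

Locus clustering (`cluster_category_loci()`, default gap 5 kb, chosen to
reproduce kilobase-scale clusters such as flagellar loci) closes
membership transitively. The gap is measured from the *furthest gene end
seen so far*, not simply the previous gene's end, so nested or
overlapping genes cannot split a locus — this makes the run construction
equal to a union-find closure over all in-range pairs, which is how the
test suite verifies it.

## The combined score

For a panel with per-genome, per-category counts $x_{gc}$, the package
standardizes with the panel mean and *population* standard deviation
(divisor $n$): the panel is treated as the population of interest, and
degenerate zero-variance categories yield all-zero z-scores with a
warning rather than an error. The combined score is the unweighted mean
of the four designated z-scores; the normalized variant standardizes
densities $x_{gc} / \mathrm{Mbp}_g$ first. Standardization is the only
reading of "averaging deviations across categories" that yields a
dimensionless score comparable across categories with very different
absolute counts, and it makes the score invariant under per-category
affine rescaling (a property the tests check). Percentile ranks count
strictly smaller values and ties share the lower rank, so tied panels
flag nothing — conservative flagging. COG-profile clustering uses
average linkage on $1 - r$ (Pearson); the linkage is a package choice
where the methodology names none.

## Assembly QC

Contig placement seeds on probe k-mers (default $k = 31$) taken every
$k$ bases along both orientations of the contig and located exactly in
the scaffolds; a seed k-mer unique in the scaffold implies one candidate
offset, and the full contig is then compared ungapped (the substitution
model of the generators produces no indels; real indel-containing data
should be placed with an aligner first). A placement is accepted at
mismatch fraction at most `max_mismatch_frac` (default 0.01). When only
ambiguous seeds exist, the candidate with the fewest mismatches wins and
ties leave the contig unplaced: determinism over guessing.

Reconciliation reports the fraction of scaffold bases covered at least
once, missing bases, the mean *signed* distance between consecutive
placements (negative = overlap) and base-weighted mean identity.
Coverage tracks average depth in non-overlapping windows (default
5,000 bp); window flags use `mean +/- n_sd * sd` (default 2) of window
depths. Copy number of a collapsed repeat is the ratio of the region's
mean window depth to the genome-wide mean. Note a small conservative
bias inherent in the definition: the genome-wide mean itself includes
the inflated repeat windows, so a k-fold locus occupying fraction $f$ of
the genome yields a ratio of about $k / (1 + (k-1)f)$ — with the default
fixture ($f = 1\%$) the $k = 8$ estimate is ~7.5, still within the 10%
recovery band the tests require.

Repeat definitions: *global* repeats are maximal exact match pairs of
length at least `l_g` (default 25 bp) between distinct positions, found
by k-mer anchoring and two-sided maximal extension; *local inverted*
repeats are two arms of at least `l_i` (default 10 bp) that are exact
reverse complements separated by a loop of at most `loop_max` (default
100 bp), extended to maximality inward and outward; *tandem* repeats are
maximal runs with period 1-6 and at least 3 full copies, with a
minimal-period containment filter so a homopolymer is not re-reported at
every multiple of its period. Only loop-bounded ("local") inverted
repeats are implemented; an unbounded variant would be a special case of
global repeats on the reverse complement. All three finders, and N50,
are verified against brute-force enumeration oracles on short sequences
in the test suite.

## 16S distances, neighbor joining, bootstrap

Distances use pairwise deletion (sites with `-` or `N` in either
sequence of a pair are dropped for that pair). Three models are
provided: the raw mismatch fraction $p$; Jukes-Cantor
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, which errors explicitly at
saturation ($p \ge 3/4$); and `tn93_pooled`, a composite-likelihood-style
stand-in for the maximum-composite-likelihood distances of popular tree
software: base frequencies are pooled over the whole alignment, the
transition/transversion partition is estimated from substitution counts
pooled across all pairs, each pair's observed difference fraction is
split by those pooled proportions, and the Tamura-Nei (1993) formula is
applied. With equal base frequencies and equal rates it reduces exactly
to Jukes-Cantor (the tests check agreement within 2% at $p = 0.1$);
exact equivalence with any particular software's estimator is not
claimed.

Neighbor joining is the classic Q-criterion agglomeration, made fully
deterministic: ties in Q are broken by the lexicographically lowest pair
of current node indices, and negative branch lengths are clamped to
zero. The result is an unrooted `ape::phylo` with a basal trifurcation.
Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree per replicate, and reports for each internal bipartition of
the full-data tree the percentage of replicates containing it; the
resampler is seeded, so identical seeds give identical support values.

## What the synthetic generators emulate — and what they do not

Generator defaults encode the study conditions the analyses are designed
for: panels of 500 genomes of 2-10 Mbp with category counts linear in
size (slopes of roughly 10-55 genes/Mbp across the four categories,
Gaussian count noise) and one mid-sized outlier genome offset by +3
panel standard deviations in every category; annotated genomes whose
planted HK-RR pairs, orphans and three-gene clusters are separated by
gaps chosen on either side of the 200 bp pairing threshold; 500 kb
references tiled by 2-4 kb contigs with planted -5/-10 bp overlaps,
independent 0.2% substitution rates and one window-aligned collapsed
repeat at 100x baseline depth; and alignments evolved site-i.i.d. under
Jukes-Cantor on known trees. All generators are deterministic given a
seed, and one global seed fans out to independent per-fixture streams
(`fanout_seed()`), so regenerating one fixture leaves the others
bit-identical.

These fixtures deliberately idealize real data: no indels or structural
rearrangements in contigs, no rate heterogeneity or gaps in alignments,
no annotation errors or partial domains, Poisson rather than
instrument-specific depth noise. Passing tests therefore demonstrate
*algorithmic correctness against the stated models* — that planted
structure is recovered exactly or within stated statistical bands — not
robustness to every artefact of real sequencing data. Real-genome
headline numbers (e.g. a specific organism's 210 TCS genes or a panel's
158 +/- 111 transcription-factor mean) depend on the exact genome
panel, database versions and curated domain lists, and are out of reach
of any desk-scale test; what the package guarantees is that given those
inputs, the arithmetic and algorithms are the documented ones.

## Problem sizes and numerical choices

The test suite and acceptance script use: panels of $n = 500$ (outlier
recovery over 100 seeds), 500 kb assembly fixtures (~170 contigs),
repeat-oracle sequences of 150-200 bp, NJ recovery over 100 random trees
of 5-12 taxa, and 100-500 bootstrap replicates on 4-6-taxon alignments —
sizes chosen so each property is measured at meaningful scale while the
whole suite completes in a couple of minutes. Percentages in reports are
rounded half away from zero (documented in the output), which matches
most published genome-table values; observed off-by-one discrepancies in
third-party tables (59 vs 58 for 43/73) are attributable to their
unknown rounding convention and are not special-cased. Reported
percentile ranks, z-scores and distances are never rounded internally.

## Known limitations

* Placement is ungapped substitution-only; indel-bearing contigs need an
  external aligner.
* The copy-number ratio inherits the conservative bias described above;
  for loci occupying a large genome fraction, estimate against a
  baseline excluding the locus.
* `tn93_pooled` is an approximation to composite-likelihood distances,
  not a reimplementation of any specific tool.
* Default rule lists are labeled stand-ins; inventories on real genomes
  should use study-curated lists.
* Bootstrap support is only as informative as the distance model; no
  likelihood or Bayesian support is provided.
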