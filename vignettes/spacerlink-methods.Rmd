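---
title: "CRISPR-mediated element-host dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR-mediated element-host dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerlink)
```

## The problem

Bacterial hosts in a microbial community record their encounters with
invasive mobile genetic elements (iMGEs: plasmids and bacteriophages) in
CRISPR arrays: short element-derived fragments (spacers) are stored between
near-identical repeats, and the matching sequence on the element itself is
the protospacer. In a time-resolved metagenomic series these sequence links
make host-element interactions directly observable: a spacer that appears
after its target element marks an acquisition (immunisation) event, and the
disappearance of a spacer marks a deletion. `spacerlink` turns assembled
contigs, CRISPR element tables, genome-bin assignments, depth-of-coverage
tables and plasmid/phage predictor flags into non-redundant CRISPR elements,
host-anchored loci, protospacer catalogues, labelled representative
elements, dated gain/loss events, bipartite interaction networks and a
family-level linear model of community dynamics.

## Sequence comparison conventions

All sequence comparisons run through one alignment engine
(`local_align()`, Smith-Waterman over both strands, linear gap penalty,
default scores +1/-1/-2). Two conventions are fixed package-wide so that
every threshold has a single meaning:

* **Identity** is matches / alignment columns, with gap positions counting
  as columns. For full-length ("covering the entire length") rules the
  engine switches to an end-to-end alignment in which terminal gaps also
  count as columns, so length differences and terminal mismatches reduce
  identity. `N` matches nothing, not even another `N`.
* **Coverage** of a sequence is the aligned fraction of *that* sequence.
  Rules are expressed as `both_full` (end to end on both sides, used for
  spacers at 90% identity), `both_min` (both fractions above a minimum,
  used for flanking sequences at 99% / 97.5%) and `shorter_min` (the
  shorter sequence's fraction, used for repeats at 80% / 75% and for
  elements at 80% / 50%), matching the conventions of short-read clustering
  tools.

`greedy_cluster()` is a CD-HIT-style incremental clusterer: sequences are
sorted longest first (ties broken lexicographically, so representatives are
reproducible), each sequence joins the first representative it matches, and
exact duplicates are pooled without alignment work. For long sequences
(both at least 200 nt) candidate pairs must share an exact 12-mer before an
alignment is attempted; at the identity levels used here a true match always
shares such words, while random pairs essentially never do.

`tune_repeat_parameters()` reproduces the iterative calibration of repeat
clustering: starting at 99% identity and 100% coverage, both parameters are
reduced by five percentage points per iteration (simultaneously - the
procedure's published description does not fix an order, and simultaneous
reduction is the only symmetric choice) until the known repeats of a single
locus regroup into one cluster. The production thresholds for repeats,
80% identity over at least 75% of the shorter sequence, follow that
calibration regime.

## Anchoring loci to genomes and finding protospacers

Host anchoring is two-staged. Flanking sequences are matched to genome-bin
(MAG) contigs at 95% identity with a length-dependent flank coverage: 80%
for flanks of at least 100 nt, 95% for shorter flanks. A flank of exactly
100 nt uses the permissive branch (the published rule names only the two
open intervals; the boundary had to live somewhere and long-flank semantics
are the natural reading for "not short"). A candidate is confirmed only if
a repeat from the same locus aligns to a contig of the *same* MAG at 75%
identity and 80% repeat coverage - any contig of the MAG, not necessarily
the flank's own, which is flagged in the output. Spacers of confirmed loci
are assigned to the MAG and propagated to its representative genome (rMAG);
a spacer may legitimately reach several rMAGs.

Protospacer search is seed-and-extend: exact 7-mer words anchor candidate
windows, each window is locally aligned, and hits are kept at 95% identity
and 95% spacer coverage - thresholds that dominate the outcome regardless
of seeding details. Overlapping hits of one spacer on one contig are merged
keeping the higher identity, so per-contig protospacer counts are not
inflated. Identical protospacers at different positions count as distinct.
A protospacer-containing contig (PSCC) is a contig with at least one
retained hit and no CRISPR signal of its own: contigs carrying a repeat
match or listed as CRISPR-locus contigs are excluded to avoid array
self-matching. The repeat screen additionally requires an exact 11-nt
shared word (the default word size of common nucleotide search tools)
before gapped alignment; without a seed requirement, unconstrained dynamic
programming reports weak chance alignments on a few percent of random
contigs that no practical sequence search would ever emit.

## Element classification and abundance

Predictor flags from two plasmid tools and two phage tools are consolidated
per contig: `plasmid` if either plasmid predictor fires and no phage
predictor does, `phage` in the mirror case, `ambiguous` if both sides fire,
`unclassified` if nothing fires but the contig carries a protospacer, and
"not an element" otherwise; when a contig is both predictor-labelled and a
PSCC the predictor label wins. Elements are clustered at 80% identity over
half of the shorter sequence and each cluster keeps its representative's
label. A cluster counts as a PSCC if any member carries a protospacer.

Spacer abundances are consolidated per cluster (summing member coverages
per sample), transformed to counts per million per sample within the spacer
feature class, and called present at an inclusive cutoff of 1 c.p.m. - a
deliberately permissive threshold because short spacers recruit few reads.
Genome and element abundances are length-weighted mean metagenomic (MG)
depths of their contigs; relative abundances rescale each sample to 100%.
Relative abundance is MG-based; metatranscriptomic (MT) depth contributes
to *presence* only ("detected in either MG or MT data"), which also admits
MT-only elements such as RNA phages. Presence from depth uses "greater
than zero" by default, appropriate for noise-free synthetic data; a minimum
depth parameter exists for real data.

## Event classification

For every active spacer-element pair two comparisons are made on the shared
date axis. First occurrences: spacer after element = `gain`, same date =
`probable_gain`, spacer first = `probable_secondary_encounter`. Last
occurrences: spacer after element = `loss`, same date = `probable_loss`,
spacer first = `spacer_loss_before_imge_loss`. Activity requires that the
spacer is encoded by an rMAG, co-occurs with it in at least one time point
(a biconditional: assignments failing it are removed), and targets at least
one element. Lags are fractional weeks (days / 7) because sampling is
irregular and integer weeks would distort; integration lags summarise
`gain` events and deletion lags `loss` events, with the same-date
categories excluded by default (a "lag" of zero is not a lag) and the
standard deviation computed with the n-1 denominator. The gain/loss
timeline reports the crossover as the date at which the running balance of
gains minus losses peaks - the point after which losses dominate.

## Networks

Plasmid-host and phage-host networks are built separately from active
links; ambiguous and unclassified elements are excluded. Time-point
networks keep an edge when both endpoints are present (MG or MT) and keep
present-but-partnerless nodes as orphans. Modularity is Barber's bipartite
Q, maximised by label propagation with random restarts followed by greedy
module merging under a fixed seed; the exhaustively verified property is
the *value* Q, not a particular optimiser's trajectory. Edges enter Q
unweighted; spacer multiplicities are emitted alongside for reanalysis.
Nestedness is NODF with the standard smaller-fill normalisation: pairs with
strictly decreasing fill contribute the shared fraction of the smaller
fill, all other pairs contribute zero, averaged over row pairs and column
pairs. Degree, betweenness and closeness are computed on the unweighted
bipartite graph; betweenness is normalised by (n-1)(n-2)/2 and closeness of
a disconnected node is defined as 0. The one-mode host projection weights
host pairs by their number of shared elements.

## Community linear modelling

Features are grouped at the family level (elements join the family of the
MAG they were binned with; unbinned features are excluded with a logged
count), group series are sums of member relative abundances, and all
pairwise Pearson correlations are tested two-sided with Benjamini-Hochberg
adjustment (the adjustment method is configurable; the strong-correlation
flag is |r| >= 0.7 at adjusted p <= 0.001). Groups are clustered on the
Euclidean distances between their correlation profiles with complete
linkage (the default of the clustering function named in the original
workflow) and a tree cut at height 4.

The model search draws random predictor subsets: a size uniform on 1..15,
then a uniform subset of that size. "All combinations with the same
probability" is ambiguous between combination-uniform and size-uniform
sampling; size-uniform is used because it exercises all model sizes equally
and keeps small models represented. Each realization is an OLS fit ranked
by adjusted R-squared; rank-deficient designs are skipped and counted.
Enrichment of groups among the top N models (N = 25, 50 or 100) is scored
with a one-sided hypergeometric test - the original analysis does not name
its enrichment test, so this choice is flagged as a potential divergence.
The global model regresses the response on all enriched groups; the reduced
model keeps the globally significant coefficients (alpha = 0.05,
configurable, unstated in the source analysis). `ablate_predictor()`
refits the reduced model without one group and reports the adjusted
R-squared drop. Shorter-term intervals are supported by passing a column
window to `correlate_groups()` and subsetting series before the search.

## The synthetic community

`simulate_community()` plants a complete study: 51 time points with gaps
drawn as `max(1, round(Normal(8, 4)))` days (the study's sampling had mean
8 days with a long-tailed spread; a normal with its published s.d. would
make zero or negative gaps dominate, so a truncated spread is used), 12
host rMAGs in 6 families plus 2 extra MAGs that dereplicate into existing
rMAGs, and 170 elements at the 16:1 plasmid:phage composition. Hosts carry
repeat-spacer arrays with flanking sequences (a quarter of loci get short
80-nt flanks so both matching branches are exercised); spacers are 30 nt,
drawn with a minimum pairwise edit distance of 20% of their length (also
against reverse complements) so cluster ground truth is unambiguous.
Protospacers are embedded verbatim or reverse-complemented at
non-overlapping positions; 56% of targeted elements carry at least two
protospacers and one spacer in ten targets a second element, so both
many-to-many directions occur. Presence windows are planted per pair to
realise all six event categories, and the recorded ground truth (including
lags in days) is *derived from the realised windows*, so clamping at the
series edges can never desynchronise truth from data.

Depth tables are built so the analysis path is exactly linear: a slack set
of always-present plasmids keeps the total element depth constant per
sample, and a filler population does the same on the host side, making
relative abundances proportional to depths. The dominant family's series
is then a recorded linear combination of three element-group series (its
own plasmids with a negative coefficient - they surge during the planted
community shift - plus two other groups) with Gaussian noise of 5% of the
deterministic response s.d. Family-1 plasmids triple their depth inside
the shift window and two other families rise there, reproducing the
dip-and-rise structure of a community shift. Twins (slightly mutated
copies of untargeted plasmids), MT-only elements, background contigs and
1-substitution spacer variant detections exercise clustering, the
MG-or-MT presence rule and abundance consolidation.

What the generator does *not* emulate: read-level noise (depths are exact,
not resampled), assembly fragmentation and chimerism, strain-level variation
within populations, prophage integration, horizontal transfer of CRISPR
loci, and correlated predictor-tool errors. Passing the end-to-end tests
therefore demonstrates the correctness of the decision rules and the
identifiability of planted structure under clean signals - not robustness
to assembly artefacts, which must be assessed on real data.

## Numerical choices and test scale

All randomness flows from explicit seeds; the pipeline derives one seed per
stage from its root seed, so reruns are manifest-identical. Modularity uses
20 restarts (10 for per-date networks). Ties in clustering fall to the
earlier-founded representative; ties in label propagation fall to the
lowest module id. Degenerate inputs are defined: all-zero count columns
stay zero under c.p.m., edgeless networks give `NA` modularity and NODF,
constant series give `NA` correlations and are excluded from modelling,
empty lag selections report `NA` rather than zero, and a zero-host
simulation still writes valid (empty) fixtures.

The test suite validates the optimisation primitives against independent
oracles (all-pairs dynamic programming for clustering on up to 24
sequences over 100 seeds; exhaustive partition enumeration for Barber Q on
graphs of up to 10 nodes over 100 seeds; the direct pairwise formula and
the community-ecology reference implementation for NODF), reproduces every
printed decision rule on enumerated toy cases, and recovers 100% of planted
assignments, links, event categories and lags on the default noiseless
community. Model recovery uses a 10,000-realization search - a tenfold
scale-down of the original 100,000, which at 51 samples and about a dozen
candidate groups already samples every predictor hundreds of times per
size - across 100 noise replicates, requiring all planted groups in the
reduced model in at least 95% of replicates and a strictly positive
ablation cost in every recovering replicate.

## Limitations

Alignment-based clustering is quadratic in the number of unique sequences
per batch and is sized for desk-scale data (hundreds of spacers, hundreds
of contigs), not for hundreds of thousands of elements; the word prefilter
mitigates but does not remove this. The greedy clusterer reproduces the
*convention* of incremental clustering tools, not any specific tool's
word-filter heuristics. PAM identification, self-targeting analysis,
cas-gene typing and significance null models for Q and NODF are out of
scope; annotations pass through where provided.
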