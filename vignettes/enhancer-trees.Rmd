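---
title: "Enhancer-promoter tree models and in silico enhancer perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer-promoter tree models and in silico enhancer perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Chromatin-loop assays such as H3K27ac HiChIP report pairwise contacts
between genomic anchors. `epictrees` organises those contacts into rooted
*enhancer trees*: graphs in which one promoter anchor is the root and
enhancer anchors are placed on levels according to their connectivity to
that promoter. A level-1 (E1) enhancer loops directly to the promoter via an
L1 edge; a level-2 (E2) enhancer reaches the promoter only through an E1,
via an L3 edge (edge level = sum of its endpoint levels). Trees connected
through shared anchors or promoter-promoter loops form *enhancer forests*.

The pipeline is: (1) merge all loop anchors genome-wide into disjoint
consensus anchors, classify each as promoter (midpoint inside a promoter
window) or enhancer, and re-anchor every loop onto them; (2) per cell type,
extract one tree per promoter; (3) run connectivity, distance and
nearest-promoter-skipping analyses; (4) train per-cell-type k-nearest-
neighbour classifiers on chromatin features of the trees and score each
enhancer by the accuracy lost when it is deleted in silico; (5) intersect
disease-associated SNPs with tree nodes to nominate candidate target genes.

## Coordinates and consensus construction

All coordinates are 0-based half-open (BED convention); SNP and other
1-based inputs are converted at read time so a single convention holds
internally. Anchor merging uses "any overlap" semantics with bookended
intervals (`[a,b)`, `[b,c)`) treated as mergeable, matching the default of
the standard interval toolkit. A consensus anchor's midpoint is
`floor((start + end)/2)`. Promoter windows span 2 kb upstream to 3 kb
downstream of the TSS; the window is strand-aware by default (configurable),
since upstream is only meaningful relative to transcription direction. When
an anchor midpoint falls in two genes' windows, the nearer TSS wins and
lexicographic gene id breaks exact ties. Loops shorter than 5 kb
(midpoint distance) are removed as merging artifacts.

Node names have the form `<chromosome>.<rank><P|E>` (for example
`22.1008E`). The rank is the 1-based position of the anchor midpoint within
its chromosome over all consensus anchors, promoters and enhancers sharing
one rank sequence. The published material shows the format but not the
ranking rule; this choice makes names reproducible from the input alone.

## Level assignment and pruning

The iterative "one greater than a neighbour" level-assignment rule is
order-dependent as written. `assign_levels()` therefore computes
breadth-first shortest-path levels from the root, which is the unique
fixpoint consistent with the subsequent pruning rationale (a pruned enhancer
always keeps a shorter path to the promoter). Traversal never crosses
another promoter node, so each tree contains exactly one promoter;
promoter-promoter loops are stored separately and used only for forest
linkage and the promoter-connectivity comparison. Edges joining equal-level
nodes are deleted; afterwards every edge joins consecutive levels, so edge
levels are odd. Pruning cannot change any node level (an invariant the test
suite checks on random graphs). A node may keep several parents after
pruning; the structures are leveled DAGs rooted at the promoter, which we
call trees following the field's usage.

An edge belongs to a cell type when its PET count there is at least
`min_pet` (default 1, i.e. PET > 0); this is the table-level analogue of
building trees from per-cell-type loop calls and can be raised for stricter
subgraphs.

## Distances, skipping and orientation

Distances are unsigned base pairs from the node midpoint to the root TSS.
The nearest promoter for an E1 enhancer is the closest TSS 5 kb-1 Mb from
its midpoint, ties toward the smaller gene id. An enhancer "skips" when its
looped promoter differs from that nearest TSS; skipped genes are classified
`InsideLoop` (same side of the enhancer as the looped gene) or `OutsideLoop`
(opposite sides), and the orientation-by-cell-type table is tested with a
plain Pearson chi-square (no continuity correction; the published df = 4 on
a 5 x 2 table implies the uncorrected r x c test). Paired looped-versus-
skipped expression comparisons collapse duplicates by (enhancer, looped
gene, skipped gene) within a cell type to avoid pseudo-replication from
enhancers appearing in several trees. Because the published ">80% distal"
denominator could count E1 instances or unique anchors, `connectivity_stats()`
reports both tabulations (as it also does for "indirect" fractions, which
can count edges or nodes).

## The classifier and effect sizes

For each cell type a balanced training set is built from trees whose gene
has expression specificity (ESS) above 0.7 in that cell type (positives)
versus a seeded random draw, matched in count, of tree genes with ESS below
0.3 in all four cell types. Each gene is described by 24 predictors — for
each of the four cell types, the summed ATAC of direct (level-1) enhancer
nodes, the summed PET of direct (L1) edges, the summed ATAC x PET product,
and the same three for indirect nodes and deeper edges. Two declared
conventions: the product term pairs each enhancer node with its parent-side
edges (the edges to the level below, summed when there are several minimal
parents), and each cell type's six features come from that cell type's own
tree for the gene, zeros when absent.

The classifier is kNN with Euclidean distance. Predictors are centred and
scaled inside each training fold and the held-out fold is scaled with the
training folds' statistics, so no information leaks across the split (a
test re-derives the held-out votes from an explicit train-only scaling).
k is selected from the odd grid 3-25 by 10-fold cross-validated accuracy
(the published method states CV selection but not the grid). Class calls use
neighbour vote fractions; an even split predicts the negative class, making
predictions deterministic. Two baselines share the training protocol:
promoter accessibility only (four predictors), and a linear regulatory-
domain model whose per-cell-type predictor is the ATAC of enhancers within
1 Mb of the TSS weighted by 1 kb / distance.

The effect size of enhancer `e` in tree `T` is the mean over repetitions of
`D(e)`, the sum across the four cell-type models of the absolute change in
cross-validated accuracy when `e` and its dependent descendants (nodes
whose every path to the root passes through `e`) are removed before the
features are recomputed. Removal applies to every cell type's tree of the
gene containing that anchor, so all affected feature columns respond.
Within a repetition the perturbed model reuses the original model's
negative draw, fold assignment and selected k — a paired comparison that
removes fold-resampling noise from `|delta accuracy|`; re-searching k for a
one-row feature change would only add variance. Each repetition re-draws the
negative sample and the folds (re-drawing only folds is available via
`redraw_negatives = FALSE`). The default is 100 repetitions, with the count
exposed for desk-scale runs. Ranking within a tree is by descending effect
size, ties toward the smaller node name.

## SNP annotation

SNPs passing the association threshold (default p < 1e-4) are intersected
with tree-node intervals; each containment expands to one link per tree
containing the node. For stratification, enhancers of trees containing at
least one SNP node are split into SNP-overlapping and not-overlapping and
compared with a two-sample Kolmogorov-Smirnov test. Enhancers recurring in
several such trees are collapsed to one value per node (their maximum
effect size) before the primary test; the per-instance test is also
returned, since the published analysis does not state which was used. The
external enrichment tool's computation itself is out of scope; only its
position-indexed 0/1 annotation files are exported.

## The synthetic generator

`simulate_fixture()` emulates the study's inputs at desk scale: four cell
types, per cell type 200 focal genes (ESS 0.75-0.95 there, below 0.3
elsewhere) plus a shared pool of 400 non-specific genes (ESS below 0.3
everywhere), one gene per 1.2 Mb block, 100 blocks per chromosome. Focal
trees carry 3-6 direct enhancers whose ATAC and PET are multiplied by
`signal` (default 5); one designated critical enhancer per focal tree gets
a further `critical_enhancer_boost` (default 6), so its removal drops the
tree's direct features to near background while removing any other
enhancer leaves the gene well inside the focal class — the planted ground
truth for the recovery experiment. Background trees (2-4 enhancers,
baseline signal) appear in other cell types. PET counts are negative
binomial (mu 8, size 4, floor 2) — overdispersed counts without claiming to
match any unpublished distribution — and ATAC is log-normal (meanlog
log 20, sdlog 0.5). Bystander genes (68% noncoding, low expression) are
planted between 85% of E1 enhancers and their promoters to create
nearest-promoter skipping with a 70/30 inside/outside mix; promoter-
promoter loops are enriched around focal genes (6 partners versus at most
1) to plant the forest-connectivity contrast; significant SNPs are placed
preferentially in critical enhancer anchors. Everything is a deterministic
function of the seed.

What the generator does not emulate: donor-level replicates, read-level
noise, LD structure among SNPs, distance-dependent contact decay, or any
particular genome's gene density. Passing tests therefore demonstrate that
the algorithms recover planted structure under controlled noise, not that
the biological effect sizes of any real tissue are reproduced.

## Problem sizes and numerical choices

The planted-signal experiments run at 200 focal + 200 non-focal training
instances per cell type with 20 repetitions, and the determinism check uses
a 5-focal-gene fixture with 2 repetitions — sizes chosen so the full suite
completes comfortably on a laptop-class single core while leaving the
planted contrasts unambiguous. Degenerate inputs are handled explicitly:
zero-variance predictors are centred but not scaled; k values exceeding the
smallest training fold are dropped with a note; groups too small for a rank
or paired test return a flagged `NA` rather than a fabricated p value; a
skipped TSS exactly at an enhancer midpoint has undefined orientation and
is flagged. Distance ties in the kNN sort break toward the smaller training
row index, making every reported number reproducible bit-for-bit under a
fixed seed.

## Limitations

Trees are built from called loops only; contact matrices, TADs and loop
calling itself are out of scope. One TSS per gene is assumed for promoter
windows. ESS is an input, not recomputed from single-cell data. The
accuracy-based effect size is granular at 1/n per model (n = training-set
size), so at desk scale small effects quantise; repetitions and the paired
design mitigate but do not remove this.
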