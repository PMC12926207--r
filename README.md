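# epictrees

Graph-based enhancer-promoter tree models and in silico enhancer
perturbation scoring for cell-type-resolved chromatin data.

## The problem

H3K27ac HiChIP and similar assays report chromatin loops as pairs of
genomic anchors with paired-end-tag (PET) counts, per cell type. Pairwise
loop lists obscure the structure that matters for gene regulation: which
enhancers reach which promoter, directly or through other enhancers, and
which of them actually drive cell-type-specific transcription. `epictrees`
is for regulatory genomicists who have called loops and accessibility
peaks (and per-gene expression specificity scores) and want to:

- build **enhancer trees** — one rooted graph per promoter, enhancers on
  levels by connectivity — and **enhancer forests** (trees joined by shared
  nodes or promoter-promoter loops);
- quantify connectivity: direct (E1/L1) versus indirect interactions,
  enhancer sharing, promoter-promoter hubs, nearest-promoter skipping;
- score every enhancer's contribution to cell-type-specific expression by
  deleting it in silico from the trees and measuring the loss of classifier
  accuracy;
- annotate disease-associated SNPs with candidate enhancers and target
  genes.

## The model

Consensus anchors are the genome-wide merge of all loop anchors; an anchor
whose midpoint falls in a promoter window (TSS −2 kb / +3 kb, strand-aware)
is a promoter node P, otherwise an enhancer node E, named
`<chrom>.<rank><P|E>`. For one cell type, nodes and loops form a graph; for
each promoter the node levels are breadth-first distances from that root
(`L_N(root) = 0`, direct enhancers `E1` at level 1, ...), edge levels are
endpoint sums (`L_E(e) = L_N(n1) + L_N(n2)`), and equal-level edges are
pruned as redundant, leaving only odd-level edges (L1, L3, ...).

Each tree gene is described by 24 chromatin predictors — per cell type, the
summed ATAC of direct enhancer nodes, summed PET of direct edges, their
ATAC×PET product, and the same three for indirect nodes — and a k-nearest-
neighbour classifier (Euclidean distance, per-fold standardisation, k by
10-fold cross-validation) separates cell-type-specific trees (ESS > 0.7)
from non-specific ones (ESS < 0.3 everywhere). The effect size of enhancer
`e` is the mean over repetitions of

    D(e) = Σ_{M ∈ {M_c : c ∈ cell types}} | acc(M) − acc(M \ {e}) |

where `M \ {e}` is the model re-evaluated after removing `e` and its
dependent descendants from every tree of the gene and recomputing the
features. SNPs below an association threshold are intersected with tree
nodes and effect-size distributions of SNP-overlapping versus other
enhancers are compared with a Kolmogorov-Smirnov test.

## Worked example

```r
library(epictrees)

bundle <- simulate_fixture(fixture_spec(seed = 7, n_focal = 25,
                                        n_nonfocal = 60, genes_per_chrom = 25))
anchors <- classify_anchors(
  build_consensus_anchors(do.call(rbind, lapply(bundle$loops, epictrees:::loop_anchors))),
  bundle$genes)
loops <- build_consensus_loops(bundle$loops, anchors)
trees <- setNames(lapply(bundle$cell_types, function(ct)
  extract_trees(anchors, loops, ct)), bundle$cell_types)
atac  <- atac_by_node(anchors, bundle$peaks, bundle$cell_types)

print(trees$beta)
#> enhancer_trees (beta): 101 trees, 495 node instances, 394 edges, 164 PP loops, 0 orphan enhancers

st <- connectivity_stats(trees$beta, detect_forests(trees$beta, anchors))
#> E1 enhancers: 80%   L1 loops: 80%   trees in forests: 99%

es <- rank_enhancers(epic_effect_sizes(trees, atac, bundle$expression,
                                       n_reps = 10, seed = 7))
#> tree-model CV accuracy (4 cell types): 0.93 0.97 0.97 0.91
head(es[es$cell_type == "beta", c("tree_id", "node_name", "effect_size", "rank")], 5)
#>         tree_id node_name effect_size rank
#> 329 beta.1.124P    1.128E       0.012    1
#> 330 beta.1.124P    1.127E       0.010    2
#> 331 beta.1.124P    1.120E       0.006    3
#> 332 beta.1.124P    1.126E       0.006    4
#> 333 beta.1.124P    1.119E       0.004    5
```

Most enhancers loop directly to their promoter (80% E1 here), nearly every
tree sits in a forest, the four cell-type classifiers separate specific
from non-specific trees well above chance, and within each tree the
enhancers are ranked by the accuracy their deletion costs — the top-ranked
node of `beta.1.124P` is the generator's planted critical enhancer for that
gene.

The same analyses run from the shell over a fixture directory:

```sh
Rscript inst/cli/epictrees.R simulate --out fix/ --seed 1
Rscript inst/cli/epictrees.R run --in fix/ --out results/ --seed 1 --n-reps 20
```

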