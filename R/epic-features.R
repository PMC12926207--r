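#' ATAC tag values per consensus anchor node
#'
#' Maps an accessibility peak table onto the consensus anchors by any
#' overlap, summing tag values of all peaks hitting an anchor, per cell
#' type. Anchors without a peak get 0.
#'
#' @param anchors classified consensus anchors
#' @param peaks peak table from [read_peaks()]
#' @param cell_types cell-type labels
#' @return data.frame `node_name` plus `atac_<cell type>` columns
#' @export
atac_by_node <- function(anchors, peaks, cell_types) {
  out <- data.frame(node_name = anchors$node_name, stringsAsFactors = FALSE)
  hits <- GenomicRanges::findOverlaps(as_granges(peaks), as_granges(anchors))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (ct in cell_types) {
    v <- numeric(nrow(anchors))
    if (length(qh)) {
      s <- tapply(peaks[[paste0("atac_", ct)]][qh], sh, sum)
      v[as.integer(names(s))] <- as.numeric(s)
    }
    out[[paste0("atac_", ct)]] <- v
  }
  out
}

epic_feature_names <- function(cell_types) {
  as.vector(t(outer(cell_types, c("atac_d", "pet_d", "atacxpet_d",
                                  "atac_i", "pet_i", "atacxpet_i"),
                    function(ct, f) paste0(f, "_", ct))))
}

# Per-(cell type, gene) tree structure cache used by featurize and the
# perturbation engine. parent_pet is the summed PET of the node's edges to
# the level below (its parent side).
tree_gene_cache <- function(tr, atac, gene_id) {
  tid <- tr$trees$tree_id[tr$trees$gene_id == gene_id]
  if (!length(tid)) return(NULL)
  nodes <- tr$nodes[tr$nodes$tree_id %in% tid, , drop = FALSE]
  edges <- tr$edges[tr$edges$tree_id %in% tid, , drop = FALSE]
  acol <- paste0("atac_", tr$cell_type)
  lev <- setNames(nodes$level, paste(nodes$tree_id, nodes$node_name))
  l1 <- lev[paste(edges$tree_id, edges$n1)]
  child <- ifelse(unname(l1) < edges$level - unname(l1), edges$n2, edges$n1)
  parent_key <- paste(edges$tree_id, child)
  ppet <- tapply(edges$pet, parent_key, sum)
  nodes$atac <- atac[[acol]][match(nodes$node_name, atac$node_name)]
  nodes$atac[is.na(nodes$atac)] <- 0
  nodes$parent_pet <- as.numeric(ppet[paste(nodes$tree_id, nodes$node_name)])
  nodes$parent_pet[is.na(nodes$parent_pet)] <- 0
  list(tree_ids = tid, nodes = nodes, edges = edges,
       roots = tr$trees$root[tr$trees$gene_id == gene_id])
}

# The six per-cell-type features from a cache, optionally with a set of
# removed node instances (paste(tree_id, node_name) keys).
features_from_cache <- function(cache, removed_keys = NULL) {
  if (is.null(cache)) return(c(0, 0, 0, 0, 0, 0))
  nd <- cache$nodes; ed <- cache$edges
  if (!is.null(removed_keys) && length(removed_keys)) {
    nd <- nd[!paste(nd$tree_id, nd$node_name) %in% removed_keys, , drop = FALSE]
    keep <- !(paste(ed$tree_id, ed$n1) %in% removed_keys |
              paste(ed$tree_id, ed$n2) %in% removed_keys)
    ed <- ed[keep, , drop = FALSE]
    # parent_pet must reflect surviving edges only
    lev <- setNames(nd$level, paste(nd$tree_id, nd$node_name))
    if (nrow(ed)) {
      l1 <- lev[paste(ed$tree_id, ed$n1)]
      child <- ifelse(unname(l1) < ed$level - unname(l1), ed$n2, ed$n1)
      ppet <- tapply(ed$pet, paste(ed$tree_id, child), sum)
      nd$parent_pet <- as.numeric(ppet[paste(nd$tree_id, nd$node_name)])
      nd$parent_pet[is.na(nd$parent_pet)] <- 0
    } else nd$parent_pet <- 0
  }
  d <- nd$level == 1; i <- nd$level >= 2
  c(atac_d = sum(nd$atac[d]),
    pet_d = sum(ed$pet[ed$level == 1]),
    atacxpet_d = sum(nd$atac[d] * nd$parent_pet[d]),
    atac_i = sum(nd$atac[i]),
    pet_i = sum(ed$pet[ed$level > 1]),
    atacxpet_i = sum(nd$atac[i] * nd$parent_pet[i]))
}

#' Chromatin feature vector for one gene
#'
#' For each cell type, six predictors computed from that cell type's
#' enhancer tree for the gene: summed ATAC of direct (level 1) enhancer
#' nodes, summed PET of direct (L1) edges, the summed ATAC x PET product
#' (each enhancer node paired with its parent-side edges), and the same
#' three for indirect (level >= 2) nodes and deeper edges. All six are 0 for
#' cell types where the gene has no tree. With the default four cell types
#' this is the 24-predictor vector.
#'
#' @param gene_id gene identifier
#' @param trees_by_ct named list of `enhancer_trees` objects, one per cell
#'   type
#' @param atac node accessibility table from [atac_by_node()]
#' @return named numeric vector of length `6 * length(trees_by_ct)`
#' @export
featurize <- function(gene_id, trees_by_ct, atac) {
  cell_types <- names(trees_by_ct)
  v <- unlist(lapply(cell_types, function(ct) {
    features_from_cache(tree_gene_cache(trees_by_ct[[ct]], atac, gene_id))
  }))
  setNames(v, epic_feature_names(cell_types))
}

#' Feature matrix for a set of genes
#'
#' @param gene_ids character vector of genes
#' @param trees_by_ct named list of `enhancer_trees` objects
#' @param atac node accessibility table
#' @return numeric matrix, genes in rows; per-gene tree caches are attached
#'   as attribute `"caches"` (a list by cell type, then gene) for reuse by
#'   the perturbation engine
#' @export
build_feature_matrix <- function(gene_ids, trees_by_ct, atac) {
  cell_types <- names(trees_by_ct)
  caches <- lapply(trees_by_ct, function(tr) {
    with_tree <- intersect(gene_ids, tr$trees$gene_id)
    setNames(lapply(with_tree, function(g) tree_gene_cache(tr, atac, g)), with_tree)
  })
  X <- matrix(0, nrow = length(gene_ids), ncol = 6L * length(cell_types),
              dimnames = list(gene_ids, epic_feature_names(cell_types)))
  for (ci in seq_along(cell_types)) {
    cols <- (ci - 1L) * 6L + 1:6
    cc <- caches[[ci]]
    for (g in names(cc)) X[g, cols] <- features_from_cache(cc[[g]])
  }
  attr(X, "caches") <- caches
  X
}

#' Build a balanced training set for one focal cell type
#'
#' Positives are tree genes whose ESS exceeds `ess_hi` in the focal cell
#' type; negatives are a seeded random sample, matched in count, of tree
#' genes whose ESS is below `ess_lo` in every cell type. When the eligible
#' pool is smaller than the positive count, all pool genes are used with a
#' warning.
#'
#' @param expression expression table
#' @param cell_type focal cell-type label
#' @param tree_genes_by_ct named list: genes with a tree, per cell type
#' @param ess_hi,ess_lo specificity thresholds (defaults 0.7, 0.3)
#' @param seed integer seed for the negative draw
#' @return data.frame `gene_id`, `class` (factor: `focal`, `nonfocal`)
#' @export
build_training_set <- function(expression, cell_type, tree_genes_by_ct,
                               ess_hi = 0.7, ess_lo = 0.3, seed = 1L) {
  cell_types <- names(tree_genes_by_ct)
  ess <- as.matrix(expression[, ct_cols("ess", cell_types), drop = FALSE])
  rownames(ess) <- expression$gene_id
  any_tree <- unique(unlist(tree_genes_by_ct, use.names = FALSE))
  pos <- intersect(tree_genes_by_ct[[cell_type]],
                   expression$gene_id[ess[, paste0("ess_", cell_type)] > ess_hi])
  pool <- intersect(any_tree,
                    expression$gene_id[apply(ess < ess_lo, 1, all)])
  pos <- sort(pos); pool <- sort(setdiff(pool, pos))
  if (length(pool) < length(pos)) {
    warnf("only %d eligible negatives for %d positives; using all", length(pool), length(pos))
    neg <- pool
  } else {
    neg <- with_seed(seed, sample(pool, length(pos)))
  }
  data.frame(gene_id = c(pos, neg),
             class = factor(rep(c("focal", "nonfocal"), c(length(pos), length(neg))),
                            levels = c("nonfocal", "focal")),
             stringsAsFactors = FALSE)
}

#' Promoter-accessibility baseline features
#'
#' One predictor per cell type: the summed ATAC tag value at the gene's
#' promoter anchor(s), with no loop information.
#'
#' @param gene_ids genes to featurise
#' @param anchors classified consensus anchors
#' @param atac node accessibility table
#' @param cell_types cell-type labels
#' @return numeric matrix, genes in rows
#' @export
promoter_features <- function(gene_ids, anchors, atac, cell_types) {
  X <- matrix(0, nrow = length(gene_ids), ncol = length(cell_types),
              dimnames = list(gene_ids, ct_cols("prom_atac", cell_types)))
  panch <- anchors[anchors$node_kind == "P" & anchors$gene_id %in% gene_ids, ]
  av <- atac[match(panch$node_name, atac$node_name), , drop = FALSE]
  for (ci in seq_along(cell_types)) {
    s <- tapply(av[[paste0("atac_", cell_types[ci])]], panch$gene_id, sum)
    X[names(s), ci] <- as.numeric(s)
  }
  X
}

#' Linear regulatory-domain baseline features
#'
#' One predictor per cell type: the ATAC tag values of enhancer anchors
#' within `window` bp of the TSS, each weighted inversely by its genomic
#' distance (`1 kb / distance`), summed. Enhancers at distance 0 are
#' excluded (the promoter window owns them).
#'
#' @param gene_ids genes to featurise
#' @param genes gene table (TSS lookup)
#' @param anchors classified consensus anchors
#' @param atac node accessibility table
#' @param cell_types cell-type labels
#' @param window regulatory-domain half-width in bp (default 1 Mb)
#' @return numeric matrix, genes in rows
#' @export
linear_features <- function(gene_ids, genes, anchors, atac, cell_types,
                            window = 1e6) {
  X <- matrix(0, nrow = length(gene_ids), ncol = length(cell_types),
              dimnames = list(gene_ids, ct_cols("lin_atac", cell_types)))
  enh <- anchors[anchors$node_kind == "E", , drop = FALSE]
  av <- atac[match(enh$node_name, atac$node_name), , drop = FALSE]
  g <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  for (i in seq_along(gene_ids)) {
    if (is.na(g$tss[i])) next
    same <- enh$chrom == g$chrom[i]
    d <- abs(enh$midpoint[same] - g$tss[i])
    ok <- d > 0 & d <= window
    if (!any(ok)) next
    w <- 1000 / d[ok]
    for (ci in seq_along(cell_types)) {
      X[i, ci] <- sum(av[[paste0("atac_", cell_types[ci])]][same][ok] * w)
    }
  }
  X
}
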