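#' Detect enhancer forests
#'
#' A forest is a set of two or more enhancer trees connected through shared
#' anchor nodes or through a promoter-promoter loop joining their roots.
#' Forests are the multi-tree connected components of the tree-level graph
#' (trees as vertices); singleton components are not forests.
#'
#' @param tr an `enhancer_trees` object from [extract_trees()]
#' @param anchors consensus anchors (for genomic spans)
#' @return list with `membership` (tree_id, forest_id; `NA` for singletons)
#'   and `forests` (forest_id, n_trees, n_nodes, span_bp)
#' @export
detect_forests <- function(tr, anchors) {
  tree_ids <- tr$trees$tree_id
  if (!length(tree_ids)) {
    return(list(membership = data.frame(tree_id = character(), forest_id = character()),
                forests = data.frame(forest_id = character(), n_trees = integer(),
                                     n_nodes = integer(), span_bp = numeric())))
  }
  e1 <- character(); e2 <- character()
  # shared anchor nodes: chain the trees containing each node
  by_node <- split(tr$nodes$tree_id, tr$nodes$node_name)
  for (tt in by_node) {
    tt <- unique(tt)
    if (length(tt) > 1) { e1 <- c(e1, tt[-length(tt)]); e2 <- c(e2, tt[-1]) }
  }
  # promoter-promoter loops joining roots of two trees
  root_tree <- setNames(tr$trees$tree_id, tr$trees$root)
  pp <- tr$pp_edges
  ok <- pp$n1 %in% names(root_tree) & pp$n2 %in% names(root_tree)
  e1 <- c(e1, unname(root_tree[pp$n1[ok]]))
  e2 <- c(e2, unname(root_tree[pp$n2[ok]]))
  g <- igraph::graph_from_data_frame(data.frame(e1, e2), directed = FALSE,
                                     vertices = tree_ids)
  comp <- igraph::components(g)
  member <- comp$membership[tree_ids]
  sizes <- comp$csize[member]
  forest_id <- ifelse(sizes >= 2, paste0(tr$cell_type, ".F", member), NA_character_)
  membership <- data.frame(tree_id = tree_ids, forest_id = forest_id,
                           stringsAsFactors = FALSE)
  fstats <- list()
  amap <- anchors[match(tr$nodes$node_name, anchors$node_name), ]
  for (fid in unique(stats::na.omit(forest_id))) {
    tt <- tree_ids[!is.na(forest_id) & forest_id == fid]
    sel <- tr$nodes$tree_id %in% tt
    nn <- unique(tr$nodes$node_name[sel])
    ai <- anchors[match(nn, anchors$node_name), ]
    span <- sum(vapply(split(seq_len(nrow(ai)), ai$chrom),
                       function(i) max(ai$end[i]) - min(ai$start[i]), 0))
    fstats[[fid]] <- data.frame(forest_id = fid, n_trees = length(tt),
                                n_nodes = length(nn), span_bp = span,
                                stringsAsFactors = FALSE)
  }
  forests <- if (length(fstats)) do.call(rbind, fstats) else
    data.frame(forest_id = character(), n_trees = integer(),
               n_nodes = integer(), span_bp = numeric())
  rownames(forests) <- NULL
  list(membership = membership, forests = forests)
}

#' Connectivity summary over trees and forests
#'
#' Tabulates, for one cell type: node and edge counts by level, the orphan
#' enhancer fraction, the enhancer multiplicity histogram (enhancers looping
#' to 1, 2, or 3+ promoters), the fraction of trees in forests, forest size
#' and span medians, the fractions of trees linked to other trees through
#' promoter-promoter loops or shared enhancers, and direct (E1/L1) versus
#' indirect fractions. Because the published notion of "indirect" can count
#' either edges or enhancer nodes, both tabulations are returned.
#'
#' @param tr an `enhancer_trees` object
#' @param forests result of [detect_forests()]
#' @return named list of summary statistics
#' @export
connectivity_stats <- function(tr, forests) {
  nodes <- tr$nodes; edges <- tr$edges
  enh <- nodes[nodes$kind == "E", , drop = FALSE]
  node_levels <- table(factor(enh$level, levels = sort(unique(enh$level))))
  edge_levels <- table(factor(edges$level, levels = sort(unique(edges$level))))
  n_enh_anchor <- length(unique(enh$node_name))
  orphan_fraction <- if (n_enh_anchor + length(tr$orphans) > 0)
    length(tr$orphans) / (n_enh_anchor + length(tr$orphans)) else NA_real_
  mult <- table(tapply(enh$tree_id, enh$node_name, function(x) length(unique(x))))
  m <- as.integer(names(mult))
  multiplicity <- c(`1` = sum(mult[m == 1]), `2` = sum(mult[m == 2]),
                    `3+` = sum(mult[m >= 3]))
  in_forest <- !is.na(forests$membership$forest_id)
  root_set <- tr$trees$root
  pp_linked <- tr$trees$root %in% c(tr$pp_edges$n1, tr$pp_edges$n2)
  shared <- names(which(table(unique(enh[c("tree_id", "node_name")])$node_name) > 1))
  enh_linked <- vapply(split(enh$node_name, enh$tree_id),
                       function(x) any(x %in% shared), FALSE)[tr$trees$tree_id]
  list(
    cell_type = tr$cell_type,
    n_trees = nrow(tr$trees),
    n_node_instances = nrow(nodes),
    n_edges = nrow(edges),
    node_level_counts = as.list(node_levels),
    edge_level_counts = as.list(edge_levels),
    orphan_fraction = orphan_fraction,
    multiplicity_histogram = as.list(multiplicity),
    multiplicity_fraction_single = unname(multiplicity["1"] / max(1, sum(multiplicity))),
    fraction_trees_in_forests = mean(in_forest),
    median_forest_trees = if (nrow(forests$forests)) median(forests$forests$n_trees) else NA_real_,
    median_forest_nodes = if (nrow(forests$forests)) median(forests$forests$n_nodes) else NA_real_,
    median_forest_span_bp = if (nrow(forests$forests)) median(forests$forests$span_bp) else NA_real_,
    fraction_trees_pp_linked = mean(pp_linked),
    fraction_trees_enhancer_linked = mean(unname(enh_linked), na.rm = TRUE),
    e1_fraction_instances = if (nrow(enh)) mean(enh$level == 1) else NA_real_,
    e1_fraction_anchors = if (n_enh_anchor) {
      minlev <- tapply(enh$level, enh$node_name, min)
      mean(minlev == 1)
    } else NA_real_,
    l1_fraction_edges = if (nrow(edges)) mean(edges$level == 1) else NA_real_,
    indirect_fraction_edges = if (nrow(edges)) mean(edges$level > 1) else NA_real_,
    indirect_fraction_nodes = if (nrow(enh)) mean(enh$level > 1) else NA_real_)
}

#' Compare promoter-promoter connectivity of specific and non-specific forests
#'
#' Counts promoter-promoter loops internal to each forest (both endpoint
#' promoters root member trees), splits forests by whether any member gene is
#' cell-type specific (ESS above `ess_hi` in this cell type), and compares
#' the two groups with a two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param tr an `enhancer_trees` object
#' @param forests result of [detect_forests()]
#' @param expression expression table (see [read_expression()])
#' @param ess_hi specificity threshold (default 0.7)
#' @return list with per-forest counts, group medians, the rank-sum statistic
#'   and two-sided p value. When either group has fewer than 2 forests the
#'   test is undefined and flagged (`p_value = NA`, `flag`).
#' @export
pp_comparison <- function(tr, forests, expression, ess_hi = 0.7) {
  ess_col <- paste0("ess_", tr$cell_type)
  if (!ess_col %in% names(expression)) stopf("no column '%s' in expression table", ess_col)
  ess <- setNames(expression[[ess_col]], expression$gene_id)
  fids <- forests$forests$forest_id
  if (!length(fids))
    return(list(groups = data.frame(), median_specific = NA_real_,
                median_other = NA_real_, statistic = NA_real_,
                p_value = NA_real_, flag = "no forests"))
  memb <- forests$membership
  rows <- lapply(fids, function(fid) {
    tt <- memb$tree_id[!is.na(memb$forest_id) & memb$forest_id == fid]
    roots <- tr$trees$root[tr$trees$tree_id %in% tt]
    genes <- tr$trees$gene_id[tr$trees$tree_id %in% tt]
    npp <- sum(tr$pp_edges$n1 %in% roots & tr$pp_edges$n2 %in% roots)
    spec <- any(ess[genes] > ess_hi, na.rm = TRUE)
    data.frame(forest_id = fid, pp_count = npp, specific = spec)
  })
  groups <- do.call(rbind, rows)
  a <- groups$pp_count[groups$specific]; b <- groups$pp_count[!groups$specific]
  if (length(a) < 2 || length(b) < 2) {
    return(list(groups = groups, median_specific = median(a), median_other = median(b),
                statistic = NA_real_, p_value = NA_real_,
                flag = "fewer than 2 forests in a group"))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided", exact = FALSE))
  list(groups = groups, median_specific = median(a), median_other = median(b),
       statistic = unname(wt$statistic), p_value = wt$p.value, flag = NULL)
}
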