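#' Assign breadth-first levels from a root node
#'
#' The root gets level 0; every node reachable from the root gets the length
#' of its shortest path, never traversing through a blocked node (other
#' promoters, when building trees). Unreachable and blocked nodes get `NA`.
#' BFS shortest-path levels are the unique fixpoint of the iterative
#' one-greater-than-a-neighbour assignment that is consistent with redundancy
#' pruning (pruned nodes keep their shorter path to the root).
#'
#' @param edges data.frame with columns `n1`, `n2` (node names)
#' @param root name of the starting node
#' @param nodes optional full node set (defaults to nodes appearing in edges
#'   plus the root)
#' @param blocked node names that must not be traversed or assigned
#' @return named integer vector of levels (`NA` = unassigned)
#' @export
assign_levels <- function(edges, root, nodes = NULL, blocked = character()) {
  nodes <- nodes %||% unique(c(root, edges$n1, edges$n2))
  if (!root %in% nodes) stopf("root '%s' not in graph", root)
  adj <- adjacency_list(edges, nodes)
  lev <- setNames(rep(NA_integer_, length(nodes)), nodes)
  lev[root] <- 0L
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(lev[nxt]) & !nxt %in% blocked]
    lev[nxt] <- d
    frontier <- nxt
  }
  lev
}

adjacency_list <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    sp <- split(c(edges$n2, edges$n1), c(edges$n1, edges$n2))
    adj[names(sp)] <- lapply(sp, unique)
  }
  adj
}

#' Assign edge levels from node levels
#'
#' An edge between two leveled nodes gets the sum of the node levels; edges
#' touching an unleveled node stay `NA`.
#'
#' @param edges data.frame with `n1`, `n2`
#' @param levels named integer vector from [assign_levels()]
#' @return `edges` with a `level` column
#' @export
assign_edge_levels <- function(edges, levels) {
  edges$level <- unname(levels[edges$n1] + levels[edges$n2])
  edges
}

#' Remove redundant equal-level edges
#'
#' Deletes every edge whose two endpoints have the same level. After pruning,
#' all remaining leveled edges have odd level (the endpoints differ by
#' exactly one), and node levels are untouched: an equal-level edge can never
#' lie on a shortest path from the root.
#'
#' @param edges data.frame with `n1`, `n2` (and optionally `level`)
#' @param levels named integer vector of node levels
#' @return the pruned edge table
#' @export
prune_redundant <- function(edges, levels) {
  l1 <- levels[edges$n1]; l2 <- levels[edges$n2]
  same <- !is.na(l1) & !is.na(l2) & l1 == l2
  out <- edges[!same, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract enhancer trees for one cell type
#'
#' The per-cell-type subgraph consists of consensus loops with a PET count of
#' at least `min_pet` in that cell type. Each promoter node with at least one
#' incident enhancer edge roots one tree; traversal never crosses another
#' promoter node, promoter-promoter loops are kept out of trees (recorded
#' separately for forest linkage), and an enhancer reachable from several
#' promoters appears in each such tree with its per-tree level. Equal-level
#' edges are pruned. Enhancers in components without any promoter are
#' reported as orphans.
#'
#' @param anchors classified consensus anchors ([classify_anchors()])
#' @param loops consensus loop table ([build_consensus_loops()])
#' @param cell_type cell-type label (a `pet_<cell_type>` column must exist)
#' @param min_pet minimum PET count for an edge to belong to the cell type
#' @return an object of class `enhancer_trees`: list with `cell_type`,
#'   `trees` (tree_id, root, gene_id, n_enhancers, n_edges), `nodes`
#'   (tree_id, node_name, level, kind), `edges` (tree_id, n1, n2, level,
#'   pet), `pp_edges` (n1, n2, pet), `orphans` (node names), `min_pet`
#' @export
extract_trees <- function(anchors, loops, cell_type, min_pet = 1) {
  pet_col <- paste0("pet_", cell_type)
  if (!pet_col %in% names(loops)) stopf("no column '%s' in loop table", pet_col)
  sub <- loops[loops[[pet_col]] >= min_pet, , drop = FALSE]
  kind <- setNames(anchors$node_kind, anchors$node_name)
  gene <- setNames(anchors$gene_id, anchors$node_name)
  p1 <- kind[sub$n1] == "P"; p2 <- kind[sub$n2] == "P"
  pp <- data.frame(n1 = sub$n1[p1 & p2], n2 = sub$n2[p1 & p2],
                   pet = sub[[pet_col]][p1 & p2], stringsAsFactors = FALSE)
  te <- sub[!(p1 & p2), , drop = FALSE]   # edges with >= 1 enhancer endpoint
  te_df <- data.frame(n1 = te$n1, n2 = te$n2, pet = te[[pet_col]],
                      stringsAsFactors = FALSE)
  nodeset <- unique(c(te_df$n1, te_df$n2))
  promoters <- nodeset[kind[nodeset] == "P"]
  adj <- adjacency_list(te_df, nodeset)
  # index edges by incident node for induced-subgraph lookup
  edge_nodes1 <- te_df$n1; edge_nodes2 <- te_df$n2
  trees <- list(); node_rows <- list(); edge_rows <- list()
  for (p in promoters) {
    blocked <- setdiff(promoters, p)
    lev <- bfs_levels(p, adj, blocked)
    reached <- names(lev)
    if (length(reached) < 2L) next          # no enhancer connected
    in_tree <- edge_nodes1 %in% reached & edge_nodes2 %in% reached
    ed <- te_df[in_tree, , drop = FALSE]
    ed$level <- unname(lev[ed$n1] + lev[ed$n2])
    ed <- prune_redundant(ed, lev)
    if (!nrow(ed)) next
    tid <- paste0(cell_type, ".", p)
    trees[[tid]] <- data.frame(tree_id = tid, root = p,
      gene_id = unname(gene[p]),
      n_enhancers = length(reached) - 1L, n_edges = nrow(ed),
      stringsAsFactors = FALSE)
    node_rows[[tid]] <- data.frame(tree_id = tid, node_name = reached,
      level = unname(lev[reached]), kind = unname(kind[reached]),
      stringsAsFactors = FALSE)
    ed$tree_id <- tid
    edge_rows[[tid]] <- ed[, c("tree_id", "n1", "n2", "level", "pet")]
  }
  # orphans: enhancer nodes in components with no promoter
  orphans <- character()
  if (length(nodeset)) {
    comp <- components_by_bfs(nodeset, adj)
    has_p <- tapply(kind[nodeset] == "P", comp, any)
    orphan_comp <- names(has_p)[!has_p]
    orphans <- nodeset[comp %in% orphan_comp]
  }
  structure(list(
    cell_type = cell_type,
    trees = if (length(trees)) do.call(rbind, trees) else
      data.frame(tree_id = character(), root = character(),
                 gene_id = character(), n_enhancers = integer(),
                 n_edges = integer()),
    nodes = if (length(node_rows)) do.call(rbind, node_rows) else
      data.frame(tree_id = character(), node_name = character(),
                 level = integer(), kind = character()),
    edges = if (length(edge_rows)) do.call(rbind, edge_rows) else
      data.frame(tree_id = character(), n1 = character(), n2 = character(),
                 level = integer(), pet = numeric()),
    pp_edges = pp,
    orphans = orphans,
    min_pet = min_pet), class = "enhancer_trees")
}

# BFS levels restricted to reached nodes only (named vector over reached set).
bfs_levels <- function(root, adj, blocked) {
  lev <- setNames(0L, root)
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!nxt %in% names(lev) & !nxt %in% blocked]
    if (!length(nxt)) break
    lev <- c(lev, setNames(rep(d, length(nxt)), nxt))
    frontier <- nxt
  }
  lev
}

# Connected-component labels by repeated BFS (no blocking).
components_by_bfs <- function(nodes, adj) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (n in nodes) {
    if (!is.na(comp[n])) next
    k <- k + 1L
    frontier <- n
    comp[n] <- k
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  comp
}

#' @export
print.enhancer_trees <- function(x, ...) {
  cat(sprintf("enhancer_trees (%s): %d trees, %d node instances, %d edges, %d PP loops, %d orphan enhancers\n",
      x$cell_type, nrow(x$trees), nrow(x$nodes), nrow(x$edges),
      nrow(x$pp_edges), length(x$orphans)))
  invisible(x)
}
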