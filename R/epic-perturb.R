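#' Remove an enhancer node and its dependent subtree
#'
#' Removes enhancer node `e`, all edges incident to it, and every node whose
#' every path to the root passes through `e` (nodes left unreachable).
#' Surviving nodes keep their original levels.
#'
#' @param nodes tree node table (`node_name`, `level`, ...)
#' @param edges tree edge table (`n1`, `n2`, ...)
#' @param root the promoter node name
#' @param e enhancer node to remove (the root is rejected)
#' @return list with the surviving `nodes` and `edges`
#' @export
perturb_tree <- function(nodes, edges, root, e) {
  if (identical(e, root)) stopf("cannot remove the root promoter node")
  if (!e %in% nodes$node_name) stopf("node '%s' not in tree", e)
  keep_e <- edges$n1 != e & edges$n2 != e
  ed <- edges[keep_e, , drop = FALSE]
  remaining <- setdiff(nodes$node_name, e)
  adj <- adjacency_list(ed, remaining)
  lev <- bfs_levels(root, adj, blocked = character())
  surv <- intersect(remaining, names(lev))
  out_nodes <- nodes[nodes$node_name %in% surv, , drop = FALSE]
  out_edges <- ed[ed$n1 %in% surv & ed$n2 %in% surv, , drop = FALSE]
  rownames(out_nodes) <- rownames(out_edges) <- NULL
  list(nodes = out_nodes, edges = out_edges)
}

#' Total accuracy deviation across cell-type models
#'
#' The removal score of an enhancer for one repetition: the sum of absolute
#' cross-validated accuracy deviations over the cell-type classifiers.
#'
#' @param deviations numeric vector of per-model accuracy deviations
#' @return sum of absolute deviations
#' @export
effect_size_total <- function(deviations) sum(abs(deviations))

# node-instance keys (tree_id SPACE node_name) removed when anchor `e` is
# deleted from gene cache `cache`: e plus all nodes unreachable from each
# root without it
removal_keys <- function(cache, e) {
  keys <- character()
  for (i in seq_along(cache$tree_ids)) {
    tid <- cache$tree_ids[i]; root <- cache$roots[i]
    nd <- cache$nodes[cache$nodes$tree_id == tid, , drop = FALSE]
    if (!e %in% nd$node_name) next
    ed <- cache$edges[cache$edges$tree_id == tid, , drop = FALSE]
    pt <- perturb_tree(nd, ed, root, e)
    gone <- setdiff(nd$node_name, pt$nodes$node_name)
    keys <- c(keys, paste(tid, gone))
  }
  keys
}

#' In silico enhancer perturbation effect sizes
#'
#' For every enhancer node of the target trees, repeatedly (1) draws the
#' negative class and cross-validation folds, (2) trains the per-cell-type
#' kNN classifiers on the chromatin feature matrix, (3) removes the enhancer
#' (and its dependent subtree, in every cell type's tree of the gene that
#' contains the anchor), recomputes the gene's features, and re-evaluates
#' every affected classifier on the same folds with the same selected k, and
#' (4) sums the absolute accuracy deviations across the cell-type models.
#' The effect size of an enhancer is the mean of this total deviation over
#' repetitions.
#'
#' @param trees_by_ct named list of `enhancer_trees` (the cell types entering
#'   the classifiers; typically four)
#' @param atac node accessibility table ([atac_by_node()])
#' @param expression expression table
#' @param targets optional data.frame (`cell_type`, `gene_id`) restricting
#'   which trees are scored; default: every cell-type-specific (positive)
#'   tree of every cell type
#' @param n_reps repetitions (default 100)
#' @param folds,k_grid cross-validation settings
#' @param ess_hi,ess_lo class thresholds
#' @param seed master seed; all negative draws and fold splits derive from it
#' @param redraw_negatives re-draw the negative sample each repetition
#'   (default TRUE); folds are re-split either way
#' @return data.frame (`cell_type`, `tree_id`, `gene_id`, `node_name`,
#'   `effect_size`, `n_reps`) with the per-repetition deviation matrix in
#'   attribute `"reps"` and the mean original model accuracies in attribute
#'   `"cv_accuracy"`
#' @export
epic_effect_sizes <- function(trees_by_ct, atac, expression, targets = NULL,
                              n_reps = 100L, folds = 10L,
                              k_grid = seq(3L, 25L, 2L),
                              ess_hi = 0.7, ess_lo = 0.3, seed = 1L,
                              redraw_negatives = TRUE) {
  cell_types <- names(trees_by_ct)
  tree_genes_by_ct <- lapply(trees_by_ct, function(tr) unique(tr$trees$gene_id))
  ess <- as.matrix(expression[, ct_cols("ess", cell_types), drop = FALSE])
  rownames(ess) <- expression$gene_id
  pos_by_ct <- lapply(cell_types, function(ct) {
    sort(intersect(tree_genes_by_ct[[ct]],
                   expression$gene_id[ess[, paste0("ess_", ct)] > ess_hi]))
  })
  names(pos_by_ct) <- cell_types
  pool <- sort(setdiff(
    intersect(unique(unlist(tree_genes_by_ct)),
              expression$gene_id[apply(ess < ess_lo, 1, all)]),
    unlist(pos_by_ct)))
  if (is.null(targets)) {
    targets <- do.call(rbind, lapply(cell_types, function(ct) {
      if (!length(pos_by_ct[[ct]])) return(NULL)
      data.frame(cell_type = ct, gene_id = pos_by_ct[[ct]], stringsAsFactors = FALSE)
    }))
  }
  if (is.null(targets) || !nrow(targets)) stopf("no target trees to score")
  all_genes <- sort(unique(c(unlist(pos_by_ct), pool, targets$gene_id)))
  F0 <- build_feature_matrix(all_genes, trees_by_ct, atac)
  caches <- attr(F0, "caches")

  # enumerate enhancer-node perturbations and their recomputed feature rows
  entries <- list()
  for (i in seq_len(nrow(targets))) {
    ct0 <- targets$cell_type[i]; g <- targets$gene_id[i]
    cc0 <- caches[[ct0]][[g]]
    if (is.null(cc0)) next
    for (tid in cc0$tree_ids) {
      nd <- cc0$nodes[cc0$nodes$tree_id == tid, , drop = FALSE]
      for (e in nd$node_name[nd$level >= 1 & nd$kind == "E"]) {
        row <- F0[g, ]
        for (ci in seq_along(cell_types)) {
          cc <- caches[[cell_types[ci]]][[g]]
          if (is.null(cc) || !e %in% cc$nodes$node_name) next
          cols <- (ci - 1L) * 6L + 1:6
          row[cols] <- features_from_cache(cc, removal_keys(cc, e))
        }
        entries[[length(entries) + 1L]] <- list(
          cell_type = ct0, tree_id = tid, gene_id = g, node_name = e, row = row)
      }
    }
  }
  if (!length(entries)) stopf("target trees contain no enhancer nodes")
  n_e <- length(entries)
  entry_gene <- vapply(entries, `[[`, "", "gene_id")
  changed <- vapply(entries, function(en) any(en$row != F0[en$gene_id, ]), FALSE)

  rep_seeds <- derive_seeds(seed, 2L * n_reps * length(cell_types))
  dim(rep_seeds) <- c(2L, length(cell_types), n_reps)
  D <- matrix(NA_real_, nrow = n_e, ncol = n_reps)
  acc_reps <- matrix(NA_real_, nrow = n_reps, ncol = length(cell_types),
                     dimnames = list(NULL, cell_types))
  neg_fixed <- lapply(seq_along(cell_types), function(ci) {
    n_pos <- length(pos_by_ct[[ci]])
    if (length(pool) <= n_pos) pool else
      with_seed(rep_seeds[1, ci, 1], sample(pool, n_pos))
  })
  for (r in seq_len(n_reps)) {
    models <- vector("list", length(cell_types))
    for (ci in seq_along(cell_types)) {
      ct <- cell_types[ci]
      pos <- pos_by_ct[[ct]]
      if (length(pos) < 2) next
      neg <- if (redraw_negatives) {
        if (length(pool) <= length(pos)) pool else
          with_seed(rep_seeds[1, ci, r], sample(pool, length(pos)))
      } else neg_fixed[[ci]]
      inst <- c(pos, neg)
      y_pos <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
      X <- F0[inst, , drop = FALSE]
      fold <- make_folds(y_pos, folds = folds, seed = rep_seeds[2, ci, r])
      k_use <- k_grid[k_grid <= length(inst) - max(tabulate(fold))]
      votes <- knn_cv_votes_cpp(X, as.integer(y_pos), as.integer(fold),
                                as.integer(k_use))
      acc <- apply(votes, 2, acc_from_votes, y_pos = y_pos)
      best <- which.max(acc)
      models[[ci]] <- list(X = X, y = y_pos, fold = fold, k = k_use[best],
                           acc = unname(acc[best]),
                           rowmap = setNames(seq_along(inst), inst))
      acc_reps[r, ci] <- unname(acc[best])
    }
    for (j in seq_len(n_e)) {
      g <- entry_gene[j]
      dev <- numeric(0)
      for (ci in seq_along(cell_types)) {
        mo <- models[[ci]]
        if (is.null(mo)) next
        ri <- mo$rowmap[g]
        if (is.na(ri)) next
        if (!changed[j]) { dev <- c(dev, 0); next }
        acc_p <- cv_accuracy_swap(mo$X, mo$y, mo$fold, mo$k,
                                  swap_row = unname(ri), new_row = entries[[j]]$row)
        dev <- c(dev, mo$acc - acc_p)
      }
      D[j, r] <- if (length(dev)) effect_size_total(dev) else NA_real_
    }
  }
  undefined <- rowSums(!is.na(D)) == 0
  if (any(undefined))
    warnf("%d enhancer(s) belong to genes absent from every training set; effect size undefined",
          sum(undefined))
  out <- data.frame(
    cell_type = vapply(entries, `[[`, "", "cell_type"),
    tree_id = vapply(entries, `[[`, "", "tree_id"),
    gene_id = entry_gene,
    node_name = vapply(entries, `[[`, "", "node_name"),
    effect_size = rowMeans(D),
    n_reps = n_reps, stringsAsFactors = FALSE)
  attr(out, "reps") <- D
  attr(out, "cv_accuracy") <- colMeans(acc_reps, na.rm = TRUE)
  attr(out, "cv_accuracy_reps") <- acc_reps
  out
}

#' Rank enhancers by effect size within each tree
#'
#' Descending effect size; ties break toward the lexicographically smaller
#' node name, so the ordering is deterministic.
#'
#' @param es effect-size table from [epic_effect_sizes()]
#' @return `es` sorted, with a `rank` column (1 = largest within its tree)
#' @export
rank_enhancers <- function(es) {
  ord <- order(es$tree_id, -es$effect_size, es$node_name)
  out <- es[ord, , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$tree_id, FUN = seq_along)
  rownames(out) <- NULL
  out
}
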