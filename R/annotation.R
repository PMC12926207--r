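#' Extract P0-E1(-E2) chains with genomic distances
#'
#' For every tree, emits one record per P0-E1 pair and one per P0-E1-E2
#' chain. Distances are unsigned base pairs from the node midpoint to the
#' root gene's TSS; `pet_l1` is the PET count of the promoter-E1 edge and
#' `pet_l3` that of the E1-E2 edge.
#'
#' @param tr an `enhancer_trees` object
#' @param anchors classified consensus anchors
#' @param genes gene table (TSS lookup for the roots)
#' @return data.frame of chain records (`e2`, `d_e2`, `pet_l3` are `NA` for
#'   E1 nodes without a child)
#' @export
extract_chains <- function(tr, anchors, genes) {
  mid <- setNames(anchors$midpoint, anchors$node_name)
  tss <- setNames(genes$tss, genes$gene_id)
  out <- list()
  for (i in seq_len(nrow(tr$trees))) {
    tid <- tr$trees$tree_id[i]; gid <- tr$trees$gene_id[i]
    t_tss <- tss[gid]
    if (is.na(t_tss)) next
    nd <- tr$nodes[tr$nodes$tree_id == tid, ]
    ed <- tr$edges[tr$edges$tree_id == tid, ]
    e1s <- nd$node_name[nd$level == 1]
    for (e1 in e1s) {
      l1 <- ed[ed$level == 1 & (ed$n1 == e1 | ed$n2 == e1), ]
      l3 <- ed[ed$level == 3 & (ed$n1 == e1 | ed$n2 == e1), ]
      base <- data.frame(tree_id = tid, cell_type = tr$cell_type, gene_id = gid,
                         e1 = e1, d_e1 = abs(mid[e1] - t_tss),
                         pet_l1 = sum(l1$pet),
                         stringsAsFactors = FALSE)
      if (!nrow(l3)) {
        base$e2 <- NA_character_; base$d_e2 <- NA_real_; base$pet_l3 <- NA_real_
        out[[length(out) + 1L]] <- base
      } else {
        e2s <- ifelse(l3$n1 == e1, l3$n2, l3$n1)
        rec <- base[rep(1L, length(e2s)), ]
        rec$e2 <- e2s
        rec$d_e2 <- abs(mid[e2s] - t_tss)
        rec$pet_l3 <- l3$pet
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tree_id = character(), cell_type = character(),
               gene_id = character(), e1 = character(), d_e1 = numeric(),
               pet_l1 = numeric(), e2 = character(), d_e2 = numeric(),
               pet_l3 = numeric())
  rownames(res) <- NULL
  res[, c("tree_id", "cell_type", "gene_id", "e1", "e2", "d_e1", "d_e2",
          "pet_l1", "pet_l3")]
}

#' Classify a skipped gene's position relative to the enhancer loop
#'
#' `InsideLoop` when the skipped and looped TSS lie on the same side of the
#' enhancer midpoint, `OutsideLoop` when they flank it. Vectorised; a skipped
#' TSS exactly at the midpoint is undefined (`NA`, with a warning).
#'
#' @param mid enhancer midpoint(s)
#' @param looped_tss TSS of the looped gene(s)
#' @param skipped_tss TSS of the skipped gene(s)
#' @return character vector of `"InsideLoop"` / `"OutsideLoop"` / `NA`
#' @export
classify_orientation <- function(mid, looped_tss, skipped_tss) {
  s1 <- sign(looped_tss - mid); s2 <- sign(skipped_tss - mid)
  out <- ifelse(s1 == s2, "InsideLoop", "OutsideLoop")
  undef <- s2 == 0 | s1 == 0
  if (any(undef)) {
    warnf("%d orientation(s) undefined: TSS at the enhancer midpoint", sum(undef))
    out[undef] <- NA_character_
  }
  out
}

#' Nearest-promoter skipping analysis for E1 enhancers
#'
#' For every E1 node instance, finds the nearest TSS in the 5 kb - 1 Mb band
#' around the enhancer midpoint and asks whether the looped (tree root) gene
#' differs from it. Skipping enhancers are annotated with the skipped gene's
#' biotype, the loop orientation, and which gene (looped or skipped) wins on
#' expression specificity and transcript abundance in the tree's cell type.
#'
#' @param tr an `enhancer_trees` object
#' @param anchors classified consensus anchors
#' @param genes gene table
#' @param expression expression table ([read_expression()])
#' @param min_d,max_d nearest-TSS distance band in bp (defaults 5 kb, 1 Mb)
#' @param coding_only restrict the nearest-gene search to coding genes
#' @return data.frame with one row per (tree, E1 node): `skipped` is `NA`
#'   when no gene qualifies in the band; `orientation` is defined only for
#'   skipping rows; winners are `"looped"`, `"skipped"`, `"tie"`, or
#'   `"unknown"` when expression is missing.
#' @export
skipping_analysis <- function(tr, anchors, genes, expression,
                              min_d = 5000L, max_d = 1e6L, coding_only = FALSE) {
  mid <- setNames(anchors$midpoint, anchors$node_name)
  chrom <- setNames(anchors$chrom, anchors$node_name)
  gpool <- if (coding_only) genes[genes$biotype == "coding", , drop = FALSE] else genes
  ess_col <- paste0("ess_", tr$cell_type)
  ab_col <- paste0("abund_", tr$cell_type)
  ess <- setNames(expression[[ess_col]], expression$gene_id)
  ab <- setNames(expression[[ab_col]], expression$gene_id)
  tss <- setNames(genes$tss, genes$gene_id)
  biotype <- setNames(genes$biotype, genes$gene_id)

  e1 <- tr$nodes[tr$nodes$level == 1 & tr$nodes$kind == "E", , drop = FALSE]
  if (!nrow(e1)) return(data.frame())
  gid <- tr$trees$gene_id[match(e1$tree_id, tr$trees$tree_id)]
  m <- unname(mid[e1$node_name]); ch <- unname(chrom[e1$node_name])
  nearest <- nearest_tss(m, ch, gpool, min_d = min_d, max_d = max_d)
  skipped <- ifelse(is.na(nearest), NA, nearest != gid)
  winner <- function(v_l, v_s) {
    ifelse(is.na(v_l) | is.na(v_s), "unknown",
      ifelse(v_l > v_s, "looped", ifelse(v_l < v_s, "skipped", "tie")))
  }
  is_skip <- !is.na(skipped) & skipped
  orientation <- rep(NA_character_, nrow(e1))
  if (any(is_skip))
    orientation[is_skip] <- classify_orientation(m[is_skip],
      unname(tss[gid[is_skip]]), unname(tss[nearest[is_skip]]))
  n_unknown <- sum(is_skip & (is.na(ess[gid]) | is.na(ess[nearest])))
  if (n_unknown)
    message(sprintf("skipping_analysis: %d pair(s) with missing expression marked 'unknown'", n_unknown))
  out <- data.frame(
    cell_type = tr$cell_type, tree_id = e1$tree_id, e1 = e1$node_name,
    looped_gene = gid, nearest_gene = nearest, skipped = skipped,
    skipped_biotype = ifelse(is_skip, unname(biotype[nearest]), NA_character_),
    orientation = orientation,
    ess_winner = ifelse(is_skip, winner(unname(ess[gid]), unname(ess[nearest])), NA_character_),
    abundance_winner = ifelse(is_skip, winner(unname(ab[gid]), unname(ab[nearest])), NA_character_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test over an orientation count table
#'
#' Plain r x c test of independence, no continuity correction;
#' `df = (rows - 1)(cols - 1)`.
#'
#' @param counts matrix or data.frame of non-negative counts (rows = cell
#'   types, columns = orientation classes)
#' @return list with `chi2`, `df`, `p_value`
#' @export
orientation_chisq <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2 || ncol(m) < 2) stopf("need at least a 2x2 table")
  if (any(m < 0)) stopf("counts must be non-negative")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) stopf("zero marginal in row '%s'",
    (rownames(m) %||% as.character(seq_len(nrow(m))))[which(rs == 0)[1]])
  if (any(cs == 0)) stopf("zero marginal in column '%s'",
    (colnames(m) %||% as.character(seq_len(ncol(m))))[which(cs == 0)[1]])
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Expression versus tree size, and paired looped-vs-skipped comparison
#'
#' Bins tree genes by expression quantile (specificity and abundance in the
#' tree's cell type) and reports the median tree size (number of enhancer
#' node instances) per bin. Over the skipping pairs, collapsed to one record
#' per (enhancer, looped gene, skipped gene), runs paired t tests of looped
#' versus skipped gene ESS and abundance.
#'
#' @param tr an `enhancer_trees` object
#' @param expression expression table
#' @param skip skipping table from [skipping_analysis()]
#' @param n_quantiles number of expression bins (default 4)
#' @return list with `bins` (per-quantile medians) and `paired` (t statistic,
#'   df, p, n_pairs for ESS and abundance; `NA` + flag with < 2 pairs)
#' @export
expression_vs_treesize <- function(tr, expression, skip, n_quantiles = 4L) {
  ct <- tr$cell_type
  ess <- setNames(expression[[paste0("ess_", ct)]], expression$gene_id)
  ab <- setNames(expression[[paste0("abund_", ct)]], expression$gene_id)
  size <- setNames(tr$trees$n_enhancers, tr$trees$gene_id)
  genes <- intersect(names(size), names(ess))
  bin_medians <- function(v) {
    q <- cut(rank(v[genes], ties.method = "first"), breaks = n_quantiles, labels = FALSE)
    data.frame(quantile = sort(unique(q)),
               n = as.integer(table(q)),
               median_tree_size = as.numeric(tapply(size[genes], q, median)))
  }
  paired <- function(v) {
    sk <- skip[!is.na(skip$skipped) & skip$skipped, , drop = FALSE]
    sk <- sk[!duplicated(sk[, c("e1", "looped_gene", "nearest_gene")]), , drop = FALSE]
    x <- unname(v[sk$looped_gene]); y <- unname(v[sk$nearest_gene])
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2)
      return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                  n_pairs = sum(ok), flag = "fewer than 2 pairs"))
    if (all(x[ok] == y[ok]))
      return(list(t = 0, df = sum(ok) - 1, p_value = 1, n_pairs = sum(ok), flag = NULL))
    ht <- t.test(x[ok], y[ok], paired = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n_pairs = sum(ok), flag = NULL)
  }
  list(bins = list(ess = bin_medians(ess), abundance = bin_medians(ab)),
       paired = list(ess = paired(ess), abundance = paired(ab)))
}
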