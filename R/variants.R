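#' Intersect association SNPs with tree nodes
#'
#' SNPs passing the association threshold are intersected with the anchor
#' intervals of tree nodes; every containment is expanded to every tree
#' containing the node, giving one link per (SNP, node, tree) with the
#' tree's promoter gene. SNPs on chromosomes absent from the node set are
#' skipped with a tally.
#'
#' @param snps SNP table from [read_snps()] (0-based positions)
#' @param trees_by_ct named list of `enhancer_trees`
#' @param anchors classified consensus anchors
#' @param gwas_threshold association p-value cutoff (default 1e-4; SNPs with
#'   `gwas_p < threshold` qualify)
#' @return data.frame of links (`link_id`, `snp_id`, `node_name`, `tree_id`,
#'   `gene_id`, `cell_type`, `gwas_p`); attribute `n_no_chrom` counts
#'   skipped SNPs
#' @export
intersect_snps <- function(snps, trees_by_ct, anchors, gwas_threshold = 1e-4) {
  sig <- snps[snps$gwas_p < gwas_threshold, , drop = FALSE]
  node_chroms <- unique(anchors$chrom)
  off <- !sig$chrom %in% node_chroms
  n_no_chrom <- sum(off)
  if (n_no_chrom)
    message(sprintf("intersect_snps: %d SNP(s) on chromosomes without nodes skipped", n_no_chrom))
  sig <- sig[!off, , drop = FALSE]
  out <- list()
  if (nrow(sig)) {
    snp_gr <- GenomicRanges::GRanges(sig$chrom, IRanges::IRanges(sig$pos + 1L, sig$pos + 1L))
    anc_gr <- as_granges(anchors)
    hits <- GenomicRanges::findOverlaps(snp_gr, anc_gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (ct in names(trees_by_ct)) {
      tr <- trees_by_ct[[ct]]
      gene <- setNames(tr$trees$gene_id, tr$trees$tree_id)
      for (h in seq_along(qh)) {
        nn <- anchors$node_name[sh[h]]
        tids <- tr$nodes$tree_id[tr$nodes$node_name == nn]
        if (!length(tids)) next
        out[[length(out) + 1L]] <- data.frame(
          snp_id = sig$snp_id[qh[h]], node_name = nn, tree_id = tids,
          gene_id = unname(gene[tids]), cell_type = ct,
          gwas_p = sig$gwas_p[qh[h]], stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(), node_name = character(),
               tree_id = character(), gene_id = character(),
               cell_type = character(), gwas_p = numeric())
  links$link_id <- paste(links$snp_id, links$node_name, links$tree_id, sep = "|")
  rownames(links) <- NULL
  links <- links[, c("link_id", "snp_id", "node_name", "tree_id", "gene_id",
                     "cell_type", "gwas_p")]
  attr(links, "n_no_chrom") <- n_no_chrom
  links
}

#' Stratify effect sizes by SNP overlap
#'
#' Restricts to trees containing at least one SNP-overlapping node, splits
#' their enhancers into SNP-overlapping (group A) and not-overlapping
#' (group B), and compares the two effect-size distributions with a
#' two-sample, two-sided Kolmogorov-Smirnov test. With `dedupe = TRUE`
#' (default) each enhancer node contributes one value per cell type (its
#' maximum effect size across trees); the non-deduplicated test is also
#' returned.
#'
#' @param links SNP links from [intersect_snps()]
#' @param effect_sizes effect-size table from [epic_effect_sizes()]
#' @param cell_type cell type to stratify
#' @param dedupe collapse repeated nodes before the primary test
#' @return list with `overlapping`, `other` (the two value vectors after
#'   deduplication), `D`, `p_value`, the `by_instance` secondary test, and
#'   the two empirical CDFs; flagged with `p_value = NA` when a group is
#'   empty
#' @export
stratify_effect_sizes <- function(links, effect_sizes, cell_type, dedupe = TRUE) {
  lk <- links[links$cell_type == cell_type, , drop = FALSE]
  es <- effect_sizes[effect_sizes$cell_type == cell_type &
                       !is.na(effect_sizes$effect_size), , drop = FALSE]
  snp_trees <- unique(lk$tree_id)
  es <- es[es$tree_id %in% snp_trees, , drop = FALSE]
  snp_nodes <- unique(lk$node_name)
  es$overlapping <- es$node_name %in% snp_nodes
  if (!any(es$overlapping) || all(es$overlapping)) {
    return(list(overlapping = es$effect_size[es$overlapping],
                other = es$effect_size[!es$overlapping],
                D = NA_real_, p_value = NA_real_, by_instance = NULL,
                flag = "a stratum is empty"))
  }
  run_ks <- function(a, b) {
    ht <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
    list(D = unname(ht$statistic), p_value = ht$p.value)
  }
  inst <- run_ks(es$effect_size[es$overlapping], es$effect_size[!es$overlapping])
  if (dedupe) {
    dd <- tapply(es$effect_size, list(es$node_name, es$overlapping), max)
    a <- stats::na.omit(dd[, "TRUE"]); b <- stats::na.omit(dd[, "FALSE"])
  } else {
    a <- es$effect_size[es$overlapping]; b <- es$effect_size[!es$overlapping]
  }
  main <- run_ks(a, b)
  list(overlapping = as.numeric(a), other = as.numeric(b),
       D = main$D, p_value = main$p_value,
       by_instance = inst,
       ecdf_overlapping = stats::ecdf(a), ecdf_other = stats::ecdf(b),
       flag = NULL)
}

#' Export annotation-overlap files for external enrichment tools
#'
#' For each cell type, writes a two-column text file (`pos`, then a 0/1
#' annotation flag) recording whether each query position falls inside a
#' tree-node interval of that cell type. Unsorted positions are sorted, with
#' a note.
#'
#' @param positions data.frame with `chrom` and `pos` (0-based) query
#'   positions (typically the SNP panel)
#' @param trees_by_ct named list of `enhancer_trees`
#' @param anchors classified consensus anchors
#' @param dir output directory
#' @return named character vector of written file paths
#' @export
export_enrichment_annotations <- function(positions, trees_by_ct, anchors, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- order(positions$chrom, positions$pos)
  if (!identical(ord, seq_len(nrow(positions)))) {
    message("export_enrichment_annotations: positions were unsorted; sorted")
    positions <- positions[ord, , drop = FALSE]
  }
  pos_gr <- GenomicRanges::GRanges(positions$chrom,
    IRanges::IRanges(positions$pos + 1L, positions$pos + 1L))
  paths <- character(0)
  for (ct in names(trees_by_ct)) {
    nn <- unique(trees_by_ct[[ct]]$nodes$node_name)
    anc <- anchors[anchors$node_name %in% nn, , drop = FALSE]
    flag <- integer(nrow(positions))
    if (nrow(anc)) {
      hits <- GenomicRanges::findOverlaps(pos_gr, as_granges(anc))
      flag[unique(S4Vectors::queryHits(hits))] <- 1L
    }
    path <- file.path(dir, paste0("annotation_", ct, ".txt"))
    writeLines(paste(positions$chrom, positions$pos, flag), path)
    paths[ct] <- path
  }
  paths
}
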