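#' Intersect two loop sets by shared anchors
#'
#' A loop from `set_a` is retained when some loop in `set_b` overlaps it
#' anchor-wise: anchor1 with anchor1 and anchor2 with anchor2, or in the
#' swapped pairing. Overlap is any-overlap of the anchor intervals. Retained
#' loops carry `set_a`'s PET counts. This mirrors the pair-to-pair overlap
#' used to intersect calls from two independent loop callers.
#'
#' @param set_a,set_b loop tables as returned by [read_loops()]
#' @return the retained subset of `set_a`
#' @export
intersect_loop_sets <- function(set_a, set_b) {
  if (!nrow(set_a) || !nrow(set_b)) return(set_a[0, , drop = FALSE])
  gr <- function(df, which) {
    s <- df[[paste0("start", which)]]; e <- df[[paste0("end", which)]]
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(s + 1L, e))
  }
  a1 <- gr(set_a, 1); a2 <- gr(set_a, 2)
  b1 <- gr(set_b, 1); b2 <- gr(set_b, 2)
  pair_hits <- function(x1, y1, x2, y2) {
    h1 <- GenomicRanges::findOverlaps(x1, y1)
    h2 <- GenomicRanges::findOverlaps(x2, y2)
    k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
    k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
    unique(as.integer(sub(" .*", "", intersect(k1, k2))))
  }
  keep <- union(pair_hits(a1, b1, a2, b2), pair_hits(a1, b2, a2, b1))
  out <- set_a[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build consensus anchors from pooled loop anchors
#'
#' Anchors from all cell types are merged genome-wide (any overlap, bookended
#' intervals included). Each merged anchor's midpoint is
#' `floor((start + end) / 2)`.
#'
#' @param anchors data.frame with `chrom`, `start`, `end` of every anchor
#'   occurrence (both sides of every loop, all cell types)
#' @return data.frame of disjoint consensus anchors with `anchor_id` and
#'   `midpoint`
#' @export
build_consensus_anchors <- function(anchors) {
  m <- merge_intervals(anchors, gap = 0L)
  m$midpoint <- as.integer(floor((m$start + m$end) / 2))
  m$anchor_id <- seq_len(nrow(m))
  m
}

# Pull both anchors of a loop table into one interval data.frame.
loop_anchors <- function(loops) {
  rbind(
    data.frame(chrom = loops$chrom, start = loops$start1, end = loops$end1),
    data.frame(chrom = loops$chrom, start = loops$start2, end = loops$end2))
}

#' Classify consensus anchors as promoter or enhancer nodes and name them
#'
#' An anchor whose midpoint falls inside a gene's promoter window becomes a
#' promoter (P) node carrying that gene; all others are enhancer (E) nodes.
#' When the midpoint lies in two genes' windows the gene with the nearest TSS
#' wins (ties toward the lexicographically smaller `gene_id`); collisions are
#' reported with a message. Node names are
#' `<chromosome>.<rank><P|E>` where rank is the 1-based position of the
#' anchor midpoint within its chromosome, over all anchors.
#'
#' @param anchors consensus anchors from [build_consensus_anchors()]
#' @param genes gene table (see [read_genes()])
#' @param up,down promoter window extents in bp (see [promoter_windows()])
#' @param strand_aware mirror windows on minus-strand genes
#' @return `anchors` with `node_kind`, `node_name`, `gene_id` columns
#' @export
classify_anchors <- function(anchors, genes, up = 2000L, down = 3000L,
                             strand_aware = TRUE) {
  win <- promoter_windows(genes, up = up, down = down, strand_aware = strand_aware)
  win <- win[win$end > win$start, , drop = FALSE]
  mid_gr <- GenomicRanges::GRanges(anchors$chrom,
    IRanges::IRanges(anchors$midpoint + 1L, anchors$midpoint + 1L))
  win_gr <- as_granges(win)
  hits <- GenomicRanges::findOverlaps(mid_gr, win_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  anchors$node_kind <- "E"
  anchors$gene_id <- NA_character_
  if (length(qh)) {
    d <- abs(win$tss[sh] - anchors$midpoint[qh])
    ord <- order(qh, d, win$gene_id[sh])
    qh <- qh[ord]; sh <- sh[ord]
    n_collide <- sum(duplicated(qh))
    if (n_collide)
      message(sprintf("classify_anchors: %d anchor(s) inside multiple promoter windows; nearest TSS assigned", n_collide))
    first <- !duplicated(qh)
    anchors$node_kind[qh[first]] <- "P"
    anchors$gene_id[qh[first]] <- win$gene_id[sh[first]]
  }
  rank <- stats::ave(anchors$midpoint, anchors$chrom,
                     FUN = function(x) rank(x, ties.method = "first"))
  anchors$node_name <- paste0(chrom_label(anchors$chrom), ".",
                              as.integer(rank), anchors$node_kind)
  anchors
}

#' Build the consensus loop table
#'
#' Re-anchors every per-cell-type loop to the consensus anchors (each input
#' anchor maps to exactly one consensus anchor because consensus anchors are
#' the merged union), aggregates PET counts per cell type for each unique
#' anchor pair, and removes loops shorter than `min_length` (midpoint
#' distance), a known artifact of anchor merging.
#'
#' @param loop_sets named list (by cell type) of loop tables from
#'   [read_loops()]
#' @param anchors classified consensus anchors from [classify_anchors()]
#' @param min_length minimum loop length in bp (default 5000)
#' @return data.frame with anchor ids (`a1 < a2`), node names `n1`, `n2`,
#'   `chrom`, `length`, and one `pet_<cell type>` column per cell type.
#'   Attributes `n_short_removed` and `n_self_removed` tally the filters.
#' @export
build_consensus_loops <- function(loop_sets, anchors, min_length = 5000L) {
  cell_types <- names(loop_sets)
  if (is.null(cell_types) || any(!nzchar(cell_types)))
    stopf("loop_sets must be a named list keyed by cell type")
  anchor_gr <- as_granges(anchors)
  map_anchor <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    hits <- GenomicRanges::findOverlaps(gr, anchor_gr)
    if (length(hits) != length(gr) || anyDuplicated(S4Vectors::queryHits(hits)))
      stopf("an input anchor maps to %s consensus anchors; anchors must cover inputs disjointly",
            if (length(hits) > length(gr)) "multiple" else "zero")
    anchors$anchor_id[S4Vectors::subjectHits(hits)]
  }
  rows <- list()
  for (ct in cell_types) {
    lp <- loop_sets[[ct]]
    if (!nrow(lp)) next
    id1 <- map_anchor(lp$chrom, lp$start1, lp$end1)
    id2 <- map_anchor(lp$chrom, lp$start2, lp$end2)
    rows[[ct]] <- data.frame(a1 = pmin(id1, id2), a2 = pmax(id1, id2),
                             pet = lp$pet, cell_type = ct,
                             stringsAsFactors = FALSE)
  }
  all_rows <- do.call(rbind, rows)
  n_self <- sum(all_rows$a1 == all_rows$a2)
  all_rows <- all_rows[all_rows$a1 != all_rows$a2, , drop = FALSE]
  key <- paste(all_rows$a1, all_rows$a2)
  uk <- !duplicated(key)
  out <- all_rows[uk, c("a1", "a2")]
  for (ct in cell_types) {
    sums <- tapply(all_rows$pet * (all_rows$cell_type == ct), key, sum)
    out[[paste0("pet_", ct)]] <- as.numeric(sums[key[uk]])
  }
  mid <- setNames(anchors$midpoint, anchors$anchor_id)
  nm <- setNames(anchors$node_name, anchors$anchor_id)
  ch <- setNames(anchors$chrom, anchors$anchor_id)
  out$n1 <- nm[as.character(out$a1)]
  out$n2 <- nm[as.character(out$a2)]
  out$chrom <- unname(ch[as.character(out$a1)])
  out$length <- abs(mid[as.character(out$a1)] - mid[as.character(out$a2)])
  n_short <- sum(out$length < min_length)
  out <- out[out$length >= min_length, , drop = FALSE]
  out <- out[order(out$a1, out$a2),
             c("a1", "a2", "n1", "n2", "chrom", "length", ct_cols("pet", cell_types))]
  rownames(out) <- NULL
  attr(out, "n_short_removed") <- n_short
  attr(out, "n_self_removed") <- n_self
  attr(out, "cell_types") <- cell_types
  out
}
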