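#' Merge genomic intervals ("any overlap")
#'
#' Union of overlapping intervals, per chromosome. With `gap = 0`, bookended
#' intervals (`[a,b)`, `[b,c)`) are merged, matching the default any-overlap
#' behaviour of standard interval tools. Larger `gap` also merges intervals
#' separated by at most `gap` bases.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open)
#' @param gap maximum separation (bp) at which two intervals are still merged
#' @return data.frame of merged intervals, sorted by chromosome then start
#' @export
merge_intervals <- function(intervals, gap = 0L) {
  check_intervals(intervals)
  if (gap < 0) stopf("gap must be >= 0")
  gr <- GenomicRanges::reduce(as_granges(intervals), min.gapwidth = gap + 1L)
  out <- granges_to_df(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand-aware promoter window around a TSS
#'
#' The window spans `up` bases upstream and `down` bases downstream of the
#' TSS, relative to transcription direction, clamped at position 0. For a
#' plus-strand gene with TSS t this is `[t - up, t + down)`.
#'
#' @param genes data.frame with `tss` and `strand` columns (one row per gene);
#'   additional columns are carried through.
#' @param up upstream extent in bp (default 2000)
#' @param down downstream extent in bp (default 3000)
#' @param strand_aware mirror the window for minus-strand genes (default TRUE)
#' @return `genes` with `start` and `end` columns added (0-based half-open)
#' @export
promoter_windows <- function(genes, up = 2000L, down = 3000L, strand_aware = TRUE) {
  minus <- strand_aware & genes$strand == "-"
  start <- ifelse(minus, genes$tss - down, genes$tss - up)
  end <- ifelse(minus, genes$tss + up, genes$tss + down)
  genes$start <- pmax(0L, as.integer(start))
  genes$end <- as.integer(end)
  genes
}

#' Nearest TSS within a distance band
#'
#' Finds, for each query point, the gene on the same chromosome whose TSS
#' minimises `|tss - point|` subject to `min_d <= |tss - point| <= max_d`.
#' Equidistant ties are broken toward the lexicographically smaller
#' `gene_id`, making the result deterministic.
#'
#' @param points integer vector of positions (0-based)
#' @param chroms chromosome of each point (recycled if length 1)
#' @param genes gene table (`gene_id`, `chrom`, `tss`, ...)
#' @param min_d minimum distance in bp (default 5000)
#' @param max_d maximum distance in bp (default 1e6)
#' @return character vector of gene ids (NA where no gene qualifies)
#' @export
nearest_tss <- function(points, chroms, genes, min_d = 5000L, max_d = 1e6L) {
  if (min_d >= max_d) stopf("min_d must be < max_d")
  if (length(chroms) == 1L) chroms <- rep(chroms, length(points))
  # order candidate genes once: by chrom, then tss, then gene_id
  g <- genes[order(genes$chrom, genes$tss, genes$gene_id), , drop = FALSE]
  out <- rep(NA_character_, length(points))
  for (ch in unique(chroms)) {
    gi <- g[g$chrom == ch, , drop = FALSE]
    idx <- which(chroms == ch)
    if (!nrow(gi)) next
    for (i in idx) {
      d <- abs(gi$tss - points[i])
      ok <- d >= min_d & d <= max_d
      if (!any(ok)) next
      dmin <- min(d[ok])
      cand <- gi$gene_id[ok & d == dmin]
      out[i] <- min(cand)
    }
  }
  out
}
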