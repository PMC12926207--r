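#' @useDynLib epictrees, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats chisq.test kruskal.test ks.test median quantile rlnorm
#'   rnbinom runif sd t.test wilcox.test setNames
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a vector of sub-seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Strip a leading "chr" prefix for node-name construction ("chr22" -> "22").
chrom_label <- function(chrom) sub("^chr", "", chrom)

#' Column names holding a per-cell-type quantity
#' @param prefix column prefix, e.g. "pet" or "atac"
#' @param cell_types character vector of cell-type labels
#' @return character vector like `c("pet_alpha", "pet_beta", ...)`
#' @export
ct_cols <- function(prefix, cell_types) paste0(prefix, "_", cell_types)

# Validate a 0-based half-open interval data.frame.
check_intervals <- function(df, what = "interval") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stopf("%s table must have columns %s", what, paste(need, collapse = ", "))
  if (any(df$start < 0)) stopf("%s with negative start", what)
  if (any(df$end <= df$start)) stopf("%s with end <= start", what)
  if (any(!nzchar(df$chrom))) stopf("%s with empty chromosome", what)
  invisible(df)
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# GRanges -> data.frame (0-based half-open)
granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
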