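#' Read a BEDPE-like chromatin loop table
#'
#' Parses loop calls with two anchors per row plus a paired-end-tag (PET)
#' count. Coordinates are 0-based half-open (BED convention). Rows whose two
#' anchors lie on different chromosomes (trans contacts) are handled according
#' to `trans`: dropped with a tally, or raised as an error.
#'
#' @param path path to a tab-separated BEDPE file; columns
#'   `chrom1 start1 end1 chrom2 start2 end2 [name] [pet ...]`. A header line
#'   starting with `#` or `chrom1` is allowed.
#' @param cell_type label attached to the returned records.
#' @param pet_col column index (or name, when the file has a header) holding
#'   the PET count. Default 8, the BEDPE "score" slot.
#' @param trans policy for inter-chromosomal rows: `"drop"` (default) or
#'   `"error"`.
#' @return data.frame with columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `pet`, `cell_type`; attribute `n_trans_dropped` carries the
#'   number of discarded trans rows.
#' @export
read_loops <- function(path, cell_type, pet_col = 8L, trans = c("drop", "error")) {
  trans <- match.arg(trans)
  if (!file.exists(path)) stopf("loop file not found: %s", path)
  lines <- readLines(path)
  header <- grep("^(#\\s*)?chrom1\\t", lines, value = TRUE)
  if (is.character(pet_col) && !is.numeric(pet_col)) {
    if (!length(header)) stopf("pet_col '%s' given by name but the file has no header", pet_col)
    cols <- strsplit(sub("^#\\s*", "", header[1]), "\t", fixed = TRUE)[[1]]
    idx <- match(pet_col, cols)
    if (is.na(idx)) stopf("no column named '%s' in the loop file header", pet_col)
    pet_col <- idx
  }
  keep <- !grepl("^(#|chrom1\\t)", lines) & nzchar(lines)
  line_no <- which(keep)
  if (!length(line_no)) {
    out <- data.frame(chrom = character(), start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(), pet = integer(),
                      cell_type = character())
    attr(out, "n_trans_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stopf("malformed loop row at line %d: fewer than 6 columns", line_no[which(nf < 6)[1]])
  if (is.numeric(pet_col) && any(nf < pet_col))
    stopf("malformed loop row at line %d: no PET column %d",
          line_no[which(nf < pet_col)[1]], pet_col)
  get_col <- function(i) vapply(fields, `[[`, "", i)
  num_col <- function(i, what) {
    v <- suppressWarnings(as.numeric(get_col(i)))
    if (anyNA(v))
      stopf("malformed loop row at line %d: non-numeric %s", line_no[which(is.na(v))[1]], what)
    v
  }
  df <- data.frame(
    chrom1 = get_col(1), start1 = num_col(2, "start1"), end1 = num_col(3, "end1"),
    chrom2 = get_col(4), start2 = num_col(5, "start2"), end2 = num_col(6, "end2"),
    pet = num_col(pet_col, "PET count"),
    stringsAsFactors = FALSE)
  bad <- which(df$end1 <= df$start1 | df$end2 <= df$start2)
  if (length(bad))
    stopf("invalid anchor at line %d: end <= start", line_no[bad[1]])
  bad <- which(df$start1 < 0 | df$start2 < 0)
  if (length(bad))
    stopf("invalid anchor at line %d: negative start", line_no[bad[1]])
  bad <- which(df$pet < 0)
  if (length(bad))
    stopf("negative PET count at line %d", line_no[bad[1]])
  is_trans <- df$chrom1 != df$chrom2
  if (any(is_trans) && trans == "error")
    stopf("inter-chromosomal loop at line %d", line_no[which(is_trans)[1]])
  n_trans <- sum(is_trans)
  if (n_trans) message(sprintf("read_loops: dropped %d inter-chromosomal row(s)", n_trans))
  df <- df[!is_trans, , drop = FALSE]
  out <- data.frame(chrom = df$chrom1,
                    start1 = as.integer(df$start1), end1 = as.integer(df$end1),
                    start2 = as.integer(df$start2), end2 = as.integer(df$end2),
                    pet = df$pet, cell_type = rep(cell_type, nrow(df)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_trans_dropped") <- n_trans
  out
}

#' Read a simplified gene annotation
#'
#' Six-column TSV: `gene_id`, `symbol`, `chrom`, `strand` (+/-), `tss`
#' (0-based), `biotype` (coding/noncoding). A header is required.
#' @param path file path
#' @return validated data.frame
#' @export
read_genes <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "chrom", "strand", "tss", "biotype")
  if (!all(need %in% names(g)))
    stopf("gene table must have columns %s", paste(need, collapse = ", "))
  validate_genes(g)
}

validate_genes <- function(g) {
  if (any(!g$strand %in% c("+", "-"))) stopf("gene strand must be '+' or '-'")
  if (any(g$tss < 0)) stopf("gene TSS must be >= 0")
  if (any(!g$biotype %in% c("coding", "noncoding")))
    stopf("gene biotype must be 'coding' or 'noncoding'")
  if (anyDuplicated(g$gene_id)) stopf("duplicated gene_id in gene table")
  g
}

#' Read a gene-by-cell-type expression table
#'
#' TSV with `gene_id` plus, per cell type, an expression specificity score
#' column `ess_<cell type>` in `[0, 1]` and a non-negative transcript
#' abundance column `abund_<cell type>`.
#' @param path file path
#' @param cell_types cell-type labels expected in the header
#' @return validated data.frame
#' @export
read_expression <- function(path, cell_types) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_expression(x, cell_types)
}

validate_expression <- function(x, cell_types) {
  need <- c("gene_id", ct_cols("ess", cell_types), ct_cols("abund", cell_types))
  if (!all(need %in% names(x)))
    stopf("expression table must have columns %s", paste(need, collapse = ", "))
  ess <- as.matrix(x[, ct_cols("ess", cell_types), drop = FALSE])
  if (any(ess < 0 | ess > 1)) stopf("ESS values must lie in [0, 1]")
  ab <- as.matrix(x[, ct_cols("abund", cell_types), drop = FALSE])
  if (any(ab < 0)) stopf("abundance values must be >= 0")
  x
}

#' Read an accessibility peak table
#'
#' BED-like TSV with `chrom`, `start`, `end` plus one tag-count/density
#' column per cell type (`atac_<cell type>`).
#' @param path file path
#' @param cell_types cell-type labels expected in the header
#' @return validated data.frame
#' @export
read_peaks <- function(path, cell_types) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  check_intervals(x, "peak")
  need <- ct_cols("atac", cell_types)
  if (!all(need %in% names(x)))
    stopf("peak table must have columns %s", paste(need, collapse = ", "))
  if (any(as.matrix(x[, need]) < 0)) stopf("negative ATAC tag value in peak table")
  x
}

#' Read a SNP association table
#'
#' TSV with columns `chrom`, `pos`, `snp_id`, `gwas_p`. Positions are read as
#' 1-based (VCF convention) and converted to the package's 0-based internal
#' convention.
#' @param path file path
#' @return data.frame with 0-based `pos`
#' @export
read_snps <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "snp_id", "gwas_p")
  if (!all(need %in% names(x)))
    stopf("SNP table must have columns %s", paste(need, collapse = ", "))
  if (any(x$gwas_p <= 0 | x$gwas_p > 1)) stopf("gwas_p must lie in (0, 1]")
  if (any(x$pos < 1)) stopf("SNP positions must be 1-based and >= 1")
  x$pos <- as.integer(x$pos) - 1L
  x
}

#' Write a table as TSV
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
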