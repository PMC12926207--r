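#' Specification for the synthetic pancreas-like fixture
#'
#' Defines a seeded toy genome with planted structure: per cell type,
#' `n_focal` genes are cell-type specific (ESS above 0.7 in that cell type)
#' and carry enhancer trees whose direct enhancers have amplified
#' accessibility and interaction frequency (`signal`), with one designated
#' "critical" enhancer per focal tree further amplified
#' (`critical_enhancer_boost`). A shared pool of `n_nonfocal` genes has low
#' ESS everywhere and background-level trees. Bystander genes planted
#' between enhancers and their looped promoters create nearest-promoter
#' skipping; promoter-promoter loops are enriched around focal genes;
#' significant SNPs are preferentially placed in critical enhancer anchors.
#'
#' PET counts are negative binomial (overdispersed counts), ATAC tag
#' densities log-normal. All output is a deterministic function of `seed`.
#'
#' @param seed master seed
#' @param cell_types cell-type labels (default the four used for
#'   classification)
#' @param n_focal focal (cell-type-specific) genes per cell type
#' @param n_nonfocal size of the shared non-specific gene pool
#' @param signal ATAC/PET multiplier for direct enhancers of focal trees
#' @param critical_enhancer_boost extra multiplier for the designated
#'   critical enhancer of each focal tree
#' @param pet_mu,pet_size negative-binomial PET parameters
#' @param atac_meanlog,atac_sdlog log-normal ATAC parameters
#' @param p_e2 probability that an E1 enhancer carries an E2 child
#' @param p_extra_ee probability of an extra same-level E1-E1 loop (prune
#'   fodder)
#' @param p_background_tree probability a focal gene also has a background
#'   tree in another cell type
#' @param p_ct_tree_nonfocal probability a pool gene has a tree in a given
#'   cell type
#' @param p_bystander probability an E1 gets a planted nearer bystander gene
#' @param p_outside fraction of bystanders planted on the far side of the
#'   enhancer (OutsideLoop geometry)
#' @param pp_partners_specific,pp_partners_other promoter-promoter loop
#'   partners for focal / non-focal genes
#' @param p_pp_other probability a non-focal gene links to its partner
#' @param p_shared_enhancer probability adjacent trees share an enhancer
#' @param snp_in_critical,snp_in_other per-focal-tree probabilities of a
#'   significant SNP in the critical / a non-critical enhancer anchor
#' @param n_background_snps non-significant background SNPs
#' @param block_bp genomic block reserved per gene
#' @param genes_per_chrom gene blocks per chromosome
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(seed = 1L,
                         cell_types = c("alpha", "beta", "acinar", "duct"),
                         n_focal = 200L, n_nonfocal = 400L,
                         signal = 5, critical_enhancer_boost = 6,
                         pet_mu = 8, pet_size = 4,
                         atac_meanlog = log(20), atac_sdlog = 0.5,
                         p_e2 = 0.4, p_extra_ee = 0.15,
                         p_background_tree = 0.5, p_ct_tree_nonfocal = 0.75,
                         p_bystander = 0.85, p_outside = 0.3,
                         pp_partners_specific = 6L, pp_partners_other = 1L,
                         p_pp_other = 0.6, p_shared_enhancer = 0.25,
                         snp_in_critical = 0.35, snp_in_other = 0.1,
                         n_background_snps = 500L,
                         block_bp = 1.2e6, genes_per_chrom = 100L) {
  spec <- as.list(environment())
  if (spec$signal < 1 || spec$critical_enhancer_boost < 1)
    stopf("signal multipliers must be >= 1")
  if (spec$n_focal < 1 || spec$n_nonfocal < 1 || spec$genes_per_chrom < 1)
    stopf("infeasible fixture: gene counts must be positive")
  if (spec$block_bp < 2e5) stopf("block_bp too small to place anchors")
  class(spec) <- "fixture_spec"
  spec
}

#' Generate the synthetic input bundle
#'
#' Produces every table the pipeline consumes — gene annotation, per-cell-
#' type loop tables, accessibility peaks, expression (ESS + abundance), and
#' SNPs — plus a ground-truth manifest listing planted class labels,
#' critical enhancers, and SNP placements. Running twice with the same spec
#' yields identical bundles.
#'
#' @param spec a [fixture_spec()]
#' @return list with `spec`, `cell_types`, `genes`, `expression`, `peaks`,
#'   `loops` (named list of per-cell-type loop tables), `snps`, `manifest`
#' @export
simulate_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  cts <- spec$cell_types; K <- length(cts)
  n_tg <- K * spec$n_focal + spec$n_nonfocal
  focal_ct <- sample(c(rep(cts, each = spec$n_focal),
                       rep(NA_character_, spec$n_nonfocal)))
  gid <- sprintf("g%05d", seq_len(n_tg))
  chrom <- paste0("chr", ceiling(seq_len(n_tg) / spec$genes_per_chrom))
  b0 <- ((seq_len(n_tg) - 1L) %% spec$genes_per_chrom) * spec$block_bp
  tss <- b0 + 300000L
  grid_step <- 8000L

  anchors <- list()     # one row per planted anchor
  loops <- setNames(vector("list", K), cts)
  bystanders <- list()
  critical <- list()
  by_ct_genes <- setNames(vector("list", K), cts)   # genes with a tree per ct

  nb_pet <- function(n) 2 + rnbinom(n, mu = spec$pet_mu, size = spec$pet_size)

  for (i in seq_len(n_tg)) {
    is_focal <- !is.na(focal_ct[i])
    # promoter anchor around the TSS
    p_key <- paste0(gid[i], ".P")
    anchors[[p_key]] <- data.frame(key = p_key, gene_id = gid[i], role = "P",
      chrom = chrom[i], mid = tss[i], start = tss[i] - 1000L, end = tss[i] + 1500L,
      stringsAsFactors = FALSE)
    # enhancer slots on an 8 kb grid, 20-550 kb from the TSS
    slots <- b0[i] + 20000L + grid_step * (0:((550000L + 280000L) %/% grid_step))
    slots <- slots[abs(slots - tss[i]) >= 20000L & abs(slots - tss[i]) <= 550000L]
    n_e1 <- if (is_focal) sample(3:6, 1) else sample(2:4, 1)
    has_e2 <- runif(n_e1) < spec$p_e2
    picked <- sample(slots, n_e1 + sum(has_e2))
    e1_mid <- picked[seq_len(n_e1)]
    e2_mid <- picked[n_e1 + seq_len(sum(has_e2))]
    e2_parent <- which(has_e2)
    mk_anchor <- function(key, mid, role) {
      w <- sample(1500:4000, length(mid), replace = TRUE)
      data.frame(key = key, gene_id = gid[i], role = role, chrom = chrom[i],
                 mid = mid, start = mid - w %/% 2L, end = mid + (w - w %/% 2L),
                 stringsAsFactors = FALSE)
    }
    e1_keys <- paste0(gid[i], ".E1.", seq_len(n_e1))
    e2_keys <- if (length(e2_mid)) paste0(gid[i], ".E2.", seq_along(e2_mid)) else character()
    for (r in seq_len(n_e1)) anchors[[e1_keys[r]]] <- mk_anchor(e1_keys[r], e1_mid[r], "E1")
    for (r in seq_along(e2_mid)) anchors[[e2_keys[r]]] <- mk_anchor(e2_keys[r], e2_mid[r], "E2")
    if (is_focal) {
      critical[[gid[i]]] <- data.frame(gene_id = gid[i], cell_type = focal_ct[i],
        key = e1_keys[1], chrom = chrom[i],
        start = anchors[[e1_keys[1]]]$start, end = anchors[[e1_keys[1]]]$end,
        midpoint = e1_mid[1], stringsAsFactors = FALSE)
    }
    # which cell types carry a tree for this gene
    has_tree <- if (is_focal) {
      (cts == focal_ct[i]) | (runif(K) < spec$p_background_tree)
    } else {
      ht <- runif(K) < spec$p_ct_tree_nonfocal
      if (!any(ht)) ht[sample(K, 1)] <- TRUE
      ht
    }
    for (ci in which(has_tree)) {
      ct <- cts[ci]
      by_ct_genes[[ct]] <- c(by_ct_genes[[ct]], gid[i])
      focal_here <- is_focal && ct == focal_ct[i]
      use <- if (focal_here) seq_len(n_e1) else
        sort(sample(n_e1, min(n_e1, sample(2:3, 1))))
      rows <- list()
      pet <- nb_pet(length(use))
      if (focal_here) {
        pet <- round(pet * spec$signal)
        pet[use == 1] <- round(pet[use == 1] * spec$critical_enhancer_boost)
      }
      rows$pe <- data.frame(k1 = p_key, k2 = e1_keys[use], pet = pet)
      inc_e2 <- e2_parent %in% use & (focal_here | runif(length(e2_parent)) < 0.5)
      if (any(inc_e2)) {
        rows$ee2 <- data.frame(k1 = e1_keys[e2_parent[inc_e2]],
                               k2 = e2_keys[inc_e2], pet = nb_pet(sum(inc_e2)))
      }
      if (length(use) > 1) {
        pair <- cbind(use[-length(use)], use[-1])
        ex <- runif(nrow(pair)) < spec$p_extra_ee
        if (any(ex)) {
          rows$ee1 <- data.frame(k1 = e1_keys[pair[ex, 1]],
                                 k2 = e1_keys[pair[ex, 2]], pet = nb_pet(sum(ex)))
        }
      }
      loops[[ct]][[gid[i]]] <- do.call(rbind, rows)
    }
    # bystander genes planted between E1 enhancers and the promoter
    for (r in seq_len(n_e1)) {
      if (runif(1) >= spec$p_bystander) next
      d <- e1_mid[r] - tss[i]
      j_max <- min((abs(d) - 4001L) %/% grid_step, 7L)
      if (j_max < 1) next
      delta <- grid_step * sample(j_max, 1) + 4000L
      toward <- -sign(d)   # direction from the enhancer toward the TSS
      side <- if (runif(1) < spec$p_outside) -toward else toward
      pos <- e1_mid[r] + side * delta
      if (pos < b0[i] + 5000L || pos > b0[i] + spec$block_bp - 5000L) next
      bystanders[[length(bystanders) + 1L]] <- data.frame(
        host_gene = gid[i], e1_key = e1_keys[r], chrom = chrom[i], tss = pos,
        planted_side = if (side == toward) "inside" else "outside",
        stringsAsFactors = FALSE)
    }
  }

  anchor_df <- do.call(rbind, anchors)
  rownames(anchor_df) <- NULL

  # promoter-promoter loops: focal genes link to several downstream
  # promoters on their chromosome; non-focal genes to at most one
  for (ci in seq_len(K)) {
    ct <- cts[ci]
    tg <- by_ct_genes[[ct]]
    idx <- which(gid %in% tg)
    for (pos_i in seq_along(idx)) {
      i <- idx[pos_i]
      n_partner <- if (!is.na(focal_ct[i]) && focal_ct[i] == ct)
        spec$pp_partners_specific
      else if (runif(1) < spec$p_pp_other) spec$pp_partners_other else 0L
      if (n_partner < 1) next
      later <- idx[-seq_len(pos_i)]
      later <- later[chrom[later] == chrom[i]]
      partners <- head(later, n_partner)
      if (!length(partners)) next
      loops[[ct]][[paste0("pp.", gid[i])]] <- data.frame(
        k1 = paste0(gid[i], ".P"), k2 = paste0(gid[partners], ".P"),
        pet = nb_pet(length(partners)))
    }
    # shared enhancers between adjacent trees
    for (pos_i in seq_along(idx)[-1]) {
      i <- idx[pos_i]; prev <- idx[pos_i - 1L]
      if (chrom[i] != chrom[prev]) next
      if (runif(1) >= spec$p_shared_enhancer) next
      prev_e1 <- anchor_df$key[anchor_df$gene_id == gid[prev] & anchor_df$role == "E1"]
      loops[[ct]][[paste0("share.", gid[i])]] <- data.frame(
        k1 = paste0(gid[i], ".P"), k2 = sample(prev_e1, 1), pet = nb_pet(1))
    }
  }

  # materialise loop tables with anchor coordinates
  arow <- setNames(seq_len(nrow(anchor_df)), anchor_df$key)
  loops_out <- setNames(vector("list", K), cts)
  for (ct in cts) {
    lp <- do.call(rbind, loops[[ct]])
    i1 <- arow[lp$k1]; i2 <- arow[lp$k2]
    loops_out[[ct]] <- data.frame(
      chrom = anchor_df$chrom[i1],
      start1 = anchor_df$start[i1], end1 = anchor_df$end[i1],
      start2 = anchor_df$start[i2], end2 = anchor_df$end[i2],
      pet = lp$pet, cell_type = ct, stringsAsFactors = FALSE)
    rownames(loops_out[[ct]]) <- NULL
  }

  # accessibility peaks: one peak per planted anchor
  peaks <- data.frame(chrom = anchor_df$chrom, start = anchor_df$start,
                      end = anchor_df$end, stringsAsFactors = FALSE)
  for (ci in seq_len(K)) {
    v <- rlnorm(nrow(anchor_df), spec$atac_meanlog, spec$atac_sdlog)
    boost_i <- !is.na(focal_ct[match(anchor_df$gene_id, gid)]) &
      focal_ct[match(anchor_df$gene_id, gid)] == cts[ci] & anchor_df$role == "E1"
    v[boost_i] <- v[boost_i] * spec$signal
    crit <- boost_i & grepl("\\.E1\\.1$", anchor_df$key)
    v[crit] <- v[crit] * spec$critical_enhancer_boost
    peaks[[paste0("atac_", cts[ci])]] <- round(v, 3)
  }

  # gene annotation: tree genes plus bystanders
  by_df <- if (length(bystanders)) do.call(rbind, bystanders) else NULL
  genes <- data.frame(gene_id = gid, symbol = toupper(gid), chrom = chrom,
                      strand = sample(c("+", "-"), n_tg, replace = TRUE),
                      tss = tss, biotype = "coding", stringsAsFactors = FALSE)
  if (!is.null(by_df)) {
    nb <- nrow(by_df)
    by_genes <- data.frame(
      gene_id = sprintf("by%05d", seq_len(nb)), symbol = sprintf("BY%05d", seq_len(nb)),
      chrom = by_df$chrom, strand = sample(c("+", "-"), nb, replace = TRUE),
      tss = by_df$tss,
      biotype = ifelse(runif(nb) < 0.68, "noncoding", "coding"),
      stringsAsFactors = FALSE)
    by_df$gene_id <- by_genes$gene_id
    genes <- rbind(genes, by_genes)
  }

  # expression: ESS and abundance per cell type
  expr <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  fct <- focal_ct[match(genes$gene_id, gid)]   # NA for pool genes and bystanders
  is_by <- grepl("^by", genes$gene_id)
  for (ct in cts) {
    e <- runif(nrow(genes), 0.02, 0.28)
    hi <- !is.na(fct) & fct == ct
    e[hi] <- runif(sum(hi), 0.75, 0.95)
    a <- rlnorm(nrow(genes), log(10), 0.5)
    a[hi] <- a[hi] * 5
    a[is_by] <- rlnorm(sum(is_by), log(2), 0.5)
    expr[[paste0("ess_", ct)]] <- round(e, 4)
    expr[[paste0("abund_", ct)]] <- round(a, 3)
  }

  # SNPs: significant ones planted in critical / other enhancer anchors,
  # plus a non-significant background panel
  crit_df <- if (length(critical)) do.call(rbind, critical) else NULL
  snp_rows <- list()
  if (!is.null(crit_df)) {
    in_crit <- runif(nrow(crit_df)) < spec$snp_in_critical
    for (r in which(in_crit)) {
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        chrom = crit_df$chrom[r], pos = crit_df$midpoint[r],
        snp_id = paste0("rsC_", crit_df$gene_id[r]),
        gwas_p = 10^-runif(1, 5, 9), placement = "critical",
        gene_id = crit_df$gene_id[r], stringsAsFactors = FALSE)
    }
    in_other <- runif(nrow(crit_df)) < spec$snp_in_other
    for (r in which(in_other)) {
      g <- crit_df$gene_id[r]
      cand <- anchor_df[anchor_df$gene_id == g & anchor_df$role != "P" &
                          anchor_df$key != crit_df$key[r], , drop = FALSE]
      if (!nrow(cand)) next
      pick <- cand[sample(nrow(cand), 1), ]
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        chrom = pick$chrom, pos = pick$mid, snp_id = paste0("rsO_", g),
        gwas_p = 10^-runif(1, 5, 9), placement = "other", gene_id = g,
        stringsAsFactors = FALSE)
    }
  }
  n_chrom <- max(1L, ceiling(n_tg / spec$genes_per_chrom))
  bg <- data.frame(
    chrom = paste0("chr", sample(n_chrom, spec$n_background_snps, replace = TRUE)),
    pos = sample.int(spec$genes_per_chrom * spec$block_bp, spec$n_background_snps),
    snp_id = sprintf("rsB%05d", seq_len(spec$n_background_snps)),
    gwas_p = 10^-runif(spec$n_background_snps, 0, 3),
    placement = "background", gene_id = NA_character_, stringsAsFactors = FALSE)
  snp_manifest <- rbind(if (length(snp_rows)) do.call(rbind, snp_rows) else NULL, bg)
  rownames(snp_manifest) <- NULL
  snps <- snp_manifest[, c("chrom", "pos", "snp_id", "gwas_p")]

  manifest <- list(
    params = unclass(spec),
    focal = data.frame(gene_id = gid[!is.na(focal_ct)],
                       cell_type = focal_ct[!is.na(focal_ct)],
                       stringsAsFactors = FALSE),
    critical = if (!is.null(crit_df)) crit_df[, c("gene_id", "cell_type", "chrom",
                                                  "start", "end", "midpoint")] else NULL,
    bystanders = by_df,
    snps = snp_manifest,
    tree_genes_by_ct = by_ct_genes,
    n_genes = nrow(genes), n_anchors = nrow(anchor_df))

  list(spec = spec, cell_types = cts, genes = genes, expression = expr,
       peaks = peaks, loops = loops_out, snps = snps, manifest = manifest)
}

#' Write a fixture bundle to disk as plain-text tables
#'
#' Writes `genes.tsv`, `expression.tsv`, `peaks.tsv`, `snps.tsv` (1-based
#' positions), one `loops_<cell type>.bedpe` per cell type, and
#' `manifest.json`. The files round-trip through the package readers.
#'
#' @param bundle result of [simulate_fixture()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv(bundle$genes, file.path(dir, "genes.tsv"))
  write_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  write_tsv(bundle$peaks, file.path(dir, "peaks.tsv"))
  snps <- bundle$snps
  snps$pos <- snps$pos + 1L
  write_tsv(snps, file.path(dir, "snps.tsv"))
  for (ct in bundle$cell_types) {
    lp <- bundle$loops[[ct]]
    bedpe <- data.frame(chrom1 = lp$chrom, start1 = lp$start1, end1 = lp$end1,
                        chrom2 = lp$chrom, start2 = lp$start2, end2 = lp$end2,
                        name = sprintf("loop%06d", seq_len(nrow(lp))),
                        pet = lp$pet)
    utils::write.table(bedpe, file.path(dir, paste0("loops_", ct, ".bedpe")),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(cell_types = bundle$cell_types,
                            manifest = bundle$manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a fixture directory back into a bundle
#'
#' @param dir directory written by [write_fixture()]
#' @return list shaped like [simulate_fixture()] output (without `spec`)
#' @export
read_fixture <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cts <- man$cell_types
  loops <- setNames(lapply(cts, function(ct)
    read_loops(file.path(dir, paste0("loops_", ct, ".bedpe")), ct)), cts)
  list(cell_types = cts,
       genes = read_genes(file.path(dir, "genes.tsv")),
       expression = read_expression(file.path(dir, "expression.tsv"), cts),
       peaks = read_peaks(file.path(dir, "peaks.tsv"), cts),
       loops = loops,
       snps = read_snps(file.path(dir, "snps.tsv")),
       manifest = man$manifest)
}

#' Resolve planted critical enhancers to consensus node names
#'
#' @param manifest fixture manifest (list with a `critical` data.frame)
#' @param anchors classified consensus anchors
#' @return the `critical` table with a `node_name` column
#' @export
map_manifest_nodes <- function(manifest, anchors) {
  cr <- manifest$critical
  if (is.null(cr) || !nrow(cr)) return(cr)
  hit <- function(chrom, mid) {
    i <- which(anchors$chrom == chrom & anchors$start <= mid & anchors$end > mid)
    if (length(i) == 1L) anchors$node_name[i] else NA_character_
  }
  cr$node_name <- mapply(hit, cr$chrom, cr$midpoint)
  cr
}
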