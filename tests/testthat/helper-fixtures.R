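# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small four-cell-type bundle with consensus products, for module tests.
small_world <- function() {
  if (is.null(.fixture_env$small)) {
    b <- simulate_fixture(fixture_spec(seed = 42, n_focal = 10, n_nonfocal = 25,
                                       n_background_snps = 60,
                                       genes_per_chrom = 15))
    all_iv <- do.call(rbind, lapply(b$loops, epictrees:::loop_anchors))
    anchors <- classify_anchors(build_consensus_anchors(all_iv), b$genes)
    loops <- build_consensus_loops(b$loops, anchors)
    trees <- setNames(lapply(b$cell_types, function(ct)
      extract_trees(anchors, loops, ct)), b$cell_types)
    atac <- atac_by_node(anchors, b$peaks, b$cell_types)
    .fixture_env$small <- list(bundle = b, anchors = anchors, loops = loops,
                               trees = trees, atac = atac)
  }
  .fixture_env$small
}

# Hand-built one-cell-type tree object:
#   P (root, gene gX) - E1a (atac 10, pet 4) ; E1a - E2a (atac 2, pet 1)
#   P - E1b (atac 7, pet 3)
toy_tree <- function(cell_type = "alpha") {
  structure(list(
    cell_type = cell_type,
    trees = data.frame(tree_id = "t1", root = "P", gene_id = "gX",
                       n_enhancers = 3L, n_edges = 3L),
    nodes = data.frame(tree_id = "t1",
                       node_name = c("P", "E1a", "E1b", "E2a"),
                       level = c(0L, 1L, 1L, 2L),
                       kind = c("P", "E", "E", "E")),
    edges = data.frame(tree_id = "t1",
                       n1 = c("P", "P", "E1a"), n2 = c("E1a", "E1b", "E2a"),
                       level = c(1L, 1L, 3L), pet = c(4, 3, 1)),
    pp_edges = data.frame(n1 = character(), n2 = character(), pet = numeric()),
    orphans = character(), min_pet = 1), class = "enhancer_trees")
}

toy_atac <- function(cell_types = c("alpha", "beta", "acinar", "duct")) {
  df <- data.frame(node_name = c("P", "E1a", "E1b", "E2a"))
  for (ct in cell_types) df[[paste0("atac_", ct)]] <- c(5, 10, 7, 2)
  df
}

# Random small graph over one promoter + enhancers, for level-oracle tests.
random_graph <- function(n_nodes, p_edge = 0.3) {
  nodes <- c("P1", paste0("E", seq_len(n_nodes - 1)))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(n1 = pairs[keep, 1], n2 = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
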