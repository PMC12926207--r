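test_that("level assignment follows shortest paths from the root", {
  chain <- data.frame(n1 = c("P", "A"), n2 = c("A", "B"))
  expect_equal(assign_levels(chain, "P"), c(P = 0L, A = 1L, B = 2L))
  sq <- data.frame(n1 = c("P", "A", "P", "B"), n2 = c("A", "B", "C", "C"))
  lev <- assign_levels(sq, "P")
  expect_equal(lev[c("A", "C", "B")], c(A = 1L, C = 1L, B = 2L))
})

test_that("edge levels are endpoint sums and equal-level edges get pruned", {
  lev <- c(P = 0L, E1a = 1L, E1b = 1L, E2 = 2L)
  ed <- data.frame(n1 = c("P", "E1a", "E1a"), n2 = c("E1a", "E2", "E1b"))
  ed <- assign_edge_levels(ed, lev)
  expect_equal(ed$level, c(1L, 3L, 2L))
  pruned <- prune_redundant(ed, lev)
  expect_equal(pruned$level, c(1L, 3L))
  # chain with nothing to delete is unchanged
  chain <- assign_edge_levels(data.frame(n1 = c("P", "A"), n2 = c("A", "B")),
                              c(P = 0L, A = 1L, B = 2L))
  expect_equal(prune_redundant(chain, c(P = 0L, A = 1L, B = 2L)), chain)
})

test_that("pruning removes every even edge and never changes node levels", {
  set.seed(21)
  for (i in 1:50) {
    g <- random_graph(sample(4:12, 1))
    lev <- assign_levels(g$edges, "P1", nodes = g$nodes)
    ed <- assign_edge_levels(g$edges, lev)
    pruned <- prune_redundant(ed, lev)
    expect_true(all(is.na(pruned$level) | pruned$level %% 2 == 1))
    expect_true(all(abs(lev[pruned$n1] - lev[pruned$n2]) == 1, na.rm = TRUE))
    # shortest paths are preserved without the equal-level edges
    lev2 <- assign_levels(pruned, "P1", nodes = g$nodes)
    expect_equal(lev2, lev)
  }
})

test_that("an enhancer between two promoters appears in both trees", {
  genes <- data.frame(gene_id = c("g1", "g2"), symbol = c("g1", "g2"),
                      chrom = "chr1", strand = "+", tss = c(10000, 40000),
                      biotype = "coding")
  anchors <- classify_anchors(build_consensus_anchors(data.frame(
    chrom = "chr1", start = c(9000, 24000, 39000), end = c(10500, 25000, 40500))),
    genes)
  loops <- build_consensus_loops(list(alpha = data.frame(
    chrom = "chr1", start1 = c(9000, 24000), end1 = c(10500, 25000),
    start2 = c(24000, 39000), end2 = c(25000, 40500), pet = c(2, 3),
    cell_type = "alpha")), anchors)
  tr <- extract_trees(anchors, loops, "alpha")
  expect_equal(nrow(tr$trees), 2)
  e_rows <- tr$nodes[tr$nodes$kind == "E", ]
  expect_equal(nrow(e_rows), 2)                      # one instance per tree
  expect_equal(unique(e_rows$node_name), "1.2E")     # same anchor in both
  expect_equal(e_rows$level, c(1L, 1L))
  expect_equal(sort(tr$trees$gene_id), c("g1", "g2"))
})

test_that("promoterless components are counted as orphan enhancers", {
  genes <- data.frame(gene_id = "g1", symbol = "g1", chrom = "chr1",
                      strand = "+", tss = 10000, biotype = "coding")
  anchors <- classify_anchors(build_consensus_anchors(data.frame(
    chrom = "chr1", start = c(9000, 50000, 70000), end = c(10500, 51000, 71000))),
    genes)
  loops <- build_consensus_loops(list(alpha = data.frame(
    chrom = "chr1", start1 = 50000, end1 = 51000, start2 = 70000, end2 = 71000,
    pet = 2, cell_type = "alpha")), anchors)
  tr <- extract_trees(anchors, loops, "alpha")
  expect_equal(nrow(tr$trees), 0)
  expect_setequal(tr$orphans, c("1.2E", "1.3E"))
})

test_that("tree extraction matches an independent per-promoter BFS oracle", {
  set.seed(31)
  w <- small_world()
  tr <- w$trees$beta
  kind <- setNames(w$anchors$node_kind, w$anchors$node_name)
  sub <- w$loops[w$loops$pet_beta >= 1, ]
  ee <- sub[!(kind[sub$n1] == "P" & kind[sub$n2] == "P"), c("n1", "n2")]
  promoters <- unique(c(sub$n1, sub$n2))
  promoters <- promoters[kind[promoters] == "P"]
  nodes <- unique(c(ee$n1, ee$n2))
  for (p in intersect(promoters, tr$trees$root)[1:10]) {
    lev <- oracle_levels(ee, p, nodes, blocked = setdiff(promoters, p))
    want <- lev[!is.na(lev)]
    got <- tr$nodes[tr$nodes$tree_id == paste0("beta.", p), ]
    expect_setequal(got$node_name, names(want))
    expect_equal(setNames(got$level, got$node_name)[names(want)], want)
  }
})

test_that("every tree has exactly one promoter: its root", {
  w <- small_world()
  for (ct in names(w$trees)) {
    nd <- w$trees[[ct]]$nodes
    n_p <- tapply(nd$kind == "P", nd$tree_id, sum)
    expect_true(all(n_p == 1))
    roots <- setNames(w$trees[[ct]]$trees$root, w$trees[[ct]]$trees$tree_id)
    p_nodes <- nd$node_name[nd$kind == "P"]
    expect_setequal(unique(p_nodes), unique(unname(roots)))
  }
})

test_that("forest detection equals union-find components and partitions trees", {
  w <- small_world()
  for (ct in c("alpha", "duct")) {
    tr <- w$trees[[ct]]
    fo <- detect_forests(tr, w$anchors)
    # oracle: trees connected iff they share a node or their roots share a PP loop
    ids <- tr$trees$tree_id
    by_node <- split(tr$nodes$tree_id, tr$nodes$node_name)
    prs <- do.call(rbind, lapply(by_node, function(tt) {
      tt <- unique(tt)
      if (length(tt) < 2) return(NULL)
      t(combn(tt, 2))
    }))
    root_tree <- setNames(ids, tr$trees$root)
    pp_ok <- tr$pp_edges$n1 %in% names(root_tree) & tr$pp_edges$n2 %in% names(root_tree)
    prs <- rbind(prs, cbind(unname(root_tree[tr$pp_edges$n1[pp_ok]]),
                            unname(root_tree[tr$pp_edges$n2[pp_ok]])))
    comp <- oracle_components(ids, if (is.null(prs)) matrix(character(), 0, 2) else prs)
    sizes <- table(comp)
    want_in_forest <- sizes[comp] >= 2
    got_in_forest <- !is.na(fo$membership$forest_id[match(ids, fo$membership$tree_id)])
    expect_equal(unname(got_in_forest), unname(want_in_forest), ignore_attr = TRUE)
    # same partition among forest trees
    inf <- ids[got_in_forest]
    got_part <- fo$membership$forest_id[match(inf, fo$membership$tree_id)]
    expect_true(all(tapply(comp[inf], got_part, function(x) length(unique(x))) == 1))
    # membership covers all trees at most once
    expect_setequal(fo$membership$tree_id, ids)
  }
})

test_that("two trees sharing an enhancer form a forest; disjoint trees do not", {
  mk_trees <- function(share) {
    e2 <- if (share) "Es" else "E2"
    structure(list(cell_type = "alpha",
      trees = data.frame(tree_id = c("t1", "t2"), root = c("P1", "P2"),
                         gene_id = c("g1", "g2"), n_enhancers = 1L, n_edges = 1L),
      nodes = data.frame(tree_id = c("t1", "t1", "t2", "t2"),
                         node_name = c("P1", "Es", "P2", e2),
                         level = c(0L, 1L, 0L, 1L), kind = c("P", "E", "P", "E")),
      edges = data.frame(tree_id = c("t1", "t2"), n1 = c("P1", "P2"),
                         n2 = c("Es", e2), level = 1L, pet = 1),
      pp_edges = data.frame(n1 = character(), n2 = character(), pet = numeric()),
      orphans = character(), min_pet = 1), class = "enhancer_trees")
  }
  anchors <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                        end = c(50, 150, 250, 350), midpoint = c(25, 125, 225, 325),
                        node_name = c("P1", "Es", "P2", "E2"),
                        node_kind = c("P", "E", "P", "E"), anchor_id = 1:4,
                        gene_id = c("g1", NA, "g2", NA))
  expect_equal(nrow(detect_forests(mk_trees(TRUE), anchors)$forests), 1)
  expect_equal(nrow(detect_forests(mk_trees(FALSE), anchors)$forests), 0)
})

test_that("connectivity summaries count multiplicity and direct fractions", {
  # P1-E-P2: the shared enhancer touches two promoters
  tr <- structure(list(cell_type = "alpha",
    trees = data.frame(tree_id = c("t1", "t2"), root = c("P1", "P2"),
                       gene_id = c("g1", "g2"), n_enhancers = 1L, n_edges = 1L),
    nodes = data.frame(tree_id = c("t1", "t1", "t2", "t2"),
                       node_name = c("P1", "E", "P2", "E"),
                       level = c(0L, 1L, 0L, 1L), kind = c("P", "E", "P", "E")),
    edges = data.frame(tree_id = c("t1", "t2"), n1 = c("P1", "P2"),
                       n2 = c("E", "E"), level = 1L, pet = 1),
    pp_edges = data.frame(n1 = character(), n2 = character(), pet = numeric()),
    orphans = character(), min_pet = 1), class = "enhancer_trees")
  anchors <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                        end = c(50, 150, 250), midpoint = c(25, 125, 225),
                        node_name = c("P1", "E", "P2"), node_kind = c("P", "E", "P"),
                        anchor_id = 1:3, gene_id = c("g1", NA, "g2"))
  st <- connectivity_stats(tr, detect_forests(tr, anchors))
  expect_equal(unlist(st$multiplicity_histogram), c(`1` = 0L, `2` = 1L, `3+` = 0L))
  # chain P-A-B: one direct and one indirect enhancer, one L1 of two edges
  chain <- toy_tree()
  chain$nodes <- chain$nodes[chain$nodes$node_name != "E1b", ]
  chain$edges <- chain$edges[chain$edges$n2 != "E1b", ]
  chain$trees$n_enhancers <- 2L
  st2 <- connectivity_stats(chain, detect_forests(chain, data.frame(
    chrom = "chr1", start = c(0, 100, 200), end = c(50, 150, 250),
    midpoint = c(25, 125, 225), node_name = c("P", "E1a", "E2a"),
    node_kind = c("P", "E", "E"), anchor_id = 1:3, gene_id = c("gX", NA, NA))))
  expect_equal(st2$e1_fraction_instances, 0.5)
  expect_equal(st2$l1_fraction_edges, 0.5)
})

test_that("pp_comparison separates planted PP-rich specific forests", {
  w <- small_world()
  tr <- w$trees$alpha
  fo <- detect_forests(tr, w$anchors)
  res <- pp_comparison(tr, fo, w$bundle$expression)
  if (is.null(res$flag)) {
    expect_gte(res$median_specific, res$median_other)
    # U statistic equals exhaustive rank enumeration
    a <- res$groups$pp_count[res$groups$specific]
    b <- res$groups$pp_count[!res$groups$specific]
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    expect_equal(unname(wt$statistic), oracle_U(a, b))
  }
})
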