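four_cts <- c("alpha", "beta", "acinar", "duct")

empty_trees <- function(ct) {
  structure(list(cell_type = ct,
    trees = data.frame(tree_id = character(), root = character(),
                       gene_id = character(), n_enhancers = integer(),
                       n_edges = integer()),
    nodes = data.frame(tree_id = character(), node_name = character(),
                       level = integer(), kind = character()),
    edges = data.frame(tree_id = character(), n1 = character(),
                       n2 = character(), level = integer(), pet = numeric()),
    pp_edges = data.frame(n1 = character(), n2 = character(), pet = numeric()),
    orphans = character(), min_pet = 1), class = "enhancer_trees")
}

test_that("the six per-cell-type predictors follow the parent-edge pairing", {
  trees <- list(alpha = toy_tree("alpha"), beta = empty_trees("beta"),
                acinar = empty_trees("acinar"), duct = empty_trees("duct"))
  fv <- featurize("gX", trees, toy_atac())
  expect_length(fv, 24)
  # E1a: atac 10 with L1 pet 4; E1b: atac 7 pet 3; E2a: atac 2 with L3 pet 1
  expect_equal(unname(fv["atac_d_alpha"]), 17)
  expect_equal(unname(fv["pet_d_alpha"]), 7)
  expect_equal(unname(fv["atacxpet_d_alpha"]), 10 * 4 + 7 * 3)
  expect_equal(unname(fv["atac_i_alpha"]), 2)
  expect_equal(unname(fv["pet_i_alpha"]), 1)
  expect_equal(unname(fv["atacxpet_i_alpha"]), 2)
  # no tree in the other cell types: all zeros
  expect_true(all(fv[grep("duct|beta|acinar", names(fv))] == 0))
})

test_that("features equal an independent per-node summation on generated trees", {
  w <- small_world()
  genes <- head(sort(unique(w$trees$alpha$trees$gene_id)), 8)
  X <- build_feature_matrix(genes, w$trees, w$atac)
  for (g in genes) {
    for (ct in four_cts) {
      tr <- w$trees[[ct]]
      tids <- tr$trees$tree_id[tr$trees$gene_id == g]
      nd <- tr$nodes[tr$nodes$tree_id %in% tids, ]
      ed <- tr$edges[tr$edges$tree_id %in% tids, ]
      av <- setNames(w$atac[[paste0("atac_", ct)]], w$atac$node_name)
      # brute force: loop over node instances
      atac_d <- pet_d <- axp_d <- atac_i <- pet_i <- axp_i <- 0
      for (r in seq_len(nrow(nd))) {
        if (nd$level[r] < 1) next
        a <- unname(av[nd$node_name[r]])
        par <- ed[ed$tree_id == nd$tree_id[r] &
                    ((ed$n1 == nd$node_name[r] & ed$level - nd$level[r] < nd$level[r]) |
                     (ed$n2 == nd$node_name[r] & ed$level - nd$level[r] < nd$level[r])), ]
        pp <- sum(par$pet)
        if (nd$level[r] == 1) { atac_d <- atac_d + a; axp_d <- axp_d + a * pp }
        else { atac_i <- atac_i + a; axp_i <- axp_i + a * pp }
      }
      pet_d <- sum(ed$pet[ed$level == 1]); pet_i <- sum(ed$pet[ed$level > 1])
      expect_equal(unname(X[g, paste0(c("atac_d_", "pet_d_", "atacxpet_d_",
                                        "atac_i_", "pet_i_", "atacxpet_i_"), ct)]),
                   c(atac_d, pet_d, axp_d, atac_i, pet_i, axp_i))
    }
  }
})

test_that("training sets are balanced, thresholded, and seeded", {
  w <- small_world()
  tg <- lapply(w$trees, function(tr) unique(tr$trees$gene_id))
  ts <- build_training_set(w$bundle$expression, "alpha", tg, seed = 4)
  expect_equal(sum(ts$class == "focal"), sum(ts$class == "nonfocal"))
  ess <- w$bundle$expression
  pos_ess <- ess$ess_alpha[match(ts$gene_id[ts$class == "focal"], ess$gene_id)]
  expect_true(all(pos_ess > 0.7))
  neg <- ts$gene_id[ts$class == "nonfocal"]
  neg_ess <- as.matrix(ess[match(neg, ess$gene_id), ct_cols("ess", four_cts)])
  expect_true(all(neg_ess < 0.3))
  expect_identical(ts, build_training_set(w$bundle$expression, "alpha", tg, seed = 4))
  # a gene between the thresholds joins neither class
  mid <- ess
  mid$ess_alpha[1] <- 0.5
  ts2 <- build_training_set(mid, "alpha", tg, seed = 4)
  expect_false(mid$gene_id[1] %in% ts2$gene_id[ts2$class == "focal"])
})

test_that("kNN cross-validation separates a wide-margin dataset and respects folds", {
  set.seed(2)
  X <- rbind(matrix(rnorm(200, 10), 20), matrix(rnorm(200, -10), 20))
  y <- factor(rep(c("focal", "nonfocal"), each = 20), levels = c("nonfocal", "focal"))
  m <- train_and_evaluate(X, y, folds = 5, k_grid = c(3, 5, 7), seed = 1)
  expect_equal(m$cv_accuracy, 1)
  expect_true(all(m$prob[1:20] > 0.5) && all(m$prob[21:40] < 0.5))
  # k = 1 classifies an exact duplicate pair with equal labels correctly
  X2 <- rbind(X, X[c(1, 21), ])
  y2 <- factor(c(as.character(y), "focal", "nonfocal"), levels = levels(y))
  m2 <- train_and_evaluate(X2, y2, folds = 5, k_grid = 1, seed = 3)
  expect_equal(m2$cv_accuracy, 1)
  # too-large k values are dropped with a message
  expect_message(train_and_evaluate(X, y, folds = 5, k_grid = c(3, 500), seed = 1),
                 "dropped 1 k value")
})

test_that("per-fold standardisation uses training-fold statistics only", {
  set.seed(8)
  n <- 60; p <- 4
  X <- matrix(rnorm(n * p, sd = c(1, 10, 100, 1000)), n, byrow = TRUE)
  y_pos <- rep(c(TRUE, FALSE), each = n / 2)
  fold <- make_folds(y_pos, 5, seed = 2)
  k <- 5
  votes <- epictrees:::knn_cv_votes_cpp(X, as.integer(y_pos), as.integer(fold), as.integer(k))
  # independent R recomputation with explicit train-only scaling
  want <- rep(NA_real_, n)
  for (f in 1:5) {
    tr <- which(fold != f); te <- which(fold == f)
    mu <- colMeans(X[tr, ]); sdv <- apply(X[tr, ], 2, sd); sdv[sdv == 0] <- 1
    Xs <- scale(X, center = mu, scale = sdv)
    for (t in te) {
      d <- sqrt(rowSums((Xs[tr, , drop = FALSE] -
                           matrix(Xs[t, ], length(tr), p, byrow = TRUE))^2))
      ord <- order(d, tr)   # distance ties toward smaller training index
      want[t] <- mean(y_pos[tr][ord[1:k]])
    }
  }
  expect_equal(as.numeric(votes), want)
})

test_that("deterministic voting agrees with a reference kNN on tie-free data", {
  skip_if_not_installed("class")
  set.seed(5)
  X <- matrix(rnorm(80 * 3), 80)
  y_pos <- rep(c(TRUE, FALSE), 40)
  fold <- make_folds(y_pos, 4, seed = 6)
  votes <- epictrees:::knn_cv_votes_cpp(X, as.integer(y_pos), as.integer(fold), 7L)
  for (f in 1:4) {
    tr <- which(fold != f); te <- which(fold == f)
    mu <- colMeans(X[tr, ]); sdv <- apply(X[tr, ], 2, sd)
    Xs <- scale(X, center = mu, scale = sdv)
    ref <- class::knn(Xs[tr, ], Xs[te, ], factor(y_pos[tr]), k = 7, prob = TRUE)
    pr <- attr(ref, "prob")
    ref_votes <- ifelse(ref == "TRUE", pr, 1 - pr)
    expect_equal(votes[te], ref_votes, tolerance = 1e-9)
  }
})

test_that("promoter-only and linear baseline features follow their definitions", {
  anchors <- data.frame(chrom = "chr1", start = c(9000, 19750, 2009750),
                        end = c(10500, 20250, 2010250),
                        midpoint = c(9750, 20000, 2010000),
                        node_name = c("1.1P", "1.2E", "1.3E"),
                        node_kind = c("P", "E", "E"), anchor_id = 1:3,
                        gene_id = c("g1", NA, NA))
  atac <- data.frame(node_name = c("1.1P", "1.2E", "1.3E"))
  for (ct in four_cts) atac[[paste0("atac_", ct)]] <- c(6, 40, 99)
  genes <- data.frame(gene_id = "g1", symbol = "G1", chrom = "chr1",
                      strand = "+", tss = 10000, biotype = "coding")
  P <- promoter_features("g1", anchors, atac, four_cts)
  expect_equal(unname(P["g1", ]), rep(6, 4))
  L <- linear_features("g1", genes, anchors, atac, four_cts)
  # single enhancer with ATAC 40 at 10 kb contributes 40 * (1000/10000) = 4;
  # the enhancer at 2 Mb is outside the domain
  expect_equal(unname(L["g1", ]), rep(4, 4))
  # brute-force windowed weighted sum on random layouts
  set.seed(17)
  mids <- sort(sample(seq(5000, 3e6, 250), 30))
  anchors2 <- data.frame(chrom = "chr1", start = mids - 100, end = mids + 100,
                         midpoint = mids, node_name = paste0("1.", 1:30, "E"),
                         node_kind = "E", anchor_id = 1:30, gene_id = NA)
  atac2 <- data.frame(node_name = anchors2$node_name)
  vals <- runif(30, 1, 50)
  for (ct in four_cts) atac2[[paste0("atac_", ct)]] <- vals
  L2 <- linear_features("g1", genes, anchors2, atac2, four_cts)
  d <- abs(mids - 10000)
  ok <- d > 0 & d <= 1e6
  expect_equal(unname(L2["g1", 1]), sum(vals[ok] * 1000 / d[ok]))
})

test_that("tree perturbation removes dependent descendants only", {
  nodes <- data.frame(node_name = c("P", "A", "B"), level = 0:2)
  edges <- data.frame(n1 = c("P", "A"), n2 = c("A", "B"), level = c(1, 3), pet = 1)
  pt <- perturb_tree(nodes, edges, "P", "A")
  expect_equal(pt$nodes$node_name, "P")     # B is orphaned by A's removal
  expect_equal(nrow(pt$edges), 0)
  # diamond: B survives via C
  nodes2 <- data.frame(node_name = c("P", "A", "C", "B"), level = c(0, 1, 1, 2))
  edges2 <- data.frame(n1 = c("P", "P", "A", "C"), n2 = c("A", "C", "B", "B"),
                       level = c(1, 1, 3, 3), pet = 1)
  pt2 <- perturb_tree(nodes2, edges2, "P", "A")
  expect_setequal(pt2$nodes$node_name, c("P", "C", "B"))
  expect_equal(nrow(pt2$edges), 2)
  # removing a leaf removes only that node and its edge
  pt3 <- perturb_tree(nodes2, edges2, "P", "B")
  expect_setequal(pt3$nodes$node_name, c("P", "A", "C"))
  expect_error(perturb_tree(nodes, edges, "P", "P"), "root")
  expect_error(perturb_tree(nodes, edges, "P", "Z"), "not in tree")
})

test_that("the total deviation is the absolute-deviation sum", {
  expect_equal(effect_size_total(c(0.02, 0, 0.05, 0.02)), 0.09)
  expect_equal(effect_size_total(c(-0.02, 0, 0.05, -0.02)), 0.09)
  expect_equal(effect_size_total(numeric(0)), 0)
})

test_that("enhancers rank by effect size with name tie-breaks", {
  es <- data.frame(cell_type = "beta", tree_id = "t",
                   gene_id = "g", node_name = c("5.3120E", "5.3108E"),
                   effect_size = c(0.04, 0.1), n_reps = 1)
  r <- rank_enhancers(es)
  expect_equal(r$node_name, c("5.3108E", "5.3120E"))
  expect_equal(r$rank, c(1, 2))
  ties <- data.frame(cell_type = "beta", tree_id = "t", gene_id = "g",
                     node_name = c("bE", "aE", "cE"), effect_size = 0.1, n_reps = 1)
  expect_equal(rank_enhancers(ties)$node_name, c("aE", "bE", "cE"))
  set.seed(19)
  rnd <- data.frame(cell_type = "x", tree_id = sample(c("t1", "t2"), 30, TRUE),
                    gene_id = "g", node_name = sprintf("%02dE", 1:30),
                    effect_size = round(runif(30), 2), n_reps = 1)
  rr <- rank_enhancers(rnd)
  for (t in c("t1", "t2")) {
    sub <- rr[rr$tree_id == t, ]
    expect_true(all(diff(sub$effect_size) <= 0))
    expect_equal(sub$rank, seq_len(nrow(sub)))
  }
})

test_that("all-zero indirect predictors leave the full and direct-only models equal", {
  set.seed(23)
  Xd <- rbind(matrix(rnorm(120, 2), 12), matrix(rnorm(120, -2), 12))
  X <- cbind(Xd, matrix(0, 24, 12))   # indirect half identically zero
  y <- factor(rep(c("focal", "nonfocal"), each = 12), levels = c("nonfocal", "focal"))
  full <- train_and_evaluate(X, y, folds = 4, k_grid = c(3, 5), seed = 2)
  direct <- train_and_evaluate(Xd, y, folds = 4, k_grid = c(3, 5), seed = 2,
                               model_kind = "tree_direct_only")
  expect_equal(full$cv_accuracy, direct$cv_accuracy)
  expect_equal(full$prob, direct$prob)
})

test_that("effect sizes are non-negative, seeded, and null for inert nodes", {
  w <- small_world()
  tg <- w$bundle$manifest$focal
  targets <- head(tg[order(tg$gene_id), ], 4)
  es1 <- epic_effect_sizes(w$trees, w$atac, w$bundle$expression,
                           targets = targets, n_reps = 3, seed = 21)
  es2 <- epic_effect_sizes(w$trees, w$atac, w$bundle$expression,
                           targets = targets, n_reps = 3, seed = 21)
  expect_identical(es1, es2)                       # seeded determinism
  expect_true(all(es1$effect_size >= 0, na.rm = TRUE))
  # a node with zero ATAC and zero PET everywhere leaves features unchanged
  trees0 <- w$trees
  ct0 <- targets$cell_type[1]; g0 <- targets$gene_id[1]
  tr <- trees0[[ct0]]
  tid <- tr$trees$tree_id[tr$trees$gene_id == g0][1]
  leafs <- tr$nodes$node_name[tr$nodes$tree_id == tid & tr$nodes$level == 1]
  add <- "99.9999E"
  tr$nodes <- rbind(tr$nodes, data.frame(tree_id = tid, node_name = add,
                                         level = 1L, kind = "E"))
  tr$edges <- rbind(tr$edges, data.frame(tree_id = tid,
                                         n1 = tr$trees$root[tr$trees$tree_id == tid],
                                         n2 = add, level = 1L, pet = 0))
  trees0[[ct0]] <- tr
  atac0 <- rbind(w$atac, setNames(data.frame(add, 0, 0, 0, 0), names(w$atac)))
  es0 <- epic_effect_sizes(trees0, atac0, w$bundle$expression,
                           targets = targets[1, , drop = FALSE],
                           n_reps = 3, seed = 21)
  expect_equal(es0$effect_size[es0$node_name == add], 0)
})
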