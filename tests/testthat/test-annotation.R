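toy_anchor_table <- function() {
  data.frame(chrom = "chr5", start = c(0, 275302, 149575, 400000),
             end = c(500, 275802, 150075, 400500),
             midpoint = c(250, 275552, 149825, 400250),
             node_name = c("P", "E1a", "E2a", "E1b"),
             node_kind = c("P", "E", "E", "E"),
             anchor_id = 1:4, gene_id = c("gX", NA, NA, NA))
}

test_that("chain records carry midpoint-to-TSS distances and edge PETs", {
  tr <- toy_tree()
  anchors <- toy_anchor_table()
  anchors$node_name[4] <- "E1b"
  genes <- data.frame(gene_id = "gX", symbol = "GX", chrom = "chr5",
                      strand = "+", tss = 0, biotype = "coding")
  ch <- extract_chains(tr, anchors, genes)
  full <- ch[ch$e1 == "E1a", ]
  expect_equal(full$d_e1, 275552)
  expect_equal(full$d_e2, 149825)
  expect_equal(full$pet_l1, 4)
  expect_equal(full$pet_l3, 1)
  leaf <- ch[ch$e1 == "E1b", ]
  expect_true(is.na(leaf$e2) && is.na(leaf$d_e2))
  expect_equal(leaf$pet_l1, 3)
})

test_that("chain distances equal recomputation from raw coordinates", {
  w <- small_world()
  tr <- w$trees$acinar
  ch <- extract_chains(tr, w$anchors, w$bundle$genes)
  mid <- setNames(w$anchors$midpoint, w$anchors$node_name)
  tss <- setNames(w$bundle$genes$tss, w$bundle$genes$gene_id)
  expect_equal(ch$d_e1, abs(mid[ch$e1] - tss[ch$gene_id]), ignore_attr = TRUE)
  has2 <- !is.na(ch$e2)
  expect_equal(ch$d_e2[has2], unname(abs(mid[ch$e2[has2]] - tss[ch$gene_id[has2]])))
})

test_that("orientation is a sign comparison and reflection-invariant", {
  expect_equal(classify_orientation(500000, 400000, 450000), "InsideLoop")
  expect_equal(classify_orientation(500000, 400000, 520000), "OutsideLoop")
  expect_warning(classify_orientation(500000, 400000, 500000), "undefined")
  set.seed(13)
  mid <- runif(50, 0, 1e6)
  lo <- mid + sample(c(-1, 1), 50, TRUE) * runif(50, 1, 1e5)
  sk <- mid + sample(c(-1, 1), 50, TRUE) * runif(50, 1, 1e5)
  got <- classify_orientation(mid, lo, sk)
  want <- ifelse(sign(lo - mid) == sign(sk - mid), "InsideLoop", "OutsideLoop")
  expect_equal(got, want)
  # reflect all coordinates about an arbitrary point
  r <- 123456
  expect_equal(classify_orientation(2 * r - mid, 2 * r - lo, 2 * r - sk), got)
})

test_that("skipping classification and winners behave on planted structure", {
  w <- small_world()
  tr <- w$trees$beta
  sk <- skipping_analysis(tr, w$anchors, w$bundle$genes, w$bundle$expression)
  # count conservation over assessed E1 nodes
  n_e1 <- sum(tr$nodes$level == 1 & tr$nodes$kind == "E")
  expect_equal(nrow(sk), n_e1)
  expect_equal(sum(is.na(sk$skipped)) + sum(sk$skipped, na.rm = TRUE) +
                 sum(!sk$skipped, na.rm = TRUE), n_e1)
  # looped gene == nearest gene is never 'skipped'
  same <- !is.na(sk$skipped) & sk$nearest_gene == sk$looped_gene
  expect_true(all(!sk$skipped[same]))
  # planted focal trees loop to high-ESS genes while bystanders are low:
  # whenever the skipped gene is a planted bystander, the looped gene wins
  focal_beta <- w$bundle$manifest$focal$gene_id[w$bundle$manifest$focal$cell_type == "beta"]
  pl <- sk[!is.na(sk$skipped) & sk$skipped & sk$looped_gene %in% focal_beta &
             grepl("^by", sk$nearest_gene), ]
  expect_gt(nrow(pl), 0)
  expect_true(all(pl$ess_winner == "looped"))
})

test_that("Pearson chi-square matches hand computation and flags degeneracy", {
  got <- orientation_chisq(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(got$chi2, 20 / 3, tolerance = 1e-12)   # by the r x c formula
  expect_equal(got$df, 1)
  prop <- matrix(c(10, 20, 20, 40, 5, 10), 3, byrow = TRUE)
  expect_equal(orientation_chisq(prop)$chi2, 0, tolerance = 1e-12)
  expect_error(orientation_chisq(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "row")
  expect_error(orientation_chisq(matrix(c(0, 1, 0, 4), 2, byrow = TRUE)), "column")
  five <- matrix(c(30, 12, 25, 14, 40, 11, 22, 9, 18, 8), 5, byrow = TRUE)
  expect_equal(orientation_chisq(five)$df, 4)
})

test_that("paired expression comparison matches textbook arithmetic", {
  w <- small_world()
  tr <- w$trees$alpha
  sk <- skipping_analysis(tr, w$anchors, w$bundle$genes, w$bundle$expression)
  res <- expression_vs_treesize(tr, w$bundle$expression, sk)
  expect_equal(nrow(res$bins$ess), 4)
  # recompute the paired t for ESS by the formula t = mean(d) / (sd(d)/sqrt(n))
  ess <- setNames(w$bundle$expression$ess_alpha, w$bundle$expression$gene_id)
  pairs <- sk[!is.na(sk$skipped) & sk$skipped, ]
  pairs <- pairs[!duplicated(pairs[, c("e1", "looped_gene", "nearest_gene")]), ]
  d <- unname(ess[pairs$looped_gene] - ess[pairs$nearest_gene])
  d <- d[!is.na(d)]
  expect_equal(res$paired$ess$t, mean(d) / (sd(d) / sqrt(length(d))), tolerance = 1e-12)
  expect_equal(res$paired$ess$n_pairs, length(d))
  # identical pairs give t = 0
  sk0 <- pairs[1:3, ]
  sk0$nearest_gene <- sk0$looped_gene
  res0 <- expression_vs_treesize(tr, w$bundle$expression, sk0)
  expect_equal(res0$paired$ess$t, 0)
})
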