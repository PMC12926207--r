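# Independent brute-force oracles used across tests. These deliberately do
# not share code with the implementation they check.

# O(n^2) interval union by repeated pairwise merging (any overlap, bookended
# counts as overlapping at gap 0).
oracle_merge <- function(df, gap = 0L) {
  out <- do.call(rbind, lapply(split(df, df$chrom), function(x) {
    s <- x$start; e <- x$end
    alive <- rep(TRUE, length(s))
    repeat {
      changed <- FALSE
      for (i in which(alive)) {
        if (!alive[i]) next
        for (j in which(alive)) {
          if (i == j || !alive[j] || !alive[i]) next
          if (s[i] <= e[j] + gap && s[j] <= e[i] + gap) {
            s[i] <- min(s[i], s[j]); e[i] <- max(e[i], e[j])
            alive[j] <- FALSE
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    data.frame(chrom = x$chrom[1], start = s[alive], end = e[alive])
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# Shortest-path levels by adjacency-matrix powers: level(v) = smallest t with
# (A^t)[root, v] > 0, over the graph with blocked nodes deleted.
oracle_levels <- function(edges, root, nodes, blocked = character()) {
  keep <- setdiff(nodes, blocked)
  A <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  for (i in seq_len(nrow(edges))) {
    a <- edges$n1[i]; b <- edges$n2[i]
    if (a %in% keep && b %in% keep) { A[a, b] <- 1; A[b, a] <- 1 }
  }
  lev <- setNames(rep(NA_integer_, length(nodes)), nodes)
  lev[root] <- 0L
  reach <- A[root, , drop = TRUE]
  P <- A
  for (t in seq_len(length(keep))) {
    new <- names(which(P[root, ] > 0 & is.na(lev[keep])))
    lev[new] <- t
    P <- P %*% A
  }
  lev
}

# Union-find connected components over an edge list.
oracle_components <- function(vertices, pairs) {
  parent <- setNames(vertices, vertices)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(vertices, find, "")
}

# Exhaustive nearest-TSS scan.
oracle_nearest <- function(point, chrom, genes, min_d, max_d) {
  best <- NA_character_; bd <- Inf
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    d <- abs(genes$tss[i] - point)
    if (d < min_d || d > max_d) next
    if (d < bd || (d == bd && genes$gene_id[i] < best)) { bd <- d; best <- genes$gene_id[i] }
  }
  best
}

# Two-sample KS statistic as the sup difference of step CDFs.
oracle_ks_D <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# Mann-Whitney U by exhaustive pair comparison.
oracle_U <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
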