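#' Stratified cross-validation fold assignment
#'
#' @param y binary labels (logical/factor/0-1)
#' @param folds number of folds
#' @param seed integer seed
#' @return integer vector of fold ids in `1..folds`
#' @export
make_folds <- function(y, folds = 10L, seed = 1L) {
  y <- as.integer(as.factor(y))
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

# accuracy from held-out vote fractions; even-split ties go to the negative
# class, deterministically
acc_from_votes <- function(votes, y_pos) mean((votes > 0.5) == y_pos)

#' Train and evaluate a kNN classifier with cross-validation
#'
#' Predictors are standardised inside each training fold (the held-out fold
#' is scaled with the training folds' means and SDs), distances are
#' Euclidean, and the neighbour count k is chosen from `k_grid` by
#' cross-validated accuracy (ties toward the smallest k). Held-out class
#' probabilities are the fraction of the k neighbours in the positive class;
#' an even vote predicts the negative class.
#'
#' @param X numeric feature matrix (instances in rows)
#' @param y class labels; the positive class is `positive`
#' @param folds number of CV folds (default 10)
#' @param k_grid candidate neighbour counts (default odd 3..25)
#' @param seed seed for the fold assignment
#' @param positive label treated as the positive class (default `"focal"`)
#' @param model_kind descriptive tag carried in the result
#' @return object of class `epic_model`: list with `model_kind`, `k`,
#'   `cv_accuracy`, `prob` (held-out positive-class probability per
#'   instance), `acc_by_k`, `folds` (the assignment), `seed`
#' @export
train_and_evaluate <- function(X, y, folds = 10L, k_grid = seq(3L, 25L, 2L),
                               seed = 1L, positive = "focal",
                               model_kind = "tree_full") {
  X <- as.matrix(X)
  y_pos <- as.character(y) == positive
  if (sum(y_pos) < 2 || sum(!y_pos) < 2) stopf("need >= 2 instances per class")
  fold <- make_folds(y_pos, folds = folds, seed = seed)
  min_train <- nrow(X) - max(tabulate(fold))
  k_use <- k_grid[k_grid <= min_train]
  if (length(k_use) < length(k_grid))
    message(sprintf("train_and_evaluate: dropped %d k value(s) larger than the smallest training fold",
                    length(k_grid) - length(k_use)))
  if (!length(k_use)) stopf("no usable k in k_grid")
  votes <- knn_cv_votes_cpp(X, as.integer(y_pos), as.integer(fold),
                            as.integer(k_use))
  acc <- apply(votes, 2, acc_from_votes, y_pos = y_pos)
  best <- which.max(acc)   # first maximum = smallest k
  structure(list(model_kind = model_kind, k = k_use[best],
                 cv_accuracy = unname(acc[best]),
                 prob = votes[, best], acc_by_k = setNames(acc, k_use),
                 folds = fold, seed = seed),
            class = "epic_model")
}

#' @export
print.epic_model <- function(x, ...) {
  cat(sprintf("epic_model '%s': k = %d, CV accuracy = %.3f (n = %d)\n",
              x$model_kind, x$k, x$cv_accuracy, length(x$prob)))
  invisible(x)
}

# re-evaluate accuracy at a fixed k / fold assignment with one feature row
# swapped (the perturbation fast path)
cv_accuracy_swap <- function(X, y_pos, fold, k, swap_row = 0L, new_row = numeric()) {
  votes <- knn_cv_votes_swap_cpp(X, as.integer(y_pos), as.integer(fold),
                                 as.integer(k), as.integer(swap_row),
                                 as.numeric(new_row))
  acc_from_votes(votes, y_pos)
}

#' Promoter-accessibility baseline model
#'
#' Same training protocol as the tree model, over the 4 promoter-ATAC
#' predictors only.
#'
#' @inheritParams train_and_evaluate
#' @param gene_ids training genes (rows of the promoter feature matrix)
#' @param anchors classified consensus anchors
#' @param atac node accessibility table
#' @param cell_types cell-type labels
#' @return an `epic_model`
#' @export
baseline_promoter_only <- function(gene_ids, y, anchors, atac, cell_types,
                                   folds = 10L, k_grid = seq(3L, 25L, 2L),
                                   seed = 1L) {
  X <- promoter_features(gene_ids, anchors, atac, cell_types)
  train_and_evaluate(X, y, folds = folds, k_grid = k_grid, seed = seed,
                     model_kind = "promoter_only")
}

#' Linear regulatory-domain baseline model
#'
#' Same training protocol over the 4 distance-weighted enhancer-ATAC
#' predictors.
#'
#' @inheritParams baseline_promoter_only
#' @param genes gene table (TSS lookup)
#' @param window domain half-width in bp
#' @return an `epic_model`
#' @export
baseline_linear <- function(gene_ids, y, genes, anchors, atac, cell_types,
                            window = 1e6, folds = 10L,
                            k_grid = seq(3L, 25L, 2L), seed = 1L) {
  X <- linear_features(gene_ids, genes, anchors, atac, cell_types, window = window)
  train_and_evaluate(X, y, folds = folds, k_grid = k_grid, seed = seed,
                     model_kind = "linear")
}
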