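#' Subset-evaluation parameters
#'
#' @param K KNN neighbour count (default 10).
#' @param folds Cross-validation fold count (default 5: each fold is an
#'   80/20 train/test split).
#' @param seed RNG seed for the stratified fold shuffle.
#' @return An `eval_params` object.
#' @export
eval_params <- function(K = 10L, folds = 5L, seed = 1L) {
  if (K < 1L) abort_config("K must be >= 1")
  if (folds < 2L) abort_config("folds must be >= 2")
  structure(list(K = as.integer(K), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "eval_params")
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`, the characteristic function scored
#' for every candidate channel subset.
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return Accuracy in `[0, 1]`.
#' @export
confusion_accuracy <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) abort_config("confusion counts must be non-negative")
  if (sum(counts) == 0) abort_config("confusion counts sum to zero")
  (TP + TN) / sum(counts)
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin, so every fold is near-balanced.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      members <- which(labels == cls)
      members <- members[sample.int(length(members))]
      assign[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  assign
}

# Majority-vote KNN with deterministic ties: neighbour ties resolved by
# lower training index (stable order), vote ties toward class 0.
knn_predict <- function(train_x, train_y, test_x, K) {
  if (K >= nrow(train_x)) {
    abort_config("K = %d too large for %d training samples", K, nrow(train_x))
  }
  tr_sq <- rowSums(train_x^2)
  te_sq <- rowSums(test_x^2)
  d2 <- outer(te_sq, tr_sq, "+") - 2 * test_x %*% t(train_x)
  apply(d2, 1L, function(drow) {
    nn <- order(drow)[seq_len(K)]
    votes1 <- sum(train_y[nn] == 1L)
    if (votes1 * 2L > K) 1L else 0L
  })
}

#' Cross-validated KNN accuracy of a channel subset
#'
#' Restricts the feature matrix to the given channels' columns, runs
#' seeded stratified k-fold cross-validation, classifies each test sample
#' by majority vote of its `K` Euclidean-nearest training samples (columns
#' min-max scaled on the training fold), and pools the confusion counts of
#' all folds into one accuracy.
#'
#' @param fm A [feature_matrix()].
#' @param channel_subset Non-empty integer vector of channel indices.
#' @param ep An [eval_params()] object.
#' @return Accuracy in `[0, 1]`.
#' @export
knn_cv_accuracy <- function(fm, channel_subset, ep = eval_params()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(ep, "eval_params"))
  if (length(channel_subset) < 1L) abort_config("channel subset must be non-empty")
  if (!all(channel_subset %in% seq_along(fm$channels))) {
    abort_config("channel subset outside 1..%d", length(fm$channels))
  }
  X <- fm$values[, channel_columns(fm, channel_subset), drop = FALSE]
  y <- fm$labels
  fold_of <- stratified_folds(y, ep$folds, ep$seed)
  correct <- 0L
  for (f in seq_len(ep$folds)) {
    tr <- fold_of != f
    lo <- apply(X[tr, , drop = FALSE], 2L, min)
    rg <- apply(X[tr, , drop = FALSE], 2L, function(v) diff(range(v)))
    rg[rg == 0] <- 1
    scale_cols <- function(M) sweep(sweep(M, 2L, lo, "-"), 2L, rg, "/")
    pred <- knn_predict(scale_cols(X[tr, , drop = FALSE]), y[tr],
                        scale_cols(X[!tr, , drop = FALSE]), ep$K)
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}
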