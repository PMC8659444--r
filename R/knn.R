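#' K-nearest-neighbor configuration
#'
#' @param k Neighbor count (odd by default so binary votes rarely tie).
#' @param cv_folds Stratified cross-validation folds used when KNN accuracy
#'   serves as a selection fitness.
#' @return An object of class `knn_config`.
#' @export
knn_config <- function(k = 5, cv_folds = 5) {
  assert_scalar_num(k, "k", min = 1)
  assert_scalar_num(cv_folds, "cv_folds", min = 2)
  structure(list(k = as.integer(k), cv_folds = as.integer(cv_folds)),
            class = "knn_config")
}

#' Deterministic k-nearest-neighbor classification
#'
#' Majority vote among the `k` Euclidean-nearest training points, with fully
#' specified tie rules: equal distances are broken in favor of the lower
#' training index, and a tied vote falls to the class of the single nearest
#' neighbor. With these rules predictions are a pure function of the inputs.
#'
#' @param train_X,test_X Numeric feature matrices with matching columns.
#' @param train_y Training labels (factor or character).
#' @param cfg A [knn_config()]; `cfg$k` must not exceed `nrow(train_X)`.
#' @return Factor of predicted labels, levels those of `train_y`.
#' @export
knn_classify <- function(train_X, train_y, test_X, cfg = knn_config()) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  if (ncol(train_X) != ncol(test_X))
    stop(sprintf("feature dimension mismatch: train %d vs test %d",
                 ncol(train_X), ncol(test_X)))
  n_train <- nrow(train_X)
  if (cfg$k > n_train)
    stop(sprintf("k = %d exceeds the %d training samples", cfg$k, n_train))
  train_y <- as.factor(train_y)
  stopifnot(length(train_y) == n_train)
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(test_X^2), rowSums(train_X^2), `+`) -
    2 * tcrossprod(test_X, train_X)
  lv <- levels(train_y)
  yi <- as.integer(train_y)
  pred <- integer(nrow(test_X))
  for (i in seq_len(nrow(test_X))) {
    # order() with the index as a secondary key: distance ties -> lower index
    nb <- order(d2[i, ], seq_len(n_train))[seq_len(cfg$k)]
    votes <- tabulate(yi[nb], nbins = length(lv))
    top <- which(votes == max(votes))
    pred[i] <- if (length(top) == 1L) top else yi[nb[1L]]
  }
  factor(lv[pred], levels = lv)
}
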