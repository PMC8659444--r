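#' SVM training specification
#'
#' Three optimization variants are supported, all built on the same
#' soft-margin dual (libsvm, via e1071): `"lm"` solves the dual once at fixed
#' hyperparameters (the Lagrange-multiplier baseline: cost 1, RBF width
#' `1/n_features`); `"evolutionary"` and `"pso"` search the
#' `(log2 cost, log2 gamma)` plane with a small evolution strategy or a
#' particle swarm, scoring each candidate by stratified cross-validation
#' accuracy on the training partition. Both searches seed the fixed-default
#' point into their initial population, so their final CV score can never
#' fall below the baseline's.
#'
#' @param optimizer One of `"lm"`, `"evolutionary"`, `"pso"`.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param log2_cost_range,log2_gamma_range Search bounds (log2 scale).
#' @param n_evals Candidate evaluations for the searching variants
#'   (default 30).
#' @param cv_folds Stratified CV folds used to score candidates (default 5).
#' @param seed Integer seed for the search and fold assignment.
#' @return An object of class `svm_spec`.
#' @export
svm_spec <- function(optimizer = c("lm", "evolutionary", "pso"),
                     kernel = c("radial", "linear"),
                     log2_cost_range = c(-5, 15),
                     log2_gamma_range = c(-15, 3),
                     n_evals = 30, cv_folds = 5, seed = 1) {
  optimizer <- match.arg(optimizer)
  kernel <- match.arg(kernel)
  stopifnot(length(log2_cost_range) == 2L, length(log2_gamma_range) == 2L,
            diff(log2_cost_range) > 0, diff(log2_gamma_range) > 0)
  assert_scalar_num(n_evals, "n_evals", min = 1)
  assert_scalar_num(cv_folds, "cv_folds", min = 2)
  structure(list(optimizer = optimizer, kernel = kernel,
                 log2_cost_range = log2_cost_range,
                 log2_gamma_range = log2_gamma_range,
                 n_evals = as.integer(n_evals), cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)), class = "svm_spec")
}

svm_fit_raw <- function(X, y, kernel, cost, gamma) {
  e1071::svm(x = X, y = y, type = "C-classification", kernel = kernel,
             cost = cost, gamma = gamma, scale = FALSE)
}

# stratified-CV accuracy of an (cost, gamma) candidate on standardized X
svm_cv_score <- function(X, y, kernel, cost, gamma, folds) {
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
    fit <- svm_fit_raw(X[tr, , drop = FALSE], y[tr], kernel, cost, gamma)
    mean(stats::predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Train an SVM under one optimization variant
#'
#' Features are standardized with the training mean/SD; the transform is part
#' of the fitted model and is re-applied at prediction time.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param spec An [svm_spec()].
#' @return An object of class `pe_svm` with elements `model`, `center`,
#'   `scale`, `cost`, `gamma`, `cv_score` (stratified CV accuracy of the
#'   adopted hyperparameters on the training partition), and `spec`.
#' @export
train_svm <- function(X, y, spec = svm_spec()) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("SVM training needs both classes present")
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sd_, `/`)
  default <- c(cost = 0, gamma = log2(1 / ncol(X)))  # log2 scale
  with_seed(spec$seed, {
    folds <- stratified_folds(y, spec$cv_folds)
    choice <- switch(spec$optimizer,
      lm = default,
      evolutionary = search_es(Z, y, spec, folds, default),
      pso = search_pso(Z, y, spec, folds, default))
    cost <- 2^choice[[1]]
    gamma <- 2^choice[[2]]
    cv <- svm_cv_score(Z, y, spec$kernel, cost, gamma, folds)
    model <- svm_fit_raw(Z, y, spec$kernel, cost, gamma)
    structure(list(model = model, center = mu, scale = sd_, cost = cost,
                   gamma = gamma, cv_score = cv, spec = spec),
              class = "pe_svm")
  })
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# (mu + lambda) evolution strategy on the log2 hyperparameter plane
search_es <- function(Z, y, spec, folds, default) {
  lo <- c(spec$log2_cost_range[1], spec$log2_gamma_range[1])
  hi <- c(spec$log2_cost_range[2], spec$log2_gamma_range[2])
  n_pop <- 6L
  score <- function(p) svm_cv_score(Z, y, spec$kernel, 2^p[1], 2^p[2], folds)
  pop <- lapply(seq_len(n_pop - 1L), function(i) stats::runif(2, lo, hi))
  pop <- c(list(clamp(default, lo, hi)), pop)
  fits <- vapply(pop, score, numeric(1))
  used <- n_pop
  sigma <- (hi - lo) / 6
  while (used < spec$n_evals) {
    parent <- pop[[sample.int(n_pop, 1L, prob = rank(fits))]]
    child <- clamp(parent + stats::rnorm(2, sd = sigma), lo, hi)
    f <- score(child)
    used <- used + 1L
    worst <- which.min(fits)
    if (f > fits[worst]) { pop[[worst]] <- child; fits[worst] <- f }
    sigma <- sigma * 0.95
  }
  pop[[which.max(fits)]]
}

# canonical global-best particle swarm on the same plane
search_pso <- function(Z, y, spec, folds, default) {
  lo <- c(spec$log2_cost_range[1], spec$log2_gamma_range[1])
  hi <- c(spec$log2_cost_range[2], spec$log2_gamma_range[2])
  n_part <- 6L
  score <- function(p) svm_cv_score(Z, y, spec$kernel, 2^p[1], 2^p[2], folds)
  pos <- lapply(seq_len(n_part - 1L), function(i) stats::runif(2, lo, hi))
  pos <- c(list(clamp(default, lo, hi)), pos)
  vel <- lapply(seq_len(n_part), function(i) stats::runif(2, -1, 1) * (hi - lo) / 10)
  fits <- vapply(pos, score, numeric(1))
  pbest <- pos; pbest_f <- fits
  g <- which.max(fits)
  gbest <- pos[[g]]; gbest_f <- fits[g]
  used <- n_part
  w <- 0.7; c1 <- 1.5; c2 <- 1.5
  while (used < spec$n_evals) {
    for (i in seq_len(n_part)) {
      if (used >= spec$n_evals) break
      vel[[i]] <- w * vel[[i]] +
        c1 * stats::runif(2) * (pbest[[i]] - pos[[i]]) +
        c2 * stats::runif(2) * (gbest - pos[[i]])
      pos[[i]] <- clamp(pos[[i]] + vel[[i]], lo, hi)
      f <- score(pos[[i]])
      used <- used + 1L
      if (f > pbest_f[i]) { pbest[[i]] <- pos[[i]]; pbest_f[i] <- f }
      if (f > gbest_f) { gbest <- pos[[i]]; gbest_f <- f }
    }
  }
  gbest
}

#' @export
predict.pe_svm <- function(object, newdata, ...) {
  Z <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L, object$scale, `/`)
  stats::predict(object$model, Z)
}

#' @export
print.pe_svm <- function(x, ...) {
  cat(sprintf("<pe_svm %s/%s: cost %.4g, gamma %.4g, CV accuracy %.4f>\n",
              x$spec$optimizer, x$spec$kernel, x$cost, x$gamma, x$cv_score))
  invisible(x)
}

# ---- evaluation metrics ----------------------------------------------------

#' Confusion quadrants for pre-ictal vs normal classification
#'
#' Quadrant layout: I = true pre-ictal predicted pre-ictal, II = normal
#' predicted pre-ictal, III = pre-ictal predicted normal, IV = normal
#' predicted normal.
#'
#' @param predictions,truths Vectors of `"preictal"` / `"normal"` labels.
#' @return An object of class `confusion_counts` (named integer vector
#'   I, II, III, IV).
#' @export
confusion_counts <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length")
  p <- as.character(predictions); t <- as.character(truths)
  ok <- c("preictal", "normal")
  if (!all(p %in% ok) || !all(t %in% ok))
    stop("labels must be 'preictal' or 'normal'")
  out <- c(I = sum(p == "preictal" & t == "preictal"),
           II = sum(p == "preictal" & t == "normal"),
           III = sum(p == "normal" & t == "preictal"),
           IV = sum(p == "normal" & t == "normal"))
  structure(as.integer(out), names = names(out), class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion quadrants
#'
#' Accuracy = (I + IV) / total, sensitivity = I / (I + III),
#' specificity = IV / (II + IV), all as percentages. A metric whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param counts A [confusion_counts()] (or named vector with I, II, III, IV).
#' @return Named numeric: `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
metrics_from_counts <- function(counts) {
  q <- as.numeric(counts[c("I", "II", "III", "IV")])
  if (anyNA(q)) stop("counts must carry quadrants I, II, III, IV")
  total <- sum(q)
  if (total == 0) stop("empty confusion counts")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(accuracy = ratio(q[1] + q[4], total),
    sensitivity = ratio(q[1], q[1] + q[3]),
    specificity = ratio(q[4], q[2] + q[4]))
}

#' Event-level seizure prediction rate
#'
#' A test seizure counts as predicted when its horizon windows trigger an
#' alarm: under rule `"any"` (default) at least one window classified
#' pre-ictal suffices; under `"majority"` more than half must be. The rate is
#' the percentage of test seizures flagged.
#'
#' @param per_seizure_predictions Named list: one vector of predicted labels
#'   per test seizure (names are seizure indices).
#' @param rule `"any"` or `"majority"`.
#' @return List with `rate` (percent) and `flags` (named logical per seizure).
#' @export
prediction_rate <- function(per_seizure_predictions,
                            rule = c("any", "majority")) {
  rule <- match.arg(rule)
  if (!length(per_seizure_predictions))
    stop("no test seizures: prediction rate undefined")
  flags <- vapply(per_seizure_predictions, function(p) {
    hits <- sum(as.character(p) == "preictal")
    if (rule == "any") hits >= 1L else hits > length(p) / 2
  }, logical(1))
  list(rate = 100 * mean(flags), flags = flags)
}

#' Train, adopt and evaluate SVM variants on a channel subset
#'
#' Restricts the feature matrices to `channels`, trains one SVM per spec in
#' `specs`, adopts the variant with the highest training-partition CV
#' accuracy (never by test performance), evaluates it once on the test
#' partition, and reports window-level metrics plus the event-level
#' prediction rate.
#'
#' @param train,test Feature sets as returned by [pe_feature_matrix()]
#'   (lists with `X`, `y`, `info`).
#' @param channels Integer channel indices to use, a [run_knn_ga()]
#'   `selection_result`, or `NULL` for all channels.
#' @param specs List of [svm_spec()]s (default: the three variants with a
#'   shared seed).
#' @param event_rule Passed to [prediction_rate()].
#' @return An object of class `evaluation_report`: confusion counts, the
#'   three window metrics, `prediction_rate`, per-seizure flags, adopted
#'   optimizer, hyperparameters, CV score, channels used.
#' @export
run_validation <- function(train, test, channels = NULL, specs = NULL,
                           event_rule = c("any", "majority")) {
  event_rule <- match.arg(event_rule)
  if (inherits(channels, "selection_result"))
    channels <- channels$selected_channels
  if (is.null(channels)) channels <- seq_len(ncol(train$X))
  if (is.null(specs))
    specs <- lapply(c("lm", "evolutionary", "pso"), svm_spec)
  if (inherits(specs, "svm_spec")) specs <- list(specs)
  Xtr <- train$X[, channels, drop = FALSE]
  Xte <- test$X[, channels, drop = FALSE]
  fits <- lapply(specs, function(s) train_svm(Xtr, train$y, s))
  scores <- vapply(fits, function(f) f$cv_score, numeric(1))
  best <- fits[[which.max(scores)]]
  pred <- predict(best, Xte)
  cc <- confusion_counts(pred, test$y)
  metrics <- metrics_from_counts(cc)
  pre_idx <- which(test$info$label == "preictal")
  pr <- if (length(pre_idx)) {
    by_seiz <- split(as.character(pred[pre_idx]),
                     test$info$seizure_index[pre_idx])
    prediction_rate(by_seiz, event_rule)
  } else list(rate = NA_real_, flags = logical(0))
  structure(list(counts = cc, accuracy = metrics[["accuracy"]],
                 sensitivity = metrics[["sensitivity"]],
                 specificity = metrics[["specificity"]],
                 prediction_rate = pr$rate, per_seizure_flags = pr$flags,
                 optimizer = best$spec$optimizer, cost = best$cost,
                 gamma = best$gamma, cv_score = best$cv_score,
                 channels = channels, event_rule = event_rule),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d channel(s), optimizer %s>\n",
              length(x$channels), x$optimizer))
  cat(sprintf("  counts I=%d II=%d III=%d IV=%d\n",
              x$counts[["I"]], x$counts[["II"]], x$counts[["III"]],
              x$counts[["IV"]]))
  cat(sprintf(
    "  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  prediction rate %.2f%%\n",
    x$accuracy, x$sensitivity, x$specificity, x$prediction_rate))
  invisible(x)
}
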