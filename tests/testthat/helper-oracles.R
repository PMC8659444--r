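# Independent oracles and small fixture builders used across test files.
# These deliberately avoid the package's internals: the PE oracle enumerates
# patterns with order(), the KNN oracle sorts full distance vectors per test
# point, applying the same published tie rules by explicit bookkeeping.

# permutation entropy by direct enumeration of delay vectors
naive_pe <- function(x, m = 3, tau = 1, normalize = TRUE) {
  n_vec <- length(x) - (m - 1) * tau
  keys <- vapply(seq_len(n_vec), function(t) {
    v <- x[t + (0:(m - 1)) * tau]
    paste(order(v) - 1L, collapse = "-")  # order() is stable: ties by position
  }, "")
  p <- as.numeric(table(keys)) / n_vec
  pe <- -sum(p * log2(p))
  if (normalize) pe / log2(factorial(m)) else pe
}

# ordinal pattern counts keyed by the sorted-position sequence
naive_ordinal_counts <- function(x, m = 3, tau = 1) {
  n_vec <- length(x) - (m - 1) * tau
  keys <- vapply(seq_len(n_vec), function(t) {
    v <- x[t + (0:(m - 1)) * tau]
    paste(order(v) - 1L, collapse = "-")
  }, "")
  table(keys)
}

# lexicographic index of a sorted-position sequence, for comparing the two
# representations
lex_index_of_positions <- function(p) {
  m <- length(p)
  idx <- 0
  for (i in seq_len(m - 1)) {
    idx <- idx + sum(p[(i + 1):m] < p[i]) * factorial(m - i)
  }
  idx
}

# brute-force KNN with the stated tie rules
naive_knn <- function(train_X, train_y, test_X, k) {
  train_y <- as.factor(train_y)
  lv <- levels(train_y)
  out <- character(nrow(test_X))
  for (i in seq_len(nrow(test_X))) {
    d <- apply(train_X, 1, function(r) sum((r - test_X[i, ])^2))
    ord <- order(d, seq_along(d))  # distance, then training index
    nb <- ord[seq_len(k)]
    tab <- table(factor(train_y[nb], levels = lv))
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1) top else as.character(train_y[nb[1]])
  }
  factor(out, levels = lv)
}

# two well-separated Gaussian clouds
separable_data <- function(n_per_class = 30, d = 2, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
               matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
    y <- factor(rep(c("preictal", "normal"), each = n_per_class),
                levels = c("preictal", "normal"))
    list(X = X, y = y)
  })
}

# small synthetic window sets for selector/classifier tests
small_spec <- function(n_channels = 6, informative = c(2, 5), seed = 7,
                       regularity = 0.8) {
  synthetic_cohort_spec(n_channels = n_channels, fs = 256,
                        informative_channels = informative,
                        preictal_regularity = regularity, seed = seed)
}

# a labeled recording at reduced rate/size, cheap enough for unit tests
small_recording <- function(n_channels = 2, fs = 32, hours = 3,
                            onsets = c(2700, 7600), seed = 3) {
  withr::with_seed(seed, {
    n <- round(hours * 3600 * fs)
    eeg_recording(matrix(rnorm(n_channels * n), nrow = n_channels), fs = fs,
                  seizure_onsets = onsets,
                  montage = channel_montage(sprintf("S%02d", 1:n_channels)),
                  patient_id = "fixture")
  })
}
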