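#' Permutation entropy configuration
#'
#' Bandt-Pompe ordinal analysis parameters: embedding order `m` (patterns are
#' the `m!` rank orderings of `m`-point delay vectors), embedding delay `tau`
#' in samples, and whether the entropy is normalized by `log2(m!)` so that
#' white noise scores near 1 and a monotone ramp scores 0.
#'
#' @param m Embedding order (>= 2). With 2.8-s windows at 256 Hz (717
#'   samples), `m = 3` gives > 100 vectors per possible pattern.
#' @param tau Embedding delay in samples (>= 1).
#' @param normalize Divide by `log2(m!)`? Default `TRUE`.
#' @return An object of class `pe_config`.
#' @export
pe_config <- function(m = 3, tau = 1, normalize = TRUE) {
  assert_scalar_num(m, "m", min = 2)
  assert_scalar_num(tau, "tau", min = 1)
  if (m != round(m) || tau != round(tau)) stop("`m` and `tau` must be integers")
  structure(list(m = as.integer(m), tau = as.integer(tau),
                 normalize = isTRUE(normalize)), class = "pe_config")
}

#' Lexicographic index of the ordinal pattern of one vector
#'
#' The ordinal pattern of `v` is the permutation of positions that sorts `v`
#' ascending, with ties broken by order of appearance (the earlier position
#' ranks lower). Patterns are indexed lexicographically over position
#' sequences, so the identity pattern (already-sorted input) has index 0 and
#' indices run over `[0, m!)`.
#'
#' @param v Numeric vector of length `m`.
#' @return Integer pattern index in `[0, factorial(m))`.
#' @examples
#' ordinal_pattern_index(c(1, 2, 3))  # 0: identity
#' ordinal_pattern_index(c(9, 10, 6)) # sorted positions (3, 1, 2)
#' @export
ordinal_pattern_index <- function(v) {
  m <- length(v)
  if (m < 2L) stop("pattern vectors need length >= 2")
  idx <- ordinal_indices(matrix(v, nrow = 1L))
  as.integer(idx)
}

# Vectorized ordinal pattern indices for an N x m embedding matrix.
# Stable ranks via pairwise comparisons (O(m^2) vector ops), then the Lehmer
# code of the sorting permutation in the factorial number system.
ordinal_indices <- function(V) {
  n <- nrow(V)
  m <- ncol(V)
  # r[, j] = stable rank of element j (0-based): count of elements strictly
  # smaller, plus equal elements appearing earlier
  r <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (k == j) next
      if (k < j) r[, j] <- r[, j] + (V[, k] <= V[, j])
      else       r[, j] <- r[, j] + (V[, k] <  V[, j])
    }
  }
  # p[, i] = position (0-based) holding rank i-1, i.e. the sorting permutation
  p <- matrix(0L, n, m)
  for (j in seq_len(m)) p[cbind(seq_len(n), r[, j] + 1L)] <- j - 1L
  # Lehmer code: idx = sum_i c_i * (m - i)!, c_i = #{j > i : p_j < p_i}
  idx <- integer(n)
  fact <- factorial(m - seq_len(m))
  for (i in seq_len(m - 1L)) {
    c_i <- integer(n)
    for (j in (i + 1L):m) c_i <- c_i + (p[, j] < p[, i])
    idx <- idx + c_i * fact[i]
  }
  idx
}

delay_embed <- function(x, m, tau) {
  n_vec <- length(x) - (m - 1L) * tau
  if (n_vec < 1L)
    stop(sprintf("series of length %d too short for m = %d, tau = %d",
                 length(x), m, tau))
  V <- matrix(0, n_vec, m)
  for (j in seq_len(m)) V[, j] <- x[seq_len(n_vec) + (j - 1L) * tau]
  V
}

#' Ordinal pattern distribution of a time series
#'
#' Counts the ordinal pattern of every overlapping delay vector
#' `x[t], x[t + tau], ..., x[t + (m-1) tau]` of the series.
#'
#' @param x Numeric series.
#' @param cfg A [pe_config()].
#' @return An object of class `ordinal_distribution`: list with `m`, `tau`,
#'   `counts` (length `m!`, lexicographic pattern order), `n_vectors`.
#' @export
ordinal_distribution <- function(x, cfg = pe_config()) {
  V <- delay_embed(as.numeric(x), cfg$m, cfg$tau)
  nfact <- factorial(cfg$m)
  if (nfact * 10 > nrow(V))
    warning(sprintf("only %d vectors for %d patterns; PE will be biased low",
                    nrow(V), nfact))
  counts <- tabulate(ordinal_indices(V) + 1L, nbins = nfact)
  structure(list(m = cfg$m, tau = cfg$tau, counts = counts,
                 n_vectors = nrow(V)), class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("<ordinal_distribution m=%d tau=%d: %d vectors over %d patterns>\n",
              x$m, x$tau, x$n_vectors, length(x$counts)))
  print(stats::setNames(x$counts, seq_along(x$counts) - 1L))
  invisible(x)
}

#' Permutation entropy of a time series
#'
#' Shannon entropy (base 2) of the ordinal pattern distribution:
#' `PE = -sum(p_i * log2(p_i))` over observed patterns, with probabilities
#' `p_i = counts_i / n_vectors`. Zero-count patterns contribute nothing
#' (`0 * log 0 := 0`). Low PE means a regular, deterministic series; the
#' normalized value approaches 1 for white noise. Because PE is rank-based it
#' is exactly invariant under strictly monotone transforms of the signal.
#'
#' @inheritParams ordinal_distribution
#' @return PE in bits, or in `[0, 1]` when `cfg$normalize` is `TRUE`.
#' @examples
#' permutation_entropy(1:100)                   # 0: a monotone ramp
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3),
#'                     pe_config(normalize = FALSE)) # 1.5219 bits
#' @export
permutation_entropy <- function(x, cfg = pe_config()) {
  if (inherits(x, "ordinal_distribution")) d <- x
  else d <- ordinal_distribution(x, cfg)
  p <- d$counts[d$counts > 0] / d$n_vectors
  pe <- -sum(p * log2(p))
  if (cfg$normalize) pe <- pe / log2(factorial(d$m))
  pe
}

#' Per-window, per-channel permutation entropy feature matrix
#'
#' The feature representation consumed by the channel selector and the
#' classifier: one row per window, one column per montage channel, each cell
#' the PE of that window on that channel.
#'
#' @param windows A [window_set()] with homogeneous shapes.
#' @param cfg A [pe_config()].
#' @return List with `X` (`n_windows x n_channels` matrix, columns
#'   `ch01, ch02, ...`), `y` (factor with levels `preictal`, `normal`), and
#'   `info` (the window provenance data.frame).
#' @export
pe_feature_matrix <- function(windows, cfg = pe_config()) {
  if (!length(windows)) stop("empty window set")
  n_ch <- nrow(windows$data[[1]])
  w <- ncol(windows$data[[1]])
  norm <- if (cfg$normalize) log2(factorial(cfg$m)) else 1
  nfact <- factorial(cfg$m)
  X <- matrix(NA_real_, length(windows), n_ch,
              dimnames = list(NULL, sprintf("ch%02d", seq_len(n_ch))))
  for (i in seq_along(windows$data)) {
    win <- windows$data[[i]]
    # embed all channels at once: stack per-channel embeddings row-wise
    for (ch in seq_len(n_ch)) {
      V <- delay_embed(win[ch, ], cfg$m, cfg$tau)
      counts <- tabulate(ordinal_indices(V) + 1L, nbins = nfact)
      p <- counts[counts > 0] / nrow(V)
      X[i, ch] <- -sum(p * log2(p)) / norm
    }
  }
  y <- factor(windows$info$label, levels = c("preictal", "normal"))
  list(X = X, y = y, info = windows$info)
}
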