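# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}

# Stratified fold assignment: integer fold id per observation, each class
# spread as evenly as possible across folds. Deterministic given the RNG state.
stratified_folds <- function(y, n_folds) {
  y <- as.factor(y)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
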