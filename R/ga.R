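#' Genetic-algorithm configuration for channel-mask search
#'
#' The search space is the set of binary channel masks ("chromosomes", one
#' gene per channel, at least one gene on). Each generation: fitness
#' evaluation, elitist carry-over of the fittest, fitness-proportionate
#' parent choice for the bred fraction of slots, uniform crossover, and
#' per-gene mutation. The run stops when the best fitness has not changed for
#' `convergence_window` generations or at `max_generations`.
#'
#' @param pop_size Population size (default 20).
#' @param max_generations Generation cap (default 30).
#' @param crossover_prob Probability a bred child undergoes uniform crossover
#'   (default 1.0; otherwise it clones one parent).
#' @param mutation_rate Per-gene flip probability (default 0.01).
#' @param reproductive_fraction Fraction of each new population bred via
#'   selection + crossover (default 0.9); the remaining slots are copied from
#'   the current fittest chromosomes, so elitism of at least one is implied.
#' @param convergence_window Generations of unchanged best fitness that stop
#'   the run early (default 5).
#' @param seed Integer seed governing every random draw of the run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 20, max_generations = 30,
                      crossover_prob = 1.0, mutation_rate = 0.01,
                      reproductive_fraction = 0.9, convergence_window = 5,
                      seed = 1) {
  assert_scalar_num(pop_size, "pop_size", min = 2)
  assert_scalar_num(max_generations, "max_generations", min = 1)
  assert_scalar_num(crossover_prob, "crossover_prob", min = 0, max = 1)
  assert_scalar_num(mutation_rate, "mutation_rate", min = 0, max = 1)
  assert_scalar_num(reproductive_fraction, "reproductive_fraction",
                    min = 0, max = 1)
  assert_scalar_num(convergence_window, "convergence_window", min = 1)
  structure(list(pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 crossover_prob = crossover_prob,
                 mutation_rate = mutation_rate,
                 reproductive_fraction = reproductive_fraction,
                 convergence_window = as.integer(convergence_window),
                 seed = as.integer(seed)), class = "ga_config")
}

validate_chromosome <- function(genes) {
  genes <- as.integer(genes)
  if (!length(genes) || !all(genes %in% c(0L, 1L)))
    stop("a chromosome is a binary gene vector")
  if (sum(genes) < 1L) stop("a chromosome must keep at least one gene on")
  genes
}

# repair an all-zero mask: switch one uniformly chosen gene on
repair_chromosome <- function(genes) {
  if (sum(genes) < 1L) genes[sample.int(length(genes), 1L)] <- 1L
  genes
}

#' Fitness-proportionate selection probabilities
#'
#' `p_i = f_i / sum(f)`. If every fitness is zero the distribution falls back
#' to uniform (with a warning) so selection remains defined.
#'
#' @param fitnesses Non-negative numeric vector.
#' @return Probability vector summing to 1.
#' @export
selection_probabilities <- function(fitnesses) {
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  s <- sum(fitnesses)
  if (s <= 0) {
    warning("all fitnesses are zero; falling back to uniform selection")
    return(rep(1 / length(fitnesses), length(fitnesses)))
  }
  fitnesses / s
}

#' Uniform crossover of two channel masks
#'
#' Each locus is copied from either parent with probability 1/2; an all-zero
#' child is repaired by switching one uniformly chosen gene on.
#'
#' @param a,b Binary gene vectors of equal length.
#' @return A binary gene vector.
#' @export
uniform_crossover <- function(a, b) {
  a <- validate_chromosome(a); b <- validate_chromosome(b)
  if (length(a) != length(b)) stop("parent chromosomes differ in length")
  from_a <- stats::runif(length(a)) < 0.5
  repair_chromosome(ifelse(from_a, a, b))
}

#' Per-gene mutation of a channel mask
#'
#' Flips each gene independently with probability `rate`; an all-zero result
#' is repaired by switching one uniformly chosen gene on.
#'
#' @param genes Binary gene vector.
#' @param rate Per-gene flip probability in `[0, 1]`.
#' @return A binary gene vector.
#' @export
mutate_genes <- function(genes, rate = 0.01) {
  genes <- validate_chromosome(genes)
  assert_scalar_num(rate, "rate", min = 0, max = 1)
  flip <- stats::runif(length(genes)) < rate
  repair_chromosome(as.integer(xor(genes, flip)))
}

#' Cross-validated KNN fitness of a channel mask
#'
#' Mean stratified cross-validation accuracy of KNN restricted to the on-gene
#' feature columns. Features are standardized with the training-fold mean/SD
#' inside each fold. Fold assignment is drawn from `seed` unless a fixed
#' `folds` vector is supplied (a GA run fixes one assignment so chromosomes
#' compete on identical folds).
#'
#' @param genes Binary gene vector (one per feature column).
#' @param X Feature matrix (`n x n_channels`), e.g. from
#'   [pe_feature_matrix()].
#' @param y Binary labels.
#' @param knn_cfg A [knn_config()].
#' @param seed Integer seed for the fold assignment.
#' @param folds Optional integer fold id per row, overriding `seed`.
#' @return Accuracy in `[0, 1]`.
#' @export
chromosome_fitness <- function(genes, X, y, knn_cfg = knn_config(),
                               seed = NULL, folds = NULL) {
  genes <- validate_chromosome(genes)
  if (length(genes) != ncol(X))
    stop("chromosome length must equal the number of feature columns")
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("fitness needs both classes present")
  if (is.null(folds))
    folds <- with_seed(seed, stratified_folds(y, knn_cfg$cv_folds))
  Xs <- X[, genes == 1L, drop = FALSE]
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    mu <- colMeans(Xs[tr, , drop = FALSE])
    sd_ <- apply(Xs[tr, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    Ztr <- sweep(sweep(Xs[tr, , drop = FALSE], 2L, mu), 2L, sd_, `/`)
    Zte <- sweep(sweep(Xs[!tr, , drop = FALSE], 2L, mu), 2L, sd_, `/`)
    pred <- knn_classify(Ztr, y[tr], Zte, knn_cfg)
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs)
}

#' Select channels with the KNN-fitness genetic algorithm
#'
#' Wrapper feature selection over channel masks: the initial population draws
#' each gene on with probability 1/2 (repaired to at least one on-gene); each
#' generation evaluates cross-validated KNN accuracy as fitness, copies the
#' elite into the non-bred slots, picks parents fitness-proportionately for
#' the bred slots, applies uniform crossover and per-gene mutation. Fitness
#' values are memoized per mask (identical masks share identical folds, hence
#' identical fitness).
#'
#' @param X Feature matrix (`n x n_channels`).
#' @param y Binary labels.
#' @param ga_cfg A [ga_config()].
#' @param knn_cfg A [knn_config()].
#' @param restarts Independent GA runs; the best-fitness result is returned
#'   (default 1).
#' @return An object of class `selection_result`: `best` (gene vector),
#'   `selected_channels` (1-based indices), `fitness` (best fitness),
#'   `fitness_history` (best-so-far per generation), `generations_run`,
#'   `ga_cfg`, `knn_cfg`, `seed`.
#' @export
run_knn_ga <- function(X, y, ga_cfg = ga_config(), knn_cfg = knn_config(),
                       restarts = 1) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("need both classes to select channels")
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- with_seed(ga_cfg$seed + (r - 1L),
                     run_knn_ga_once(X, y, ga_cfg, knn_cfg))
    if (is.null(best) || res$fitness > best$fitness) best <- res
  }
  best$seed <- ga_cfg$seed
  best
}

run_knn_ga_once <- function(X, y, ga_cfg, knn_cfg) {
  n_genes <- ncol(X)
  folds <- stratified_folds(y, knn_cfg$cv_folds)
  cache <- new.env(parent = emptyenv())
  fit1 <- function(genes) {
    key <- paste(genes, collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- chromosome_fitness(genes, X, y, knn_cfg, folds = folds)
    cache[[key]] <- val
    val
  }
  pop <- lapply(seq_len(ga_cfg$pop_size), function(i)
    repair_chromosome(as.integer(stats::runif(n_genes) < 0.5)))

  n_breed <- round(ga_cfg$reproductive_fraction * ga_cfg$pop_size)
  n_elite <- ga_cfg$pop_size - n_breed
  history <- numeric(0)
  best_genes <- NULL
  best_fit <- -Inf
  stalled <- 0L
  gen <- 0L
  while (gen < ga_cfg$max_generations) {
    gen <- gen + 1L
    fits <- vapply(pop, fit1, numeric(1))
    top <- order(fits, decreasing = TRUE)
    if (fits[top[1L]] > best_fit + 1e-12) {
      best_fit <- fits[top[1L]]
      best_genes <- pop[[top[1L]]]
      stalled <- 0L
    } else stalled <- stalled + 1L
    history <- c(history, best_fit)
    if (stalled >= ga_cfg$convergence_window) break
    if (gen >= ga_cfg$max_generations) break
    probs <- selection_probabilities(fits)
    breed <- lapply(seq_len(n_breed), function(i) {
      parents <- sample.int(length(pop), 2L, replace = TRUE, prob = probs)
      child <- if (stats::runif(1) < ga_cfg$crossover_prob)
        uniform_crossover(pop[[parents[1L]]], pop[[parents[2L]]])
      else pop[[parents[1L]]]
      mutate_genes(child, ga_cfg$mutation_rate)
    })
    elite <- pop[top[seq_len(max(1L, n_elite))]]
    pop <- c(elite[seq_len(max(1L, n_elite))], breed)[seq_len(ga_cfg$pop_size)]
  }
  structure(list(best = best_genes,
                 selected_channels = which(best_genes == 1L),
                 fitness = best_fit, fitness_history = history,
                 generations_run = gen, ga_cfg = ga_cfg, knn_cfg = knn_cfg,
                 seed = ga_cfg$seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result: %d/%d channels {%s}, fitness %.4f after %d generation(s)>\n",
    length(x$selected_channels), length(x$best),
    paste(x$selected_channels, collapse = ","), x$fitness, x$generations_run))
  invisible(x)
}
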