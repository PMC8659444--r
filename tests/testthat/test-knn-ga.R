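test_that("KNN honors zero-distance, degenerate-k and error contracts", {
  d <- separable_data(10, seed = 2)
  # a test point identical to a training point, k = 1 -> that point's label
  pred <- knn_classify(d$X, d$y, d$X[3, , drop = FALSE], knn_config(k = 1))
  expect_identical(as.character(pred), as.character(d$y[3]))
  # k = |train| -> the global majority class everywhere (here: tie -> nearest)
  unbal <- list(X = d$X[1:15, ], y = droplevels(d$y[1:15]))
  pred2 <- knn_classify(unbal$X, unbal$y, d$X[1:4, ],
                        knn_config(k = 15))
  expect_true(all(pred2 == "preictal"))  # 10 of 15 training points
  expect_error(knn_classify(d$X, d$y, d$X, knn_config(k = 100)), "exceeds")
  expect_error(knn_classify(d$X, d$y, d$X[, 1, drop = FALSE]), "mismatch")
})

test_that("KNN ties break deterministically by index then nearest class", {
  # two training points at identical distance from the origin
  X <- rbind(c(1, 0), c(-1, 0), c(3, 3))
  y <- factor(c("preictal", "normal", "normal"),
              levels = c("preictal", "normal"))
  p <- knn_classify(X, y, rbind(c(0, 0)), knn_config(k = 1))
  expect_identical(as.character(p), "preictal")  # lower training index wins
  # k = 2 vote tie -> class of the single nearest neighbor
  p2 <- knn_classify(X, y, rbind(c(0.5, 0)), knn_config(k = 2))
  expect_identical(as.character(p2), "preictal")
})

test_that("KNN predictions equal the brute-force oracle", {
  withr::with_seed(77, {
    for (trial in 1:30) {
      n <- sample(10:40, 1)
      d <- sample(2:5, 1)
      Xtr <- matrix(rnorm(n * d), ncol = d)
      ytr <- factor(sample(c("preictal", "normal"), n, replace = TRUE),
                    levels = c("preictal", "normal"))
      if (nlevels(droplevels(ytr)) < 2) next
      Xte <- matrix(rnorm(8 * d), ncol = d)
      for (k in c(1, 3, 5)) {
        if (k > n) next
        expect_identical(knn_classify(Xtr, ytr, Xte, knn_config(k = k)),
                         naive_knn(Xtr, ytr, Xte, k))
      }
    }
  })
})

test_that("chromosome fitness is CV accuracy on the on-gene columns", {
  d <- separable_data(40, d = 1, gap = 8, seed = 5)
  X <- cbind(d$X, matrix(rnorm(80 * 3), ncol = 3))  # 1 signal + 3 noise cols
  fit <- chromosome_fitness(c(1, 0, 0, 0), X, d$y, knn_config(), seed = 1)
  expect_gte(fit, 0.95)
  # permuted labels, balanced classes -> chance-level fitness
  yperm <- withr::with_seed(8, sample(d$y))
  fit0 <- chromosome_fitness(c(1, 1, 1, 1), X, yperm, knn_config(), seed = 1)
  expect_lt(abs(fit0 - 0.5), 3 * sqrt(0.25 / 80) + 0.05)
  expect_error(chromosome_fitness(c(0, 0, 0, 0), X, d$y), "at least one")
  expect_error(chromosome_fitness(c(1, 0), X, d$y), "length")
  expect_error(chromosome_fitness(c(1, 1, 1, 1), X, factor(rep("a", 80))),
               "both classes")
  # deterministic given the seed
  expect_identical(fit, chromosome_fitness(c(1, 0, 0, 0), X, d$y,
                                           knn_config(), seed = 1))
})

test_that("selection probabilities are fitness-proportionate", {
  expect_equal(selection_probabilities(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(selection_probabilities(c(3, 1)), c(0.75, 0.25))
  withr::with_seed(3, {
    for (i in 1:10) {
      f <- runif(8)
      p <- selection_probabilities(f)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(p, f / sum(f))
    }
  })
  expect_error(selection_probabilities(c(-1, 2)), "non-negative")
  expect_warning(p0 <- selection_probabilities(c(0, 0)), "uniform")
  expect_equal(p0, c(0.5, 0.5))
})

test_that("uniform crossover copies each locus from one of the parents", {
  a <- c(1, 1, 0, 0, 1, 0, 1, 0)
  b <- c(0, 1, 1, 0, 0, 1, 1, 0)
  withr::with_seed(12, {
    for (i in 1:50) {
      child <- uniform_crossover(a, b)
      expect_true(all(child == a | child == b))
      expect_gte(sum(child), 1)
    }
  })
  # identical parents -> identical child
  expect_identical(withr::with_seed(1, uniform_crossover(a, a)), as.integer(a))
  # seeded determinism
  expect_identical(withr::with_seed(4, uniform_crossover(a, b)),
                   withr::with_seed(4, uniform_crossover(a, b)))
  expect_error(uniform_crossover(a, b[1:3]), "length")
})

test_that("mutation flips per gene and repairs all-zero masks", {
  g <- c(1, 0, 1, 1, 0)
  expect_identical(withr::with_seed(1, mutate_genes(g, 0)), as.integer(g))
  # rate 1 on a mask with both values flips every gene (complement survives)
  expect_identical(withr::with_seed(1, mutate_genes(g, 1)),
                   as.integer(1 - g))
  # a single-gene chromosome whose gene flips off is repaired to >= 1 gene
  res <- withr::with_seed(2, mutate_genes(c(0, 1, 0), 1))
  expect_gte(sum(res), 1)
  one <- withr::with_seed(3, mutate_genes(c(1), 1))
  expect_identical(one, 1L)
})

test_that("the GA recovers planted channels and respects its invariants", {
  ws <- generate_window_set(small_spec(seed = 61), 60)
  feat <- pe_feature_matrix(ws)
  res <- run_knn_ga(feat$X, feat$y, ga_config(seed = 61), knn_config())
  expect_lte(res$generations_run, 30)
  expect_true(all(diff(res$fitness_history) >= 0))
  expect_identical(res$selected_channels, which(res$best == 1L))
  expect_gte(sum(res$best), 1)
  # planted channels 2 and 5 dominate the fitness landscape here
  expect_true(all(c(2, 5) %in% res$selected_channels))
  # determinism: same seed, same result
  res2 <- run_knn_ga(feat$X, feat$y, ga_config(seed = 61), knn_config())
  expect_identical(res$best, res2$best)
  expect_identical(res$fitness, res2$fitness)
})

test_that("a GA with no variation operators is a population fixed point", {
  d <- separable_data(20, d = 3, seed = 9)
  cfg <- ga_config(pop_size = 6, max_generations = 10, crossover_prob = 0,
                   mutation_rate = 0, reproductive_fraction = 0,
                   convergence_window = 3, seed = 5)
  res <- run_knn_ga(d$X, d$y, cfg, knn_config(k = 3, cv_folds = 4))
  # best fitness can never move: the run stalls out at the convergence window
  expect_identical(res$generations_run, cfg$convergence_window + 1L)
  expect_true(all(res$fitness_history == res$fitness_history[1]))
})

test_that("restarts return the best result across independent runs", {
  ws <- generate_window_set(small_spec(seed = 71), 40)
  feat <- pe_feature_matrix(ws)
  single <- run_knn_ga(feat$X, feat$y,
                       ga_config(seed = 71, max_generations = 5))
  multi <- run_knn_ga(feat$X, feat$y,
                      ga_config(seed = 71, max_generations = 5), restarts = 3)
  expect_gte(multi$fitness, single$fitness)
})
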