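test_that("Russell mapping reproduces the published class bookkeeping", {
  emotions <- rep(c("relaxed", "happy", "sad", "angry"), c(43, 21, 18, 14))
  val <- map_labels(emotions, "valence")
  expect_equal(as.vector(val$counts), c(32, 64))
  aro <- map_labels(emotions, "arousal")
  expect_equal(as.vector(aro$counts), c(61, 35))
  four <- map_labels(emotions, "four_class")
  expect_equal(as.vector(four$counts), c(43, 21, 18, 14))
  expect_error(map_labels(c("relaxed", "bored"), "valence"), "unknown emotion")

  lab <- emotion_label("angry")
  expect_equal(lab$valence, "low")
  expect_equal(lab$arousal, "high")
})

test_that("the SMO classifier reproduces a reference SVM's predictions", {
  # frozen oracle: scikit-learn SVC predictions on this exact dataset
  # (C = 2, gamma = 0.5 balanced and unbalanced agree here)
  set.seed(7)
  n <- 40
  x <- rbind(matrix(rnorm(n * 2, -1, 1), ncol = 2),
             matrix(rnorm(n * 2, 1, 1), ncol = 2))
  y <- factor(rep(c("a", "b"), each = n))
  expected <- paste0(
    "baaaaaaaabaaaaaaaaaaaaaaaaaaaaaaaaaaaaab",
    "abbbbbbbabbbbbbbbbbbabbbbabbbbbbbbbbabbb")
  for (cw in list(NULL, "balanced")) {
    fit <- svm_fit(x, y, cost = 2, gamma = 0.5, class_weight = cw)
    expect_equal(paste(predict(fit, x), collapse = ""), expected)
  }

  # imbalanced two-class problem, balanced weighting (C = 4, gamma = 0.3)
  set.seed(8)
  xi <- rbind(matrix(rnorm(60 * 2, -0.5, 1), ncol = 2),
              matrix(rnorm(12 * 2, 0.8, 1), ncol = 2))
  yi <- factor(rep(c("a", "b"), c(60, 12)))
  fit <- svm_fit(xi, yi, cost = 4, gamma = 0.3, class_weight = "balanced")
  expect_equal(paste(predict(fit, xi), collapse = ""), paste0(
    "aaaaaaaaaaaaaaaaaabaaaaabaabaaaaaabaaaaa",
    "aaaaaaaaaaaaaaaaaaaaaabbbbbbbbbb"))
})

test_that("cv_fitness separates the separable and not the permuted", {
  tc <- make_two_class(n_per = 30, sep = 3, seed = 10)
  expect_gte(cv_fitness(tc$x, tc$y, seed = 1), 0.95)

  # permutation null: accuracy near the majority rate
  set.seed(11)
  yperm <- sample(tc$y)
  accs <- vapply(1:5, function(s) cv_fitness(tc$x, yperm, seed = s), numeric(1))
  p0 <- max(table(tc$y)) / length(tc$y)
  se <- sqrt(p0 * (1 - p0) / length(tc$y))
  expect_lt(abs(mean(accs) - p0), 3 * se + 0.05)

  expect_equal(suppressWarnings(
    cv_fitness(tc$x, tc$y, mask = rep(FALSE, 2))), 0)
  expect_warning(cv_fitness(tc$x, tc$y, mask = rep(FALSE, 2)), "empty")
})

test_that("standardization uses training folds only (no leakage)", {
  # scaling parameters must come from the training split alone: training
  # rows standardize to exactly zero mean, test rows in general do not
  tc <- make_two_class(n_per = 25, sep = 1, seed = 12)
  sc <- pcgemotion:::scale_train_test(tc$x[1:30, ], tc$x[31:50, ])
  expect_equal(unname(colMeans(sc$tr)), c(0, 0), tolerance = 1e-12)
  expect_false(all(abs(colMeans(sc$te)) < 1e-12))
  expect_equal(unname(apply(sc$tr, 2, sd)), c(1, 1), tolerance = 1e-12)

  # and signal-free data stays at chance: were test-fold statistics (or
  # labels) reaching the training side, accuracy would drift upward
  null <- make_two_class(n_per = 25, sep = 0, seed = 13)
  accs <- vapply(1:5, function(s) cv_fitness(null$x, null$y, seed = s),
                 numeric(1))
  expect_lt(mean(accs), 0.5 + 3 * sqrt(0.25 / 50))
})

test_that("stratified folds are deterministic and balanced", {
  y <- factor(rep(c("a", "b"), c(40, 10)))
  f1 <- pcgemotion:::stratified_folds(y, 5, 42)
  f2 <- pcgemotion:::stratified_folds(y, 5, 42)
  expect_identical(f1, f2)
  tab <- table(fold = f1, y)
  expect_true(all(tab[, "a"] == 8))
  expect_true(all(tab[, "b"] == 2))
})

test_that("ga_select recovers planted informative features", {
  set.seed(20)
  n <- 60; D <- 30
  x <- matrix(rnorm(n * D), n)
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "b", 4] <- x[y == "b", 4] + 2.5
  x[y == "b", 17] <- x[y == "b", 17] - 2.5
  run <- ga_select(x, y, ga_config(pop = 16L, generations = 10L, folds = 3L),
                   seed = 1)
  expect_s3_class(run, "ga_run")
  expect_true(all(run$best_mask[c(4, 17)]))
  expect_true(all(diff(run$fitness_trace$best) >= 0))
  expect_equal(run$best_fitness, max(run$fitness_trace$best))
})

test_that("minimal GA configurations work and degenerate ones are rejected", {
  tc <- make_two_class(n_per = 10, sep = 2, d = 3, seed = 30)
  run <- ga_select(tc$x, tc$y, ga_config(pop = 2L, generations = 1L,
                                         folds = 2L), seed = 2)
  expect_length(run$fitness_trace$best, 1L)
  expect_length(run$best_mask, 3L)
  expect_error(ga_config(pop = 1L), "population")
  expect_error(ga_config(generations = 0L), "generation")
})

test_that("aggregate_selection retains the top 20% and weights by frequency", {
  mk_run <- function(fit, mask) {
    structure(list(best_mask = mask, best_fitness = fit,
                   fitness_trace = data.frame(generation = 1, best = fit,
                                              mean = fit),
                   seed = 0L), class = "ga_run")
  }
  D <- 6
  masks <- lapply(1:30, function(i) {
    m <- rep(FALSE, D); m[(i %% D) + 1] <- TRUE; m[1] <- TRUE; m
  })
  fits <- seq(0.5, 0.99, length.out = 30)
  runs <- Map(mk_run, fits, masks)
  agg <- aggregate_selection(runs, weight_threshold = 0.5)
  expect_length(agg$retained, 6L)          # ceil(0.2 * 30)
  expect_true(all(fits[agg$retained] >= sort(fits, decreasing = TRUE)[6]))
  expect_equal(agg$weight[1], 1.0)          # feature 1 in every retained mask
  expect_true(agg$optimal_mask[1])

  # identical masks: weight equals the mask
  same <- lapply(1:30, function(i) mk_run(0.9, c(TRUE, FALSE, TRUE,
                                                 FALSE, FALSE, FALSE)))
  agg2 <- aggregate_selection(same)
  expect_equal(agg2$weight, c(1, 0, 1, 0, 0, 0))
  expect_equal(agg2$optimal_mask, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_error(aggregate_selection(same[1:3]), "at least 5")
})

test_that("tune_cg is an exhaustive deterministic argmax", {
  tc <- make_two_class(n_per = 15, sep = 3, seed = 40)
  tv <- tune_cg(tc$x, tc$y, log2c = c(-1, 3, 7), log2g = c(-7, -3, 1),
                folds = 3, seed = 5)
  expect_equal(nrow(tv$curve), 9L)
  expect_equal(tv$accuracy, max(tv$curve$accuracy))
  expect_true(tv$accuracy >= tv$curve$accuracy[1])
  tv2 <- tune_cg(tc$x, tc$y, log2c = c(-1, 3, 7), log2g = c(-7, -3, 1),
                 folds = 3, seed = 5)
  expect_identical(tv[c("c", "g", "accuracy")], tv2[c("c", "g", "accuracy")])
})

test_that("classification reports follow confusion-matrix arithmetic", {
  truth <- factor(rep(c("low", "high"), c(32, 64)), levels = c("low", "high"))
  perfect <- classification_report(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  allpos <- classification_report(truth, factor(rep("high", 96),
                                                levels = c("low", "high")))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 64 / 96, tolerance = 1e-9)

  # row sums of the confusion matrix are the class counts
  set.seed(50)
  pred <- sample(truth)
  rep3 <- classification_report(truth, pred)
  expect_equal(as.vector(rowSums(rep3$confusion)), c(32, 64))

  # single-class truth: binary metrics undefined
  rep4 <- classification_report(factor(rep("high", 5), c("low", "high")),
                                factor(rep("high", 5), c("low", "high")))
  expect_true(is.na(rep4$specificity))
})

test_that("evaluate_model wires a fitted model to the report", {
  tc <- make_two_class(n_per = 20, sep = 3, seed = 60)
  fit <- svm_fit(scale(tc$x), tc$y, cost = 4, gamma = 0.5)
  rep <- evaluate_model(scale(tc$x), tc$y, fit)
  expect_gte(rep$accuracy, 0.95)
  expect_equal(sum(rep$confusion), 40)
})
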