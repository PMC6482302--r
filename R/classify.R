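# GA-wrapped feature selection over an RBF-kernel support-vector
# classifier, with stratified 5-fold cross-validation and the Russell
# circumplex label mappings.

EMOTIONS <- c("relaxed", "happy", "sad", "angry")

#' Emotion label with Russell-circumplex projections
#'
#' Valence: low for sad and angry, high for relaxed and happy.
#' Arousal: low for relaxed and sad, high for happy and angry.
#'
#' @param emotion one of `"relaxed"`, `"happy"`, `"sad"`, `"angry"`.
#' @return list of class `emotion_label` with `emotion`, `valence`, `arousal`.
#' @export
emotion_label <- function(emotion) {
  if (!emotion %in% EMOTIONS)
    stop_pcg("unknown emotion '%s'", as.character(emotion))
  structure(list(
    emotion = emotion,
    valence = if (emotion %in% c("sad", "angry")) "low" else "high",
    arousal = if (emotion %in% c("relaxed", "sad")) "low" else "high"
  ), class = "emotion_label")
}

#' Map emotion labels onto a classification task
#'
#' @param emotions character vector of emotion names.
#' @param task `"valence"`, `"arousal"` or `"four_class"`.
#' @return list with `classes` (factor: `low`/`high` for the binary tasks,
#'   the four emotions otherwise) and `counts` (table).
#' @export
map_labels <- function(emotions, task = c("valence", "arousal", "four_class")) {
  task <- match.arg(task)
  labs <- lapply(as.character(emotions), emotion_label)
  cls <- switch(task,
    valence = factor(vapply(labs, `[[`, "", "valence"), c("low", "high")),
    arousal = factor(vapply(labs, `[[`, "", "arousal"), c("low", "high")),
    four_class = factor(vapply(labs, `[[`, "", "emotion"), EMOTIONS)
  )
  list(classes = cls, counts = table(cls))
}

# --- Support-vector classifier (RBF kernel, SMO) ----------------------------

#' Fit an RBF-kernel support-vector classifier
#'
#' Binary problems are solved directly by sequential minimal optimisation;
#' multiclass problems by one-vs-one voting (ties broken in favour of the
#' earlier factor level). `class_weight = "balanced"` scales each class's
#' box constraint by `n / (k * n_c)`, countering class imbalance.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y factor of class labels.
#' @param cost soft-margin penalty `C > 0`.
#' @param gamma RBF kernel width; default `1 / ncol(x)`.
#' @param class_weight `"balanced"` or `NULL` (uniform).
#' @return model object of class `pcg_svm`.
#' @export
svm_fit <- function(x, y, cost = 1, gamma = NULL,
                    class_weight = "balanced") {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop_pcg("x and y sizes disagree")
  if (cost <= 0) stop_pcg("cost must be > 0")
  lev <- levels(y)
  if (length(lev) < 2L) stop_pcg("need at least 2 classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)

  fit_pair <- function(xi, yi) {
    # yi in {-1, +1}
    cw <- rep(cost, length(yi))
    if (identical(class_weight, "balanced")) {
      n <- length(yi)
      for (s in c(-1, 1)) cw[yi == s] <- cost * n / (2 * sum(yi == s))
    }
    res <- smo_train_cpp(xi, yi, cw, gamma, 1e-3, 20000L)
    sv <- which(res$alpha > 1e-8)
    list(xsv = xi[sv, , drop = FALSE],
         coef = res$alpha[sv] * yi[sv], b = res$b)
  }

  pairs <- utils::combn(seq_along(lev), 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    sel <- y %in% lev[pr]
    yi <- ifelse(y[sel] == lev[pr[1]], 1, -1)
    c(fit_pair(x[sel, , drop = FALSE], yi), list(pos = pr[1], neg = pr[2]))
  })
  structure(list(levels = lev, gamma = gamma, cost = cost, fits = fits),
            class = "pcg_svm")
}

#' Predict classes with a fitted support-vector classifier
#'
#' @param object a `pcg_svm` model.
#' @param newdata numeric matrix of samples to classify.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.pcg_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  k <- length(object$levels)
  votes <- matrix(0L, nrow(newdata), k)
  for (f in object$fits) {
    dec <- if (nrow(f$xsv) == 0L) rep(f$b, nrow(newdata))
           else smo_decision_cpp(f$xsv, f$coef, f$b, object$gamma, newdata)
    pos <- ifelse(dec >= 0, f$pos, f$neg)
    for (r in seq_len(nrow(newdata)))
      votes[r, pos[r]] <- votes[r, pos[r]] + 1L
  }
  factor(object$levels[apply(votes, 1, which.max)], levels = object$levels)
}

# --- Cross-validation -------------------------------------------------------

# Deterministic stratified k-fold assignment.
stratified_folds <- function(classes, k, seed) {
  classes <- as.factor(classes)
  fold <- integer(length(classes))
  with_seed(seed, {
    for (lv in levels(classes)) {
      idx <- which(classes == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

scale_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(tr = sweep(sweep(xtr, 2, mu), 2, sdv, "/"),
       te = sweep(sweep(xte, 2, mu), 2, sdv, "/"))
}

#' Cross-validated accuracy of a masked feature subset
#'
#' Pooled accuracy of the RBF support-vector classifier over stratified
#' folds. Standardization (centering/scaling) is computed on each training
#' fold only and applied to its test fold, so no test information leaks
#' into training. An empty mask scores 0 (penalized, with a warning).
#'
#' @param x feature matrix.
#' @param classes factor of class labels.
#' @param mask logical vector selecting feature columns; `NULL` = all.
#' @param cost,gamma classifier hyperparameters; `gamma = NULL` uses
#'   `1 / n_selected`.
#' @param folds number of folds (>= 2).
#' @param seed integer seed controlling fold assignment.
#' @return accuracy in `[0, 1]`.
#' @export
cv_fitness <- function(x, classes, mask = NULL, cost = 4, gamma = NULL,
                       folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  classes <- droplevels(as.factor(classes))
  if (folds < 2L) stop_pcg("folds must be >= 2")
  if (is.null(mask)) mask <- rep(TRUE, ncol(x))
  if (!any(mask)) {
    warning("empty feature mask: fitness 0", call. = FALSE)
    return(0)
  }
  xs <- x[, mask, drop = FALSE]
  fold <- stratified_folds(classes, folds, seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    te <- fold == f
    if (!any(te)) next
    if (length(unique(classes[!te])) < 2L) next
    sc <- scale_train_test(xs[!te, , drop = FALSE], xs[te, , drop = FALSE])
    fit <- svm_fit(sc$tr, classes[!te], cost = cost, gamma = gamma)
    pred <- predict(fit, sc$te)
    correct <- correct + sum(as.character(pred) == as.character(classes[te]))
  }
  correct / length(classes)
}

# --- Genetic-algorithm wrapper selection ------------------------------------

#' GA configuration for wrapper feature selection
#'
#' Conventional wrapper-selection defaults: population 30, 50 generations,
#' uniform crossover with probability 0.7, per-bit mutation `1/D`,
#' tournament selection of size 3, elitism 1.
#'
#' @param pop population size (>= 2).
#' @param generations number of generations (>= 1).
#' @param p_crossover crossover probability.
#' @param p_mutation per-bit mutation probability; `NULL` = `1/D`.
#' @param tournament tournament size.
#' @param elitism number of elite individuals copied unchanged.
#' @param cost,gamma classifier hyperparameters used inside the fitness.
#' @param folds CV folds of the fitness.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(pop = 30L, generations = 50L, p_crossover = 0.7,
                      p_mutation = NULL, tournament = 3L, elitism = 1L,
                      cost = 4, gamma = NULL, folds = 5L) {
  if (pop < 2L) stop_pcg("GA population must be >= 2")
  if (generations < 1L) stop_pcg("GA needs >= 1 generation")
  structure(list(pop = as.integer(pop), generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 tournament = as.integer(tournament),
                 elitism = as.integer(elitism),
                 cost = cost, gamma = gamma, folds = as.integer(folds)),
            class = "ga_config")
}

#' Genetic-algorithm feature selection (binary masks, SVM-CV fitness)
#'
#' Evolves binary feature masks whose fitness is the cross-validated
#' accuracy of the RBF support-vector classifier on the masked matrix.
#' Elitism makes the best-fitness trace non-decreasing.
#'
#' @param x feature matrix (`D >= 2` columns).
#' @param classes factor of class labels.
#' @param config a [ga_config()].
#' @param seed integer seed; the whole run is deterministic given it.
#' @return list of class `ga_run`: `best_mask`, `best_fitness`,
#'   `fitness_trace` (data frame with per-generation `best` and `mean`),
#'   `seed`.
#' @export
ga_select <- function(x, classes, config = ga_config(), seed = 1L) {
  x <- as.matrix(x)
  D <- ncol(x)
  if (D < 2L) stop_pcg("need at least 2 features for selection")
  pmut <- config$p_mutation %||% (1 / D)
  cache <- new.env(parent = emptyenv())
  fit_of <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- if (!any(mask)) 0 else
      cv_fitness(x, classes, mask, cost = config$cost, gamma = config$gamma,
                 folds = config$folds, seed = seed)
    cache[[key]] <- val
    val
  }
  with_seed(seed, {
    pop <- lapply(seq_len(config$pop), function(i) runif(D) < 0.5)
    fitness <- vapply(pop, fit_of, numeric(1))
    trace_best <- numeric(config$generations)
    trace_mean <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fitness, decreasing = TRUE)
      elite <- pop[ord[seq_len(config$elitism)]]
      tourn <- function() {
        cand <- sample.int(config$pop, config$tournament, replace = TRUE)
        pop[[cand[which.max(fitness[cand])]]]
      }
      children <- list()
      while (length(children) < config$pop - config$elitism) {
        p1 <- tourn(); p2 <- tourn()
        if (runif(1) < config$p_crossover) {
          swap <- runif(D) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (ch in list(c1, c2)) {
          flip <- runif(D) < pmut
          children[[length(children) + 1L]] <- xor(ch, flip)
        }
      }
      pop <- c(elite, children[seq_len(config$pop - config$elitism)])
      fitness <- vapply(pop, fit_of, numeric(1))
      trace_best[g] <- max(fitness)
      trace_mean[g] <- mean(fitness)
    }
    best <- which.max(fitness)
    structure(list(best_mask = pop[[best]], best_fitness = fitness[best],
                   fitness_trace = data.frame(generation = seq_len(config$generations),
                                              best = trace_best,
                                              mean = trace_mean),
                   seed = seed),
              class = "ga_run")
  })
}

#' Aggregate repeated GA runs into a consensus feature subset
#'
#' Runs whose best fitness ranks in the top 20% (ties broken by run order)
#' are retained; each feature's weight is its selection frequency among the
#' retained runs; the optimal subset keeps features with weight at or above
#' `weight_threshold`. If that subset is empty, the single best run's mask
#' is used instead (with a message).
#'
#' @param runs list of `ga_run` objects (>= 5).
#' @param weight_threshold minimal selection frequency, in `[0, 1]`.
#' @return list of class `selection_aggregate`: `retained` (indices),
#'   `weight` (numeric vector in `[0,1]^D`), `optimal_mask`, `runs`.
#' @export
aggregate_selection <- function(runs, weight_threshold = 0.5) {
  if (length(runs) < 5L) stop_pcg("need at least 5 GA runs to aggregate")
  fits <- vapply(runs, `[[`, numeric(1), "best_fitness")
  n_keep <- ceiling(0.2 * length(runs))
  retained <- order(fits, decreasing = TRUE)[seq_len(n_keep)]
  masks <- do.call(rbind, lapply(runs[retained], function(r)
    as.integer(r$best_mask)))
  weight <- colMeans(masks)
  optimal <- weight >= weight_threshold
  if (!any(optimal)) {
    message("consensus subset empty; falling back to the best run's mask")
    optimal <- runs[[retained[1]]]$best_mask
  }
  structure(list(retained = retained, weight = weight,
                 optimal_mask = optimal, runs = runs),
            class = "selection_aggregate")
}

#' Grid search for SVM penalty and kernel width
#'
#' Exhaustive search over `log2(c)` in `[-5, 15]` step 2 and `log2(g)` in
#' `[-15, 3]` step 2 (overridable), maximizing stratified CV accuracy on
#' the selected feature subset. Ties resolve to the first grid point in
#' row-major (c-major) order, so results are deterministic.
#'
#' @param x feature matrix.
#' @param classes factor of class labels.
#' @param mask logical feature mask (`NULL` = all features).
#' @param log2c,log2g grid vectors of exponents.
#' @param folds CV folds.
#' @param seed integer seed for fold assignment.
#' @return list with `c`, `g`, `accuracy` and `curve` (data frame over the
#'   full grid).
#' @export
tune_cg <- function(x, classes, mask = NULL,
                    log2c = seq(-5, 15, by = 2), log2g = seq(-15, 3, by = 2),
                    folds = 5L, seed = 1L) {
  if (!is.null(mask) && !any(mask)) stop_pcg("mask selects no features")
  grid <- expand.grid(log2c = log2c, log2g = log2g, KEEP.OUT.ATTRS = FALSE)
  acc <- vapply(seq_len(nrow(grid)), function(i)
    cv_fitness(x, classes, mask, cost = 2^grid$log2c[i],
               gamma = 2^grid$log2g[i], folds = folds, seed = seed),
    numeric(1))
  best <- which.max(acc)
  list(c = 2^grid$log2c[best], g = 2^grid$log2g[best], accuracy = acc[best],
       curve = cbind(grid, accuracy = acc))
}

# --- Evaluation -------------------------------------------------------------

#' Confusion-matrix metrics from truth and prediction vectors
#'
#' For binary tasks the positive class is `"high"` (valence/arousal).
#' Sensitivity is the recall of the positive class, specificity the recall
#' of the negative class; both are `NA` when their class is absent.
#'
#' @param truth factor of true classes.
#' @param pred factor of predicted classes.
#' @param positive positive class for binary metrics.
#' @return list with `accuracy`, `per_class_recall`, `sensitivity`,
#'   `specificity`, `macro_recall`, `confusion`.
#' @export
classification_report <- function(truth, pred, positive = "high") {
  truth <- as.factor(truth)
  pred <- factor(as.character(pred), levels = levels(truth))
  cm <- table(truth = truth, pred = pred)
  acc <- sum(diag(cm)) / sum(cm)
  recall <- vapply(levels(truth), function(lv) {
    n <- sum(cm[lv, ])
    if (n == 0) NA_real_ else cm[lv, lv] / n
  }, numeric(1))
  sens <- spec <- NA_real_
  if (length(levels(truth)) == 2L && positive %in% levels(truth)) {
    negative <- setdiff(levels(truth), positive)
    sens <- recall[[positive]]
    spec <- recall[[negative]]
  }
  list(accuracy = acc, per_class_recall = recall,
       sensitivity = sens, specificity = spec,
       macro_recall = mean(recall, na.rm = TRUE), confusion = cm)
}

#' Evaluate a fitted model on a feature matrix
#'
#' @param x feature matrix (already on the scale the model was fit on).
#' @param classes factor of true classes.
#' @param model a fitted `pcg_svm`.
#' @param positive positive class for binary metrics.
#' @return a [classification_report()].
#' @export
evaluate_model <- function(x, classes, model, positive = "high") {
  stopifnot(inherits(model, "pcg_svm"))
  classification_report(classes, predict(model, x), positive)
}
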