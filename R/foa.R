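#' Fossa Optimization Algorithm configuration
#'
#' Wrapper feature selection with a population metaheuristic modeled on a
#' fossa hunting lemurs: an exploration ("attack") phase that moves members
#' toward strictly better members, and an exploitation ("chase") phase of
#' random steps whose magnitude shrinks with the iteration counter.
#' Positions are continuous in `[lower, upper]` per dimension and binarized
#' at `threshold` into a feature subset; fitness (minimized) is
#' `(1 - accuracy) + subset_penalty * |subset| / i`, where accuracy comes
#' from a small k-nearest-neighbor classifier under stratified
#' cross-validation (or on an explicit validation set).
#'
#' @param dimensions number of features `i`.
#' @param population population size `R` (>= 2; default 20).
#' @param iterations iteration count `T` (default 50).
#' @param lower,upper per-dimension bounds (defaults 0 and 1).
#' @param subset_penalty penalty weight `alpha` (>= 0; 0 reproduces the pure
#'   maximum-accuracy objective).
#' @param threshold binarization threshold (default 0.5).
#' @param knn_k inner k-NN neighbor count.
#' @param cv_folds stratified CV fold count.
#' @param seed integer seed.
#' @return A `foa_config` list.
#' @export
foa_config <- function(dimensions, population = 20L, iterations = 50L,
                       lower = 0, upper = 1, subset_penalty = 0.01,
                       threshold = 0.5, knn_k = 3L, cv_folds = 3L,
                       seed = 1L) {
  stopifnot(population >= 2, iterations >= 0, subset_penalty >= 0,
            dimensions >= 1, threshold > 0, threshold < 1)
  lower <- rep_len(lower, dimensions)
  upper <- rep_len(upper, dimensions)
  if (any(lower >= upper)) stop("foa_config: need lower < upper")
  structure(list(dimensions = as.integer(dimensions),
                 population = as.integer(population),
                 iterations = as.integer(iterations),
                 lower = lower, upper = upper,
                 subset_penalty = subset_penalty, threshold = threshold,
                 knn_k = as.integer(knn_k), cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "foa_config")
}

#' Binarize a continuous position into a feature subset
#'
#' Indices with position `>= threshold` are selected; an empty result is
#' repaired by force-including the feature with the largest position value.
#'
#' @param position numeric position vector.
#' @param threshold binarization threshold.
#' @return Integer vector of selected indices (never empty).
#' @export
position_subset <- function(position, threshold = 0.5) {
  idx <- which(position >= threshold)
  if (!length(idx)) idx <- which.max(position)
  idx
}

#' Wrapper fitness of a candidate feature subset
#'
#' Minimized objective `(1 - acc) + alpha * |subset| / i`. Accuracy is
#' estimated by a k-NN classifier: stratified `cv_folds`-fold
#' cross-validation on `(table, labels)` when no validation set is given,
#' otherwise fit on `(table, labels)` and score on the validation pair
#' (used by the pipeline so test data never drive selection).
#'
#' @param position continuous position vector (one value per feature).
#' @param table numeric feature matrix (rows = samples).
#' @param labels integer/factor class labels (>= 2 classes).
#' @param config a [foa_config()].
#' @param folds optional precomputed fold assignment (for determinism across
#'   repeated evaluations).
#' @param val_table,val_labels optional validation pair replacing CV.
#' @return Scalar fitness (smaller is better).
#' @export
foa_fitness <- function(position, table, labels, config,
                        folds = NULL, val_table = NULL, val_labels = NULL) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2) stop("foa_fitness: single-class labels")
  sub <- position_subset(position, config$threshold)
  acc <- if (is.null(val_table)) {
    if (is.null(folds)) folds <- stratified_folds(labels, config$cv_folds,
                                                  config$seed)
    knn_cv_accuracy(table[, sub, drop = FALSE], labels, folds, config$knn_k)
  } else {
    mean(knn_predict(table[, sub, drop = FALSE], labels,
                     val_table[, sub, drop = FALSE], config$knn_k)
         == as.integer(as.factor(val_labels)))
  }
  (1 - acc) + config$subset_penalty * length(sub) / config$dimensions
}

#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Vectorized k-NN prediction: majority vote among the k nearest training
# rows (Euclidean); vote ties broken by the nearest member of the tied
# classes. Neighbors found by k successive max.col passes (no per-row sort).
knn_predict <- function(train, labels, test, k) {
  k <- min(k, nrow(train))
  nte <- nrow(test)
  d2 <- matrix(rowSums(test^2), nte, nrow(train)) +
    matrix(rowSums(train^2), nte, nrow(train), byrow = TRUE) -
    2 * tcrossprod(test, train)
  classes <- sort(unique(labels))
  cnt <- matrix(0L, nte, length(classes))
  fp <- matrix(k + 1L, nte, length(classes))   # first occurrence position
  neg <- -d2
  for (j in seq_len(k)) {
    nn <- max.col(neg, ties.method = "first")
    neg[cbind(seq_len(nte), nn)] <- -Inf
    ci <- match(labels[nn], classes)
    ii <- cbind(seq_len(nte), ci)
    cnt[ii] <- cnt[ii] + 1L
    fp[ii] <- pmin(fp[ii], j)
  }
  # majority count dominates; nearer first occurrence breaks ties
  classes[max.col(cnt * (k + 2L) - fp, ties.method = "first")]
}

knn_cv_accuracy <- function(x, labels, folds, k) {
  correct <- 0L
  for (f in unique(folds)) {
    te <- folds == f
    if (!any(te) || all(te)) next
    pred <- knn_predict(x[!te, , drop = FALSE], labels[!te],
                        x[te, , drop = FALSE], k)
    correct <- correct + sum(pred == labels[te])
  }
  correct / length(labels)
}

#' Initialize a fossa population
#'
#' Positions `s[m, D] = lower_D + a * (upper_D - lower_D)` with
#' `a ~ Uniform(0, 1)` per entry; fitness is evaluated for every member.
#'
#' @param config a [foa_config()].
#' @param fitness_fn function(position) -> scalar fitness.
#' @return A `fossa_population` list: `positions` (R x i), `fitness`,
#'   `best_position`, `best_fitness`, `history`.
#' @export
foa_init <- function(config, fitness_fn) {
  R <- config$population; i <- config$dimensions
  a <- matrix(stats::runif(R * i), R, i)
  pos <- sweep(sweep(a, 2, config$upper - config$lower, `*`), 2,
               config$lower, `+`)
  fit <- apply(pos, 1, fitness_fn)
  b <- which.min(fit)
  structure(list(positions = pos, fitness = fit,
                 best_position = pos[b, ], best_fitness = fit[b],
                 history = fit[b]),
            class = "fossa_population")
}

#' FOA attack phase (exploration)
#'
#' For each member `m`, the candidate lemur set is the strictly better
#' members (`fitness_K < fitness_m`); one lemur `psi` is drawn uniformly
#' from it and a trial position
#' `s + a * (psi - zeta * s)` (with `a ~ U(0,1)` and `zeta` drawn from
#' `{1, 2}` per coordinate) is clamped to the bounds and accepted only if it
#' improves fitness. The current best member has no candidates and stays
#' put.
#'
#' @param pop a `fossa_population`.
#' @param config a [foa_config()].
#' @param fitness_fn fitness function.
#' @return Updated `fossa_population`.
#' @export
foa_attack_step <- function(pop, config, fitness_fn) {
  R <- config$population; i <- config$dimensions
  for (m in seq_len(R)) {
    cand <- which(pop$fitness < pop$fitness[m])
    if (!length(cand)) next
    lemur <- pop$positions[cand[sample.int(length(cand), 1)], ]
    a <- stats::runif(i)
    zeta <- sample(c(1, 2), i, replace = TRUE)
    trial <- pop$positions[m, ] + a * (lemur - zeta * pop$positions[m, ])
    trial <- pmin(pmax(trial, config$lower), config$upper)
    ft <- fitness_fn(trial)
    if (ft < pop$fitness[m]) {
      pop$positions[m, ] <- trial
      pop$fitness[m] <- ft
    }
  }
  refresh_best(pop)
}

#' FOA chase phase (exploitation)
#'
#' Trial position `s + (1 - 2a) * (upper - lower) / iter` per coordinate
#' (`a ~ U(0,1)`), clamped to bounds, accepted greedily. The step magnitude
#' is bounded by `(upper - lower) / iter`, shrinking as iterations advance.
#'
#' @param pop a `fossa_population`.
#' @param iteration current iteration counter (>= 1).
#' @inheritParams foa_attack_step
#' @return Updated `fossa_population`.
#' @export
foa_chase_step <- function(pop, iteration, config, fitness_fn) {
  if (iteration < 1) stop("foa_chase_step: iteration must be >= 1")
  R <- config$population; i <- config$dimensions
  for (m in seq_len(R)) {
    a <- stats::runif(i)
    trial <- pop$positions[m, ] +
      (1 - 2 * a) * (config$upper - config$lower) / iteration
    trial <- pmin(pmax(trial, config$lower), config$upper)
    ft <- fitness_fn(trial)
    if (ft < pop$fitness[m]) {
      pop$positions[m, ] <- trial
      pop$fitness[m] <- ft
    }
  }
  refresh_best(pop)
}

refresh_best <- function(pop) {
  b <- which.min(pop$fitness)
  if (pop$fitness[b] < pop$best_fitness) {
    pop$best_fitness <- pop$fitness[b]
    pop$best_position <- pop$positions[b, ]
  }
  pop
}

#' Select features with the Fossa Optimization Algorithm
#'
#' Runs initialization followed by `iterations` rounds of attack + chase and
#' returns the binarized best position. The best-so-far history is recorded
#' per iteration and is non-increasing by the greedy acceptance rule.
#'
#' @param table numeric feature matrix.
#' @param labels class labels (>= 2 classes).
#' @param config a [foa_config()]; `dimensions` must equal `ncol(table)`.
#' @param val_table,val_labels optional validation pair for fitness (see
#'   [foa_fitness()]).
#' @return A `foa_selection` list: `selected` (indices), `names`, `mask`
#'   (0/1 vector), `best_fitness`, `history`, `seed`, `config`.
#' @export
select_features <- function(table, labels, config = NULL,
                            val_table = NULL, val_labels = NULL) {
  table <- as.matrix(table)
  if (ncol(table) < 2) stop("select_features: need >= 2 features")
  if (length(unique(labels)) < 2) stop("select_features: need >= 2 classes")
  if (is.null(config)) config <- foa_config(dimensions = ncol(table))
  if (config$dimensions != ncol(table))
    stop("select_features: config dimensions != ncol(table)")
  labels <- as.integer(as.factor(labels))
  folds <- stratified_folds(labels, config$cv_folds, config$seed)
  fitness_fn <- function(pos)
    foa_fitness(pos, table, labels, config, folds = folds,
                val_table = val_table, val_labels = val_labels)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  pop <- foa_init(config, fitness_fn)
  if (config$iterations >= 1) {
    for (iter in seq_len(config$iterations)) {
      pop <- foa_attack_step(pop, config, fitness_fn)
      pop <- foa_chase_step(pop, iter, config, fitness_fn)
      pop$history <- c(pop$history, pop$best_fitness)
    }
  }
  sel <- position_subset(pop$best_position, config$threshold)
  mask <- integer(config$dimensions)
  mask[sel] <- 1L
  structure(list(selected = sel,
                 names = colnames(table)[sel],
                 mask = mask,
                 best_fitness = pop$best_fitness,
                 history = pop$history,
                 seed = config$seed,
                 config = config),
            class = "foa_selection")
}
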