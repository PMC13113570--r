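fit_quad <- function(target) function(pos) sum((pos - target)^2)

test_that("population initialization respects bounds and the seed", {
  cfg <- foa_config(dimensions = 3, population = 4, seed = 5)
  set.seed(cfg$seed)
  pop <- foa_init(cfg, fit_quad(rep(0.5, 3)))
  expect_equal(dim(pop$positions), c(4L, 3L))
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_equal(pop$best_fitness, min(pop$fitness))
  set.seed(cfg$seed)
  pop2 <- foa_init(cfg, fit_quad(rep(0.5, 3)))
  expect_identical(pop$positions, pop2$positions)
  # degenerate bounds collapse to a point
  cfgd <- foa_config(dimensions = 2, population = 3, lower = c(0.4, 0.4),
                     upper = c(0.4 + 1e-12, 0.4 + 1e-12))
  set.seed(1)
  popd <- foa_init(cfgd, fit_quad(rep(0, 2)))
  expect_true(all(abs(popd$positions - 0.4) < 1e-9))
  expect_error(foa_config(dimensions = 2, lower = 1, upper = 0), "lower")
})

test_that("fitness combines error and subset penalty as specified", {
  # single perfectly separating feature, alpha = 0 -> fitness 0
  x <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  y <- rep(1:2, each = 10)
  cfg <- foa_config(dimensions = 1, subset_penalty = 0, seed = 2)
  expect_equal(foa_fitness(1, x, y, cfg), 0)
  # alpha = 1, all features selected, accuracy exactly 0.9 -> 0.1 + 1
  xt <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  yt <- rep(1:2, each = 10)
  xv <- matrix(c(rep(0, 5), rep(1, 4), 0), ncol = 1)  # one val point wrong
  yv <- rep(1:2, each = 5)
  cfg1 <- foa_config(dimensions = 1, subset_penalty = 1, seed = 2)
  expect_equal(foa_fitness(1, xt, yt, cfg1, val_table = xv, val_labels = yv),
               0.1 + 1, tolerance = 1e-12)
  # all-noise features on balanced labels: chance level ~ 0.5 + penalty
  set.seed(33)
  xn <- matrix(rnorm(200 * 5), 200, 5)
  yn <- rep(1:2, each = 100)
  cfg2 <- foa_config(dimensions = 5, subset_penalty = 0.01, seed = 7)
  f <- foa_fitness(rep(1, 5), xn, yn, cfg2)
  expect_lt(abs(f - (0.5 + 0.01)), 0.12)
  expect_error(foa_fitness(rep(1, 5), xn, rep(1, 200), cfg2), "single-class")
})

test_that("empty subsets are repaired to the top-valued feature", {
  expect_equal(position_subset(c(0.1, 0.4, 0.2), threshold = 0.5), 2L)
  expect_equal(position_subset(c(0.9, 0.4, 0.7)), c(1L, 3L))
})

test_that("attack and chase keep bounds, monotone fitness, fixed best", {
  cfg <- foa_config(dimensions = 4, population = 8, seed = 11)
  f <- fit_quad(c(0.2, 0.8, 0.5, 0.3))
  set.seed(cfg$seed)
  pop <- foa_init(cfg, f)
  best0 <- pop$positions[which.min(pop$fitness), ]
  for (it in 1:5) {
    old_fit <- pop$fitness
    pop <- foa_attack_step(pop, cfg, f)
    expect_true(all(pop$fitness <= old_fit + 1e-12))   # greedy acceptance
    expect_true(all(pop$positions >= 0 & pop$positions <= 1))
    old_fit <- pop$fitness
    pop2 <- foa_chase_step(pop, it, cfg, f)
    expect_true(all(pop2$fitness <= old_fit + 1e-12))
    expect_true(all(pop2$positions >= 0 & pop2$positions <= 1))
    # chase step magnitude is bounded by (upper - lower) / iteration for
    # accepted moves
    moved <- pop2$positions - pop$positions
    expect_true(all(abs(moved) <= 1 / it + 1e-12))
    pop <- pop2
  }
  # the initially best member can only have improved
  expect_lte(pop$best_fitness, f(best0))
})

test_that("select_features is greedy-monotone and matches T = 0 oracle", {
  tb <- make_feature_table(n = 120, p = 8, k = 2, r = 0, separation = 2,
                           seed = 51)
  cfg <- foa_config(dimensions = 8, population = 10, iterations = 12,
                    seed = 3)
  sel <- select_features(tb$table, tb$labels, cfg)
  expect_true(all(diff(sel$history) <= 1e-12))
  expect_gte(length(sel$selected), 1)
  expect_true(all(sel$selected %in% 1:8))
  expect_equal(which(sel$mask == 1), sel$selected)

  # T = 0: selection equals the binarized best initial member
  cfg0 <- foa_config(dimensions = 8, population = 10, iterations = 0,
                     seed = 3)
  sel0 <- select_features(tb$table, tb$labels, cfg0)
  labels <- as.integer(as.factor(tb$labels))
  folds <- lesionkit:::stratified_folds(labels, cfg0$cv_folds, cfg0$seed)
  set.seed(cfg0$seed)
  pop <- foa_init(cfg0, function(p)
    foa_fitness(p, tb$table, labels, cfg0, folds = folds))
  expect_equal(sel0$selected, position_subset(pop$best_position,
                                              cfg0$threshold))
})

test_that("a perfectly separating feature is always selected", {
  set.seed(77)
  n <- 60
  x <- cbind(matrix(rnorm(n * 10), n, 10),
             c(rnorm(n / 2, -3), rnorm(n / 2, 3)) * 0.1)
  x <- x[, sample(11)]
  sep_col <- which(apply(x, 2, function(cc) abs(diff(range(cc))) < 2))
  y <- rep(1:2, each = n / 2)
  cfg <- foa_config(dimensions = 11, population = 15, iterations = 25,
                    seed = 5)
  sel <- select_features(x, y, cfg)
  expect_true(sep_col %in% sel$selected)
})

test_that("selection is deterministic given the seed", {
  tb <- make_feature_table(n = 100, p = 6, k = 2, r = 0, seed = 9)
  cfg <- foa_config(dimensions = 6, population = 8, iterations = 5, seed = 21)
  s1 <- select_features(tb$table, tb$labels, cfg)
  s2 <- select_features(tb$table, tb$labels, cfg)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$history, s2$history)
})
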