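test_that("random forest fits, validates, and is seed-deterministic", {
  set.seed(1)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 4), 50, 2))
  y <- rep(c(0L, 1L), each = 50)
  m <- train_rf(x, y, rf_config(n_trees = 100, seed = 2))
  expect_equal(mean(predict(m, x) == y), 1)
  expect_error(train_rf(x, y, rf_config(mtry = 5)), "mtry")
  expect_error(train_rf(x, rep(0L, 100)), "single class")
  m2 <- train_rf(x, y, rf_config(n_trees = 100, seed = 2))
  xt <- matrix(rnorm(40, 2), 20, 2)
  expect_identical(predict(m, xt), predict(m2, xt))
  # the study's feature-subsampling defaults by input width
  expect_identical(ecgwellness:::default_mtry(184L), 12L)
  expect_identical(ecgwellness:::default_mtry(500L), 20L)
})

test_that("PSO converges on the sphere and respects its contracts", {
  sphere <- function(x) sum(x^2)
  for (s in 1:10) {
    res <- pso_minimize(sphere, 2, pso_config(seed = s))
    expect_lte(res$value, 0.05)  # box minimum is 0.02 at (0.1, 0.1)
    expect_true(all(res$par >= 0.1 & res$par <= 100))
    expect_true(all(diff(res$trace) <= 0))
  }
  # a single particle at a minimizer with zero velocity is a fixed point
  res <- pso_minimize(function(x) sum((x - 50)^2), 2,
                      pso_config(n_particles = 1, max_iters = 30,
                                 patience = 50, seed = 1),
                      init = matrix(c(50, 50), 1, 2))
  expect_equal(res$par, c(50, 50))
  expect_equal(res$value, 0)
  expect_error(pso_config(bounds = c(100, 0.1)), "min < max")
  expect_error(pso_minimize(function(x) NaN, 2, pso_config(seed = 1)),
               "non-finite")
})

test_that("PSO-tuned RBF-SVM separates concentric rings", {
  set.seed(11)
  n <- 120
  r <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3))
  th <- runif(n, 0, 2 * pi)
  x <- cbind(r * cos(th), r * sin(th))
  y <- rep(c(0L, 1L), each = n / 2)
  cfg <- pso_config(n_particles = 8, max_iters = 15, patience = 5, seed = 2)
  m <- train_pso_svm(x, y, cfg, cv_folds = 3)
  expect_gt(mean(predict(m, x) == y), 0.9)
  expect_true(m$C >= 0.1 && m$C <= 100)
  expect_true(m$gamma >= 0.1 && m$gamma <= 100)
  m2 <- train_pso_svm(x, y, cfg, cv_folds = 3)
  expect_identical(c(m$C, m$gamma), c(m2$C, m2$gamma))
})

test_that("evaluation metrics follow their confusion-matrix definitions", {
  perfect <- evaluate(rep(c(0L, 1L), 5), rep(c(0L, 1L), 5))
  expect_equal(unname(perfect$metrics),
               c(1, 1, 1, 100), tolerance = 1e-12)
  # an all-positive predictor: recall 1, precision = prevalence
  actual <- c(rep(1L, 3), rep(0L, 7))
  biased <- evaluate(rep(1L, 10), actual)
  expect_equal(unname(biased$metrics["REC"]), 1)
  expect_equal(unname(biased$metrics["PRE"]), 0.3)
  r <- evaluate(c(rep(1L, 4), rep(0L, 6)),
                c(rep(1L, 3), 0L, 1L, 1L, rep(0L, 4)))
  expect_identical(unname(r$confusion), c(3L, 1L, 2L, 4L))
  expect_equal(unname(r$metrics),
               c(0.6, 0.75, 2 * 0.6 * 0.75 / 1.35, 70), tolerance = 1e-12)
  expect_error(evaluate(1:3, 1:4), "lengths differ")
  none <- evaluate(rep(0L, 4), rep(0L, 4))
  expect_true(all(c("REC", "PRE") %in% none$degenerate))
})

test_that("stratified hold-out matches the per-class rounding rule", {
  labels <- c(rep(0L, 3590), rep(1L, 2740))
  sp <- split_holdout(labels, 0.70, seed = 3)
  expect_identical(sum(labels[sp$train] == 0L), 2513L)
  expect_identical(sum(labels[sp$train] == 1L), 1918L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_identical(sp, split_holdout(labels, 0.70, seed = 3))
  expect_error(split_holdout(c(0L, 1L, 1L)), "at least 2")
})

test_that("repeated-split cross-validation averages the round metrics", {
  set.seed(5)
  x <- matrix(rnorm(200), 100, 2)
  # a deterministic always-correct model: the label IS a function of x
  rule <- as.integer(x[, 1] > 0)
  cv2 <- cross_validate(
    x, rule,
    fit = function(xtr, ytr) "rule",
    predict_fn = function(model, xte) as.integer(xte[, 1] > 0),
    n_rounds = 3, seed = 4)
  expect_equal(unname(cv2$mean["ACC_percent"]), 100)
  per_round <- vapply(cv2$rounds, function(r) r$metrics, numeric(4))
  expect_equal(cv2$mean, rowMeans(per_round))
  cv3 <- cross_validate(
    x, rule, fit = function(xtr, ytr) "rule",
    predict_fn = function(model, xte) as.integer(xte[, 1] > 0),
    n_rounds = 3, seed = 4)
  expect_identical(cv2$mean, cv3$mean)
})
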