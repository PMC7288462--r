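test_that("single regression tree finds the exhaustive-search split", {
  set.seed(4)
  X <- data.frame(x1 = runif(40), x2 = runif(40))
  r <- ifelse(X$x1 > 0.6, 1, -1) + rnorm(40, 0, 0.05)
  tr <- fit_regression_tree(X, r, depth = 1, min_node_size = 3)
  expect_equal(tr$splits$variable[1], "x1")
  # brute-force oracle over all (feature, midpoint) splits
  best <- -Inf; best_var <- NA
  for (v in c("x1", "x2")) {
    xs <- sort(unique(X[[v]]))
    for (cut in (head(xs, -1) + tail(xs, -1)) / 2) {
      l <- r[X[[v]] < cut]; rr <- r[X[[v]] >= cut]
      if (length(l) < 3 || length(rr) < 3) next
      gain <- sum(l)^2 / length(l) + sum(rr)^2 / length(rr) - sum(r)^2 / 40
      if (gain > best) { best <- gain; best_var <- v; best_cut <- cut }
    }
  }
  expect_equal(tr$splits$variable[1], best_var)
  expect_equal(tr$nodes[1, 2], best_cut, tolerance = 1e-12)
  expect_equal(tr$splits$improvement[1], best, tolerance = 1e-9)
  # constant target: root-only tree predicting the mean
  tr0 <- fit_regression_tree(X, rep(2.5, 40), depth = 2)
  expect_equal(nrow(tr0$splits), 0L)
  expect_equal(tr0$pred, rep(2.5, 40))
})

test_that("boosting reduces training deviance monotonically without bagging", {
  set.seed(6)
  X <- data.frame(x = runif(150))
  y <- as.integer(runif(150) < plogis(4 * (X$x - 0.5)))
  m <- fit_brt(X, y, config = brt_config(learning_rate = 0.05, max_trees = 150,
                                         bag_fraction = 1, seed = 1))
  expect_true(all(diff(m$train_deviance) <= 1e-8))
  # null deviance bound: deviance at any stage <= intercept-only deviance
  p0 <- mean(y)
  null_dev <- -2 * mean(y * log(p0) + (1 - y) * log(1 - p0))
  expect_true(all(m$train_deviance <= null_dev + 1e-8))
})

test_that("fitted probabilities match a logistic oracle on one strong predictor", {
  set.seed(7)
  n <- 1500
  X <- data.frame(x = rbinom(n, 1, 0.5))
  y <- as.integer(runif(n) < ifelse(X$x == 1, 0.8, 0.2))
  m <- fit_brt(X, y, config = brt_config(learning_rate = 0.1, max_trees = 400,
                                         tree_depth = 1, seed = 2))
  p <- predict(m, data.frame(x = c(0, 1)), type = "prob")[, "1"]
  gl <- glm(y ~ x, data = cbind(X, y = y), family = binomial)
  p_or <- predict(gl, data.frame(x = c(0, 1)), type = "response")
  expect_lt(max(abs(p - p_or)), 0.02)
  # class-conditional frequencies within 0.02 as well
  emp <- tapply(y, X$x, mean)
  expect_lt(max(abs(p - emp)), 0.02)
})

test_that("multinomial loss keeps probabilities normalized and learns 3 classes", {
  set.seed(8)
  n <- 600
  X <- data.frame(x = runif(n, 0, 3))
  cls <- cut(X$x + rnorm(n, 0, 0.2), c(-Inf, 1, 2, Inf), labels = c("A", "C", "T"))
  m <- fit_brt(X, cls, config = brt_config(learning_rate = 0.1, max_trees = 300,
                                           seed = 3))
  pr <- predict(m, X, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, n), tolerance = 1e-9)
  expect_gt(mean(predict(m, X, type = "class") == cls), 0.85)
})

test_that("maximal-class-probability prediction uses the stated tie rules", {
  pr <- matrix(c(0.3, 0.36, 0.34), 1, dimnames = list(NULL, c("A", "C", "T")))
  expect_equal(as.character(map_class(pr)), "C")
  expect_equal(max(pr), 0.36)
  expect_equal(as.character(map_class(matrix(c(0.5, 0.5), 1))), "1")
})

test_that("CV selection: noise gives near-zero pseudo-R2, signal beats null", {
  set.seed(9)
  n <- 240
  Xn <- data.frame(x = runif(n), z = runif(n))
  yn <- factor(rbinom(n, 1, 0.5))
  mn <- suppressWarnings(
    brt_cv(Xn, yn, config = brt_config(learning_rate = 0.05, max_trees = 120,
                                       cv_folds = 5, seed = 4)))
  expect_lt(abs(mn$pseudo_r2), 0.15)
  ys <- factor(as.integer(runif(n) < ifelse(Xn$x > 0.5, 0.95, 0.05)))
  ms <- suppressWarnings(
    brt_cv(Xn, ys, config = brt_config(learning_rate = 0.05, max_trees = 300,
                                       cv_folds = 5, seed = 5)))
  expect_gt(ms$pseudo_r2, 0.5)
  null_dev <- {
    p0 <- mean(ys == "1")
    -2 * mean(ifelse(ys == "1", log(p0), log(1 - p0)))
  }
  expect_lt(min(ms$cv_deviance), null_dev)
  # fold assignment reproducible
  ms2 <- suppressWarnings(
    brt_cv(Xn, ys, config = brt_config(learning_rate = 0.05, max_trees = 300,
                                       cv_folds = 5, seed = 5)))
  expect_identical(ms$cv_deviance, ms2$cv_deviance)
  expect_error(brt_cv(Xn[1:3, ], ys[1:3],
                      config = brt_config(cv_folds = 5, max_trees = 10)),
               "fewer rows than folds")
})

test_that("pseudo-R2 follows its definition", {
  y <- factor(c(rep("a", 6), rep("b", 4)))
  expect_equal(pseudo_r2(y, y), 1)               # perfect predictions
  expect_equal(pseudo_r2(rep("a", 10), y), 0)    # majority-class predictor
  # err0 = 0.4, errM = 0.2 -> 0.5
  pred <- as.character(y); pred[c(1, 7)] <- c("b", "a")
  expect_equal(pseudo_r2(pred, y), 0.5)
  expect_true(is.na(pseudo_r2(rep("a", 3), factor(rep("a", 3)))))
})

test_that("relative influence isolates the informative predictor", {
  set.seed(10)
  n <- 400
  X <- data.frame(x = runif(n), n1 = runif(n), n2 = runif(n))
  y <- as.integer(runif(n) < ifelse(X$x > 0.5, 0.95, 0.05))
  m <- fit_brt(X, y, config = brt_config(learning_rate = 0.05, max_trees = 200,
                                         seed = 6))
  ri <- relative_influence(m)
  expect_equal(sum(ri), 100, tolerance = 1e-9)
  expect_true(all(ri >= 0))
  expect_gt(ri["x"], 90)
  # duplicated predictor shares the influence of the single column
  X2 <- data.frame(x = X$x, xdup = X$x, n1 = X$n1)
  m2 <- fit_brt(X2, y, config = brt_config(learning_rate = 0.05,
                                           max_trees = 200, seed = 6))
  ri2 <- relative_influence(m2)
  expect_gt(ri2["x"] + ri2["xdup"], 85)
})

test_that("partial dependence is flat for intercept models, monotone for stumps", {
  set.seed(11)
  X <- data.frame(x = runif(120))
  y0 <- rep(c(0L, 1L), 60)
  m0 <- fit_brt(X, y0, config = brt_config(max_trees = 10, seed = 1),
                n_trees = 5)
  pd0 <- partial_dependence(m0, X, "x", grid = seq(0, 1, length.out = 12))
  expect_lt(diff(range(pd0[[2]])), 0.05)
  y1 <- as.integer(runif(120) < plogis(8 * (X$x - 0.5)))
  m1 <- fit_brt(X, y1, config = brt_config(learning_rate = 0.1, max_trees = 150,
                                           tree_depth = 1, seed = 2))
  pd1 <- partial_dependence(m1, X, "x", grid = seq(0, 1, length.out = 12))
  expect_true(all(diff(pd1[["1"]]) >= -1e-9))
  expect_error(partial_dependence(m1, X, "x", grid = numeric(0)), "empty")
})

test_that("categorical predictors split by level subsets", {
  set.seed(12)
  n <- 300
  X <- data.frame(g = factor(sample(region_levels, n, replace = TRUE)))
  y <- as.integer(runif(n) < ifelse(X$g %in% region_levels[c(1, 3)], 0.9, 0.1))
  m <- fit_brt(X, y, config = brt_config(learning_rate = 0.1, max_trees = 120,
                                         tree_depth = 1, seed = 3))
  p <- predict(m, data.frame(g = factor(region_levels, levels = region_levels)),
               type = "prob")[, "1"]
  expect_gt(min(p[c(1, 3)]), 0.75)
  expect_lt(max(p[c(2, 4)]), 0.25)
  expect_error(predict(m, data.frame(g = "elsewhere")), "unseen level")
})
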