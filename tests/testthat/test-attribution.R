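random_binary_X <- function(n, d) {
  matrix(rbinom(n * d, 1, 0.5), n, d,
         dimnames = list(NULL, paste0("f", seq_len(d))))
}

test_that("trees solve separable and degenerate cases", {
  X <- cbind(a = c(0, 0, 1, 1, 0, 1), b = c(0, 1, 0, 1, 1, 0))
  y <- ifelse(X[, "a"] == 1, 10, 2)
  tree <- fit_tree(X, y, max_depth = 3, min_leaf = 1)
  expect_equal(predict(tree, X), y) # zero training error
  expect_equal(sum(!tree$is_leaf), 1L) # a single split suffices

  const <- fit_tree(X, rep(7, 6))
  expect_equal(nrow(const), 1L)
  expect_true(const$is_leaf)
  expect_equal(predict(const, X), rep(7, 6))
})

test_that("the root split equals the exhaustive-search oracle", {
  set.seed(21)
  for (i in 1:5) {
    X <- random_binary_X(12, 3)
    y <- rnorm(12)
    tree <- fit_tree(X, y, max_depth = 1, min_leaf = 1)
    want <- split_oracle(X, y)
    if (is.null(want)) {
      expect_true(tree$is_leaf[1])
    } else {
      expect_equal(tree$feature[1], want$feature)
    }
  }
})

test_that("leaves predict the mean of their routed training rows", {
  set.seed(4)
  X <- random_binary_X(40, 4)
  y <- rnorm(40) + 3 * X[, 1]
  tree <- fit_tree(X, y)
  pred <- predict(tree, X)
  for (v in unique(pred)) {
    expect_equal(v, mean(y[pred == v]), tolerance = 1e-12)
  }
  expect_true(all(tree$n[tree$is_leaf] >= 2)) # min_leaf default
})

test_that("splits are deterministic, sized correctly, and guarded", {
  set.seed(30)
  X <- random_binary_X(100, 5)
  y <- rnorm(100)
  s1 <- fit_forest_over_splits(X, y, n_splits = 5, seed = 42)
  s2 <- fit_forest_over_splits(X, y, n_splits = 5, seed = 42)
  expect_identical(lapply(s1, `[[`, "train_rows"),
                   lapply(s2, `[[`, "train_rows"))
  expect_true(all(vapply(s1, function(s) length(s$train_rows),
                         integer(1)) == 75L))
  expect_true(all(vapply(s1, function(s) length(s$test_rows),
                         integer(1)) == 25L))
  expect_error(fit_forest_over_splits(X, y, train_frac = 1.0), "test set")
  expect_error(fit_forest_over_splits(X[1:5, ], y[1:5]), ">= 8 rows")
})

test_that("Shapley attributions satisfy efficiency on randomized trees", {
  set.seed(50)
  for (i in 1:10) {
    X <- random_binary_X(30, 4)
    y <- rnorm(30) + 2 * X[, 2] - X[, 4]
    tree <- fit_tree(X, y)
    bg <- X[sample(30, 15), , drop = FALSE]
    x <- X[sample(30, 1), ]
    phi <- exact_shapley(tree, bg, x)
    gap <- sum(phi) - (predict(tree, matrix(x, 1)) -
                         mean(predict(tree, bg)))
    expect_lt(abs(gap), 1e-10)
  }
})

test_that("constant models and dummy features get zero attribution", {
  X <- random_binary_X(20, 3)
  const <- fit_tree(X, rep(5, 20))
  phi <- exact_shapley(const, X, X[1, ])
  expect_equal(unname(phi), c(0, 0, 0))

  # y depends only on f1; f2, f3 are dummies for the fitted tree
  set.seed(60)
  X2 <- random_binary_X(40, 3)
  y2 <- 4 * X2[, 1]
  tree <- fit_tree(X2, y2, max_depth = 2, min_leaf = 1)
  used <- stats::na.omit(tree$feature)
  expect_equal(unique(used), 1L)
  phi2 <- exact_shapley(tree, X2, X2[3, ])
  expect_equal(unname(phi2[2:3]), c(0, 0), tolerance = 1e-12)
})

test_that("an additive single-feature model attributes x1 minus its mean", {
  set.seed(61)
  X <- random_binary_X(50, 3)
  y <- X[, 1] # f(x) = x1 after a perfect depth-1 fit
  tree <- fit_tree(X, y, max_depth = 1, min_leaf = 1)
  for (x1 in c(0, 1)) {
    x <- c(x1, 1, 0)
    phi <- exact_shapley(tree, X, x)
    expect_equal(unname(phi[1]), x1 - mean(X[, 1]), tolerance = 1e-12)
    expect_equal(unname(phi[2:3]), c(0, 0), tolerance = 1e-12)
  }
})

test_that("duplicated identical features share attribution equally", {
  # a model that is symmetric in two identical features: a two-tree
  # forest in which one tree reads feature 1 and its mirror reads
  # feature 2
  set.seed(62)
  f <- rbinom(40, 1, 0.5)
  X <- cbind(a = f, b = f, c = rbinom(40, 1, 0.5))
  y <- 3 * f
  t1 <- fit_tree(X, y, max_depth = 1, min_leaf = 1)
  expect_equal(t1$feature[1], 1L) # splits on the first duplicate
  t2 <- t1
  t2$feature[!t2$is_leaf] <- 2L
  forest <- structure(list(t1, t2), class = "reg_forest")
  for (x in list(c(1, 1, 0), c(0, 0, 1))) {
    phi <- exact_shapley(forest, X, x)
    expect_equal(phi[["a"]], phi[["b"]], tolerance = 1e-12)
    expect_gt(abs(phi[["a"]]), 0) # and the attribution is real
  }
})

test_that("importance reports rank, average, and degenerate SD correctly", {
  p <- simulate_panel(spec_figure2(), seed = 5)
  fm <- build_feature_matrix(p$panel)
  splits <- fit_forest_over_splits(fm$X, fm$y, n_splits = 10, seed = 42)
  shap <- importance_report(splits, fm$X, fm$y)
  expect_equal(shap$rank, 1:5)
  expect_equal(shap$feature[order(-shap$mean_abs_shap)], shap$feature)
  per <- attr(shap, "per_split")
  expect_equal(dim(per), c(10L, 5L))
  expect_equal(unname(colMeans(per)[shap$feature[1]]),
               shap$mean_abs_shap[1])

  one <- importance_report(
    fit_forest_over_splits(fm$X, fm$y, n_splits = 1, seed = 42),
    fm$X, fm$y)
  # single split: SD column is zero by convention
  expect_true(all(one$sd == 0))
})

test_that("a label-shuffled panel shows no dominant feature", {
  p <- simulate_panel(spec_figure2(), seed = 77)
  fm <- build_feature_matrix(p$panel)
  set.seed(78)
  y_null <- sample(fm$y)
  splits <- fit_forest_over_splits(fm$X, y_null, n_splits = 50, seed = 42)
  shap <- importance_report(splits, fm$X, y_null)
  # attributions collapse towards zero relative to the real signal scale:
  # every feature's mean |SHAP| is small compared to sd(y), and the top
  # feature does not stand clear of its own across-split spread
  expect_true(all(shap$mean_abs_shap < 0.5 * sd(y_null)))
  gap <- shap$mean_abs_shap[1] - shap$mean_abs_shap[2]
  expect_lt(gap, 2 * shap$sd[1])
})

test_that("bagged forests predict by averaging their trees", {
  set.seed(70)
  X <- random_binary_X(30, 3)
  y <- rnorm(30) + X[, 1]
  fo <- fit_forest(X, y, n_trees = 5)
  manual <- rowMeans(vapply(fo, predict, numeric(nrow(X)), newdata = X))
  expect_equal(predict(fo, X), manual, tolerance = 1e-12)
})
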