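#' Feature matrix for rate attribution
#'
#' Encodes the biological labels of a panel as the five binary features
#' used for feature-importance analysis: phototrophy, carboxysome
#' association, and membership of the three carboxysome-expressing clades
#' (mutually exclusive indicators). Response is the measured kcat.
#' Restricted to active variants with a finite rate.
#'
#' @param panel A `panel_table` data.frame.
#' @return List with `X` (numeric 0/1 matrix, rownames = variant ids) and
#'   `y` (kcat, s^-1).
#' @export
build_feature_matrix <- function(panel) {
  stopifnot(is.data.frame(panel))
  sub <- panel[panel$active & !is.na(panel$kcat), , drop = FALSE]
  X <- cbind(
    trophic_mode_is_photo = as.numeric(sub$trophic_mode == "photo"),
    carboxysome = as.numeric(sub$carboxysome == "yes"),
    is_alpha_cyano = as.numeric(sub$clade == "alpha_cyano"),
    is_beta_cyano = as.numeric(sub$clade == "beta_cyano"),
    is_ccm_proteo = as.numeric(sub$clade == "ccm_proteo")
  )
  rownames(X) <- sub$variant_id
  list(X = X, y = sub$kcat)
}

# ---- depth-limited CART regression tree ------------------------------------

# exhaustive best split of rows by variance (SSE) reduction
best_split <- function(X, y, rows, min_leaf) {
  best <- NULL
  base_sse <- sum((y[rows] - mean(y[rows]))^2)
  for (j in seq_len(ncol(X))) {
    v <- X[rows, j]
    uq <- sort(unique(v))
    if (length(uq) < 2L) next
    cuts <- (uq[-1] + uq[-length(uq)]) / 2
    for (cut in cuts) {
      left <- rows[v <= cut]
      right <- rows[v > cut]
      if (length(left) < min_leaf || length(right) < min_leaf) next
      sse <- sum((y[left] - mean(y[left]))^2) +
        sum((y[right] - mean(y[right]))^2)
      gain <- base_sse - sse
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = j, cut = cut, gain = gain,
                     left = left, right = right)
      }
    }
  }
  best
}

#' Fit a depth-limited CART regression tree
#'
#' Binary tree grown by exhaustive search over axis-aligned splits,
#' maximizing variance (SSE) reduction; leaves predict the mean response
#' of their training rows. A constant response yields a root-only tree.
#'
#' @param X Numeric feature matrix.
#' @param y Response vector (length `nrow(X)`, >= 2).
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum rows per leaf.
#' @return An object of class `reg_tree`: data.frame of nodes (`id`,
#'   `feature`, `cut`, `left`, `right`, `value`, `n`, `is_leaf`).
#' @export
fit_tree <- function(X, y, max_depth = 3, min_leaf = 2) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need >= 2 rows", call. = FALSE)
  stopifnot(length(y) == nrow(X))
  nodes <- data.frame(id = integer(0), feature = integer(0),
                      cut = numeric(0), left = integer(0),
                      right = integer(0), value = numeric(0),
                      n = integer(0), is_leaf = logical(0))
  new_node <- function(rows) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, NA_integer_, NA_real_, NA_integer_,
                         NA_integer_, mean(y[rows]), length(rows), TRUE)
    id
  }
  grow <- function(rows, depth) {
    id <- new_node(rows)
    if (depth >= max_depth || length(rows) < 2L * min_leaf ||
        var(y[rows]) < 1e-24) return(id)
    sp <- best_split(X, y, rows, min_leaf)
    if (is.null(sp) || sp$gain <= 1e-12) return(id)
    left <- grow(sp$left, depth + 1L)
    right <- grow(sp$right, depth + 1L)
    nodes[id, c("feature", "cut", "left", "right", "is_leaf")] <<-
      list(sp$feature, sp$cut, left, right, FALSE)
    id
  }
  grow(seq_along(y), 0L)
  attr(nodes, "features") <- colnames(X)
  class(nodes) <- c("reg_tree", "data.frame")
  nodes
}

#' Predict from a regression tree
#'
#' @param object A `reg_tree`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Numeric predictions, one per row.
#' @export
predict.reg_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  node <- rep(1L, nrow(X))
  pred <- numeric(nrow(X))
  repeat {
    leaf <- object$is_leaf[node]
    if (all(leaf)) break
    at <- which(!leaf)
    nd <- node[at]
    goes_left <- X[cbind(at, object$feature[nd])] <= object$cut[nd]
    node[at] <- ifelse(goes_left, object$left[nd], object$right[nd])
  }
  object$value[node]
}

#' Bagged forest of depth-limited trees
#'
#' @param X,y Training data.
#' @param n_trees Number of bootstrap trees (1 = a single unbagged tree).
#' @param max_depth,min_leaf Tree controls.
#' @return An object of class `reg_forest` (list of `reg_tree`).
#' @export
fit_forest <- function(X, y, n_trees = 1, max_depth = 3, min_leaf = 2) {
  X <- as.matrix(X)
  trees <- lapply(seq_len(n_trees), function(i) {
    rows <- if (n_trees == 1L) seq_along(y)
            else sample.int(length(y), replace = TRUE)
    fit_tree(X[rows, , drop = FALSE], y[rows], max_depth, min_leaf)
  })
  structure(trees, class = "reg_forest", features = colnames(X))
}

#' @export
predict.reg_forest <- function(object, newdata, ...) {
  preds <- vapply(object, predict, numeric(nrow(as.matrix(newdata))),
                  newdata = newdata)
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' Train/test splits with one model per split
#'
#' Generates `n_splits` independent random splits at `train_frac` and fits
#' one depth-limited tree (or a small bagged forest) per split. All
#' randomness flows from the master seed, so the same seed reproduces the
#' same split sequence and models.
#'
#' @param X,y Full dataset (n >= 8).
#' @param n_splits Number of train/test splits (default 100).
#' @param train_frac Training fraction (default 0.75; must leave a
#'   non-empty test set).
#' @param max_depth,min_leaf Tree controls.
#' @param seed Master seed (default 42).
#' @param trees_per_split Trees per split (1 = single tree).
#' @return List of class `split_models`; each element has `model`,
#'   `train_rows`, `test_rows`.
#' @export
fit_forest_over_splits <- function(X, y, n_splits = 100,
                                   train_frac = 0.75, max_depth = 3,
                                   min_leaf = 2, seed = 42,
                                   trees_per_split = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 8L) stop("need >= 8 rows", call. = FALSE)
  n_train <- floor(train_frac * n)
  if (n_train < 2L) stop("train set smaller than 2 rows", call. = FALSE)
  if (n_train >= n)
    stop("train_frac leaves an empty test set", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- lapply(seq_len(n_splits), function(s) {
    train <- sort(sample.int(n, n_train))
    test <- setdiff(seq_len(n), train)
    model <- if (trees_per_split == 1L)
      fit_tree(X[train, , drop = FALSE], y[train], max_depth, min_leaf)
    else
      fit_forest(X[train, , drop = FALSE], y[train], trees_per_split,
                 max_depth, min_leaf)
    list(model = model, train_rows = train, test_rows = test)
  })
  structure(out, class = "split_models",
            settings = list(n_splits = n_splits, train_frac = train_frac,
                            max_depth = max_depth, min_leaf = min_leaf,
                            seed = seed, trees_per_split = trees_per_split))
}

# Shapley kernel weights |S|!(d-|S|-1)!/d! indexed by coalition size 0..d-1
shapley_weights <- function(d) {
  s <- 0:(d - 1)
  exp(lfactorial(s) + lfactorial(d - s - 1) - lfactorial(d))
}

#' Exact Shapley attributions for one instance
#'
#' Interventional expectation over a background set: for a coalition `S`,
#' `v(S)` is the mean model prediction over background rows with the
#' features in `S` overwritten by the instance's values. Attributions are
#' the exact Shapley sum over all `2^d` coalitions, so efficiency holds to
#' numerical precision: `sum(phi) = f(x) - mean(f(background))`.
#'
#' @param model Anything with a `predict(model, X)` method over the
#'   feature columns.
#' @param background Background feature matrix (e.g. the training rows).
#' @param x Single instance (numeric vector of the d features).
#' @param max_features Guard on `d` (enumeration is `2^d`).
#' @return Numeric vector `phi` of length d (named by feature).
#' @export
exact_shapley <- function(model, background, x, max_features = 12) {
  B <- as.matrix(background)
  d <- ncol(B)
  if (d > max_features)
    stop("too many features for exact enumeration; ",
         "a sampling approximation is out of scope", call. = FALSE)
  stopifnot(length(x) == d)
  nb <- nrow(B)

  # v(S) for all 2^d coalitions, one predict call on the stacked hybrids
  masks <- 0:(2^d - 1)
  bits <- (outer(masks, 2^(0:(d - 1)), bitwAnd) > 0) * 1
  hybrids <- do.call(rbind, lapply(seq_along(masks), function(k) {
    H <- B
    on <- which(bits[k, ] == 1)
    if (length(on)) H[, on] <- matrix(x[on], nb, length(on), byrow = TRUE)
    H
  }))
  colnames(hybrids) <- colnames(B)
  pred <- predict(model, hybrids)
  v <- rowMeans(matrix(pred, nrow = length(masks), byrow = TRUE))

  w <- shapley_weights(d)
  phi <- numeric(d)
  sizes <- rowSums(bits)
  for (i in seq_len(d)) {
    without <- which(bits[, i] == 0)
    with_i <- masks[without] + 2^(i - 1)
    # masks are 0-indexed; v is indexed by mask + 1
    phi[i] <- sum(w[sizes[without] + 1] *
                    (v[with_i + 1] - v[without]))
  }
  names(phi) <- colnames(B)
  phi
}

#' Feature-importance report: mean |Shapley| across splits
#'
#' For each split, computes exact Shapley attributions of the split's test
#' rows against its training rows as background, then averages |phi| over
#' test rows; the report gives each feature's mean and standard deviation
#' of that per-split mean across splits, ranked by mean.
#'
#' @param splits A `split_models` object from [fit_forest_over_splits()].
#' @param X,y The full dataset the splits index into.
#' @return An object of class `shap_report`: data.frame with `feature`,
#'   `mean_abs_shap` (s^-1), `sd` (across splits; 0 for a single split),
#'   `rank`; attribute `per_split` holds the split-by-feature matrix.
#' @export
importance_report <- function(splits, X, y) {
  stopifnot(inherits(splits, "split_models"))
  X <- as.matrix(X)
  d <- ncol(X)
  per_split <- matrix(NA_real_, length(splits), d,
                      dimnames = list(NULL, colnames(X)))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    bg <- X[sp$train_rows, , drop = FALSE]
    test <- X[sp$test_rows, , drop = FALSE]
    # test rows are binary label combinations; deduplicate before the
    # 2^d enumeration and weight by multiplicity
    key <- apply(test, 1, paste, collapse = "\r")
    uq <- !duplicated(key)
    counts <- table(key)[key[uq]]
    phis <- matrix(vapply(which(uq), function(i)
      abs(exact_shapley(sp$model, bg, test[i, ])), numeric(d)), nrow = d)
    per_split[s, ] <- as.numeric(phis %*% as.numeric(counts)) / nrow(test)
  }
  out <- data.frame(
    feature = colnames(X),
    mean_abs_shap = colMeans(per_split),
    sd = if (nrow(per_split) > 1) apply(per_split, 2, sd) else 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$mean_abs_shap), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "per_split") <- per_split
  attr(out, "settings") <- attr(splits, "settings")
  class(out) <- c("shap_report", "data.frame")
  out
}
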