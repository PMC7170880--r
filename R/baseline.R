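# Classical baselines over the hand-engineered features: L2-regularized
# logistic regression (glmnet ridge) and a 100-tree, depth-4 random forest.
# No random-forest package ships with this environment, so a compact CART
# forest (Gini splits, bootstrap resampling, random feature subsets) is
# implemented here.

# ---- random forest ---------------------------------------------------------

gini_impurity <- function(p) 2 * p * (1 - p)

# Best (feature, threshold) among `feats` by Gini gain; candidate thresholds
# are up to 16 quantile midpoints per feature (bounds cost, documented).
best_split <- function(X, y, feats, min_leaf = 3L) {
  n <- length(y)
  parent <- gini_impurity(mean(y))
  best <- NULL; best_gain <- 1e-12
  for (f in feats) {
    v <- X[, f]
    qs <- unique(stats::quantile(v, probs = seq(0.05, 0.95, length.out = 16),
                                 names = FALSE, type = 1))
    for (thr in qs) {
      left <- v <= thr
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      gain <- parent - (nl * gini_impurity(mean(y[left])) +
                        (n - nl) * gini_impurity(mean(y[!left]))) / n
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(feature = f, threshold = thr)
      }
    }
  }
  best
}

grow_tree <- function(X, y, depth, max_depth, mtry, min_leaf = 3L) {
  n <- length(y)
  p_hat <- mean(y)
  if (depth >= max_depth || n < 2L * min_leaf || p_hat == 0 || p_hat == 1)
    return(list(leaf = TRUE, p = p_hat))
  feats <- sample.int(ncol(X), mtry)
  sp <- best_split(X, y, feats, min_leaf)
  if (is.null(sp)) return(list(leaf = TRUE, p = p_hat))
  left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1L,
                        max_depth, mtry, min_leaf),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1L,
                         max_depth, mtry, min_leaf))
}

tree_depth <- function(node) {
  if (node$leaf) 0L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

predict_tree <- function(node, X) {
  if (node$leaf) return(rep(node$p, nrow(X)))
  out <- numeric(nrow(X))
  left <- X[, node$feature] <= node$threshold
  if (any(left)) out[left] <- predict_tree(node$left, X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(node$right, X[!left, , drop = FALSE])
  out
}

rf_fit <- function(X, y, n_trees = 100L, max_depth = 4L, seed = 1,
                   mtry = max(1L, floor(sqrt(ncol(X))))) {
  with_seed(seed, {
    trees <- vector("list", n_trees)
    n <- nrow(X)
    for (b in seq_len(n_trees)) {
      idx <- sample.int(n, n, replace = TRUE)
      trees[[b]] <- grow_tree(X[idx, , drop = FALSE], y[idx], 0L, max_depth, mtry)
    }
    list(trees = trees, n_trees = n_trees, max_depth = max_depth, mtry = mtry)
  })
}

rf_predict <- function(forest, X) {
  p <- matrix(0, nrow(X), forest$n_trees)
  for (b in seq_len(forest$n_trees)) p[, b] <- predict_tree(forest$trees[[b]], X)
  rowMeans(p)
}

# ---- baseline interface ----------------------------------------------------

#' Fit a classical baseline classifier
#'
#' `"rf"` is a random forest with exactly 100 trees of maximum depth 4
#' (the hyperparameters used for hand-engineered feature baselines in the
#' seizure detection literature); `"lr"` is L2-regularized logistic
#' regression (ridge, fixed penalty `lambda = 1e-3`). Features are z-scored
#' with training-set statistics only; zero-variance columns pass through
#' unscaled.
#'
#' @param X Training feature matrix (rows = clips).
#' @param y Binary labels (0/1).
#' @param model `"rf"` or `"lr"`.
#' @param seed Seed for the forest's bootstrap/feature randomness.
#' @param n_trees,max_depth Forest size (defaults fixed at 100 and 4).
#' @param lambda Ridge penalty for `"lr"`.
#' @return Object of class `weakeeg_baseline` with a [predict_baseline()]
#'   probability interface.
#' @export
fit_baseline <- function(X, y, model = c("rf", "lr"), seed = 1,
                         n_trees = 100L, max_depth = 4L, lambda = 1e-3) {
  model <- match.arg(model)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    abort_invalid("training labels contain a single class",
                  class = "weakeeg_empty_class")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- if (model == "rf") {
    rf_fit(Xs, y, n_trees = n_trees, max_depth = max_depth, seed = seed)
  } else {
    glmnet::glmnet(Xs, y, family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE)
  }
  structure(list(model = model, fit = fit, center = mu, scale = sdv,
                 feature_names = colnames(X)),
            class = "weakeeg_baseline")
}

#' Predicted seizure probabilities from a baseline classifier
#'
#' @param object A fitted `weakeeg_baseline`.
#' @param X Feature matrix with the training feature layout.
#' @return Numeric vector of probabilities.
#' @export
predict_baseline <- function(object, X) {
  stopifnot(inherits(object, "weakeeg_baseline"))
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  if (object$model == "rf") rf_predict(object$fit, Xs)
  else as.numeric(stats::predict(object$fit, Xs, type = "response"))
}
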