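#' Configuration for the boosted-regression-trees learner
#'
#' Defaults follow common practice for allele-frequency modelling: a slow
#' learning rate of 0.01 with a 20,000-tree cap selected by 10-fold
#' cross-validation, and a warning when the selected ensemble is smaller
#' than the 1000-tree rule of thumb.  Tree depth 2 and bag fraction 0.5 are
#' the usual small-interaction boosting defaults.
#'
#' @param learning_rate shrinkage in (0, 1].
#' @param max_trees boosting-iteration cap.
#' @param min_trees_guideline warn when fewer trees are selected.
#' @param cv_folds folds for [brt_cv()].
#' @param tree_depth maximum interaction depth of each tree.
#' @param bag_fraction fraction of rows drawn (without replacement) per tree.
#' @param min_node_size minimum rows per terminal node.
#' @param seed integer seed for bagging and fold assignment.
#' @export
brt_config <- function(learning_rate = 0.01, max_trees = 20000,
                       min_trees_guideline = 1000, cv_folds = 10,
                       tree_depth = 2, bag_fraction = 0.5,
                       min_node_size = 5, seed = 1) {
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must lie in (0, 1]")
  if (max_trees < cv_folds) stop("max_trees must be >= cv_folds")
  if (tree_depth < 1) stop("tree_depth must be >= 1")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("bag_fraction must lie in (0, 1]")
  structure(list(learning_rate = learning_rate, max_trees = max_trees,
                 min_trees_guideline = min_trees_guideline,
                 cv_folds = cv_folds, tree_depth = tree_depth,
                 bag_fraction = bag_fraction, min_node_size = min_node_size,
                 seed = seed), class = "brt_config")
}

# encode a data.frame into the numeric matrix the C++ learner expects;
# factors become 0-based level codes
.brt_encode <- function(X, features = NULL, cat_levels = NULL) {
  X <- as.data.frame(X)
  if (is.null(features)) features <- names(X)
  missing_f <- setdiff(features, names(X))
  if (length(missing_f))
    stop("predictors missing from data: ", paste(missing_f, collapse = ", "))
  X <- X[features]
  if (is.null(cat_levels)) {
    cat_levels <- lapply(X, function(col)
      if (is.factor(col) || is.character(col)) levels(factor(col)) else NULL)
  }
  m <- matrix(0, nrow(X), length(features),
              dimnames = list(NULL, features))
  for (j in seq_along(features)) {
    col <- X[[j]]
    if (!is.null(cat_levels[[j]])) {
      code <- match(as.character(col), cat_levels[[j]]) - 1L
      if (anyNA(code) && !anyNA(col))
        stop("unseen level in predictor ", features[j])
      m[, j] <- code
    } else {
      m[, j] <- as.numeric(col)
    }
  }
  list(m = m, is_cat = as.integer(!vapply(cat_levels, is.null, TRUE)),
       cat_levels = cat_levels)
}

#' Fit a boosted-regression-trees model
#'
#' Stagewise gradient boosting of depth-limited least-squares regression
#' trees.  The model is initialized at the intercept (logit of the mean for
#' the Bernoulli loss, log class proportions for the multinomial loss); at
#' each stage one tree per class is fitted to the negative gradient
#' (`y - p`, per class for the multinomial loss with its symmetric-logit
#' softmax parameterization) on a random bag of rows, shrunk by the
#' learning rate, and added to the score.
#'
#' @param X data.frame of predictors; factor/character columns are treated
#'   as categorical (split by ordered-mean subset partition).
#' @param y response: 0/1 vector or 2-level factor for `loss = "bernoulli"`;
#'   a factor with `K >= 3` levels for `loss = "multinomial"`.
#' @param loss `"bernoulli"` or `"multinomial"` (chosen from `y` when
#'   missing).
#' @param config a [brt_config()].
#' @param n_trees number of boosting stages (default `config$max_trees`).
#' @return an object of class `brt` with `print`, `summary`, `predict` and
#'   `plot` methods.
#' @examples
#' \donttest{
#' X <- data.frame(x = runif(200))
#' y <- as.integer(runif(200) < ifelse(X$x > 0.5, 0.9, 0.1))
#' m <- fit_brt(X, y, config = brt_config(max_trees = 200, seed = 2))
#' relative_influence(m)
#' }
#' @export
fit_brt <- function(X, y, loss = NULL, config = brt_config(),
                    n_trees = config$max_trees) {
  enc <- .brt_encode(X)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    classes <- levels(y)
    if (is.null(loss)) loss <- if (length(classes) <= 2L) "bernoulli" else "multinomial"
  } else {
    classes <- c("0", "1")
    y <- factor(y, levels = 0:1)
    if (is.null(loss)) loss <- "bernoulli"
  }
  loss <- match.arg(loss, c("bernoulli", "multinomial"))
  if (loss == "bernoulli" && nlevels(y) > 2L)
    stop("bernoulli loss needs a binary response")
  K <- if (loss == "bernoulli") 1L else nlevels(y)
  yi <- as.integer(y) - 1L
  if (length(unique(yi)) < 2L)
    warning("single-class response: degenerate intercept-only model")
  set.seed(config$seed)
  fit <- cpp_boost(enc$m, enc$is_cat, yi, K, as.integer(n_trees),
                   config$learning_rate, as.integer(config$tree_depth),
                   config$bag_fraction, as.integer(config$min_node_size))
  structure(list(nodes = fit$nodes, init = fit$init,
                 nodes_per_tree = fit$nodes_per_tree,
                 n_trees = as.integer(n_trees), K = K, loss = loss,
                 classes = classes, features = colnames(enc$m),
                 cat_levels = enc$cat_levels, config = config,
                 train_deviance = fit$train_deviance,
                 y_mean = mean(yi == max(yi)), call = match.call()),
            class = "brt")
}

#' @export
print.brt <- function(x, ...) {
  cat("boosted regression trees:", x$loss, "loss,", x$n_trees, "trees,",
      "depth", x$config$tree_depth, "\n")
  cat("predictors:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.brt <- function(object, ...) {
  print(object)
  ri <- relative_influence(object)
  cat("relative influence (%):\n")
  print(round(sort(ri, decreasing = TRUE), 2))
  invisible(ri)
}

#' @export
plot.brt <- function(x, ...) {
  graphics::plot(seq_along(x$train_deviance), x$train_deviance, type = "l",
                 xlab = "trees", ylab = "training deviance", ...)
  invisible(x)
}

#' Predict from a fitted BRT model
#'
#' @param object a [fit_brt()] model.
#' @param newdata data.frame with the training predictors.
#' @param n_trees number of boosting stages to use (default: all, or the
#'   CV-selected number when present).
#' @param type `"prob"` for class probabilities, `"class"` for the
#'   maximal-class-probability prediction (lowest-index tie-break),
#'   `"link"` for raw scores.
#' @param ... unused.
#' @export
predict.brt <- function(object, newdata, n_trees = NULL,
                        type = c("prob", "class", "link"), ...) {
  type <- match.arg(type)
  if (is.null(n_trees)) n_trees <- object$best_n_trees %||% object$n_trees
  n_trees <- min(n_trees, object$n_trees)
  enc <- .brt_encode(newdata, object$features, object$cat_levels)
  raw <- cpp_predict_raw(object$nodes, object$init, object$K,
                         object$nodes_per_tree, enc$m, as.integer(n_trees))
  if (type == "link") return(raw)
  if (object$K == 1L) {
    p1 <- stats::plogis(raw[, 1])
    prob <- cbind(1 - p1, p1)
  } else {
    prob <- exp(raw - apply(raw, 1, max))
    prob <- prob / rowSums(prob)
  }
  colnames(prob) <- object$classes
  if (type == "prob") return(prob)
  map_class(prob, object$classes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximal-class-probability prediction
#'
#' The predicted class is the one with the largest probability; exact ties
#' resolve to the lowest class index.  For example, probabilities
#' (0.3, 0.36, 0.34) over alleles (A, C, T) predict allele C.
#'
#' @param prob matrix (rows = observations) or vector of class
#'   probabilities.
#' @param classes class labels (default: column names).
#' @return factor of predicted classes.
#' @export
map_class <- function(prob, classes = colnames(prob)) {
  if (is.null(dim(prob))) prob <- matrix(prob, 1)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(prob)))
  factor(classes[max.col(prob, ties.method = "first")], levels = classes)
}

#' Cross-validated tree selection and model assessment
#'
#' Fold-stratified K-fold cross-validation of a BRT model: each fold's
#' ensemble is grown to `n_trees`, held-out deviance is tracked per stage,
#' and the optimal tree count minimizes the mean held-out deviance curve.
#' Warns when the optimum is below the 1000-tree rule of thumb or when the
#' cap is hit.  Held-out class predictions at the optimum give the adjusted
#' count pseudo-R-squared.
#'
#' @inheritParams fit_brt
#' @param strata optional grouping used to stratify fold assignment (e.g.
#'   the population of each allele copy); defaults to `y`.
#' @param n_trees cap on boosting stages (default `config$max_trees`).
#' @return a `brt` model fitted on all data, with extra elements
#'   `best_n_trees`, `cv_deviance` (mean held-out curve), `cv_pred`
#'   (held-out class probabilities at the optimum), `cv_map`, `pseudo_r2`.
#' @export
brt_cv <- function(X, y, loss = NULL, config = brt_config(), strata = NULL,
                   n_trees = config$max_trees) {
  if (config$cv_folds < 2L) stop("cv_folds must be >= 2")
  n <- nrow(as.data.frame(X))
  if (n < config$cv_folds) stop("fewer rows than folds")
  if (is.null(strata)) strata <- y
  set.seed(config$seed)
  fold <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(config$cv_folds), length(idx)))
  }
  Xdf <- as.data.frame(X)
  yf <- if (is.factor(y)) y else factor(y)
  dev <- matrix(NA_real_, n_trees, config$cv_folds)
  fold_models <- vector("list", config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    cfg <- config; cfg$seed <- config$seed + f
    m <- fit_brt(Xdf[tr, , drop = FALSE], droplevels_keep(yf, tr), loss,
                 cfg, n_trees = n_trees)
    enc <- .brt_encode(Xdf[!tr, , drop = FALSE], m$features, m$cat_levels)
    yi <- as.integer(yf[!tr]) - 1L
    dev[, f] <- cpp_staged_deviance(m$nodes, m$init, m$K, m$nodes_per_tree,
                                    enc$m, yi, as.integer(n_trees))
    fold_models[[f]] <- m
  }
  curve <- rowMeans(dev)
  best <- which.min(curve)
  if (best >= n_trees)
    warning("tree cap reached (", n_trees, "): consider raising max_trees")
  if (best < config$min_trees_guideline)
    warning("selected ensemble has ", best,
            " trees, below the 1000-tree rule of thumb")
  # held-out probabilities at the optimum
  prob <- matrix(NA_real_, n, nlevels(yf), dimnames = list(NULL, levels(yf)))
  for (f in seq_len(config$cv_folds)) {
    prob[fold == f, ] <- predict(fold_models[[f]],
                                 Xdf[fold == f, , drop = FALSE],
                                 n_trees = best, type = "prob")
  }
  cv_map <- map_class(prob, levels(yf))
  model <- fit_brt(Xdf, yf, loss, config, n_trees = n_trees)
  model$best_n_trees <- as.integer(best)
  model$cv_deviance <- curve
  model$cv_pred <- prob
  model$cv_map <- cv_map
  model$pseudo_r2 <- pseudo_r2(cv_map, yf)
  model
}

# factor subset that keeps the full level set (folds may miss a class)
droplevels_keep <- function(y, sel) factor(y[sel], levels = levels(y))

#' Adjusted count pseudo-R-squared
#'
#' `1 - err_M / err_0`: one minus the ratio of the model's cross-validated
#' misclassification frequency to that of the intercept-only
#' (majority-class) predictor.  `NA` when the response is single-class
#' (`err_0 = 0`).
#'
#' @param predicted cross-validated class predictions.
#' @param y observed classes.
#' @export
pseudo_r2 <- function(predicted, y) {
  y <- factor(y)
  err0 <- 1 - max(prop.table(table(y)))
  if (err0 == 0) return(NA_real_)
  errM <- mean(as.character(predicted) != as.character(y))
  1 - errM / err0
}

#' Relative influence of the predictors
#'
#' Per predictor, the sum of squared-error improvements over every split
#' using it (summed over classes for the multinomial loss), normalized to
#' percentages.  An intercept-only ensemble returns all zeros with
#' attribute `degenerate = TRUE`.
#'
#' @param model a [fit_brt()] model.
#' @param n_trees stages to account (default: CV-selected or all).
#' @return named numeric vector summing to 100 (or to 0 when degenerate).
#' @export
relative_influence <- function(model, n_trees = NULL) {
  if (is.null(n_trees)) n_trees <- model$best_n_trees %||% model$n_trees
  rows <- seq_len(n_trees * model$K * model$nodes_per_tree)
  nd <- model$nodes[rows, , drop = FALSE]
  used <- nd[, 1] >= 0 & nd[, 5] > 0
  out <- stats::setNames(numeric(length(model$features)), model$features)
  if (!any(used)) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  agg <- tapply(nd[used, 5], model$features[nd[used, 1] + 1], sum)
  out[names(agg)] <- agg
  100 * out / sum(out)
}

#' Partial dependence of the model on one predictor
#'
#' For each grid value the predictor is forced to that value in every
#' training-role row of `data` and the predicted class probabilities are
#' averaged.
#'
#' @param model a [fit_brt()] model.
#' @param data data.frame of background rows (typically the training data).
#' @param predictor predictor name.
#' @param grid values to evaluate (default: 50 points over the observed
#'   range, or the levels for a categorical predictor).
#' @param n_trees stages to use.
#' @return data.frame with the grid and one probability column per class.
#' @export
partial_dependence <- function(model, data, predictor, grid = NULL,
                               n_trees = NULL) {
  if (!predictor %in% model$features) stop("unknown predictor: ", predictor)
  data <- as.data.frame(data)
  if (is.null(grid)) {
    lv <- model$cat_levels[[match(predictor, model$features)]]
    grid <- if (!is.null(lv)) lv
            else seq(min(data[[predictor]]), max(data[[predictor]]),
                     length.out = 50)
  }
  if (!length(grid)) stop("empty partial-dependence grid")
  out <- matrix(NA_real_, length(grid), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (g in seq_along(grid)) {
    d <- data
    d[[predictor]] <- grid[g]
    out[g, ] <- colMeans(predict(model, d, n_trees = n_trees, type = "prob"))
  }
  data.frame(value = grid, out, check.names = FALSE)
}

#' Fit a single least-squares regression tree
#'
#' The base learner of the boosting ensemble, exposed directly: a
#' depth-limited regression tree on a numeric response, splits chosen by
#' maximal SSE reduction (categorical predictors by the ordered-mean subset
#' heuristic).  Constant responses give a single-leaf tree predicting the
#' mean.
#'
#' @param X data.frame of predictors.
#' @param r numeric response (e.g. gradient residuals).
#' @param depth maximum depth.
#' @param min_node_size minimum rows per terminal node.
#' @return list with `nodes` (internal node matrix), `pred` (fitted
#'   values), `splits` (data.frame of split variables and improvements).
#' @export
fit_regression_tree <- function(X, r, depth = 2, min_node_size = 5) {
  enc <- .brt_encode(X)
  if (nrow(enc$m) < 2 * min_node_size && stats::var(r) > 0)
    warning("fewer than 2 * min_node_size rows: returning a leaf")
  fit <- cpp_fit_tree(enc$m, enc$is_cat, as.numeric(r),
                      as.integer(depth), as.integer(min_node_size))
  nd <- fit$nodes
  used <- nd[, 1] >= 0 & nd[, 5] > 0
  splits <- data.frame(variable = colnames(enc$m)[nd[used, 1] + 1],
                       improvement = nd[used, 5],
                       stringsAsFactors = FALSE)
  list(nodes = nd, pred = as.numeric(fit$pred), splits = splits)
}
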