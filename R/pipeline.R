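#' Build a hyperparameter grid
#'
#' Cartesian product of the supplied vectors, returned as a list of named
#' settings (one list per combination), the form consumed by [inner_tune()].
#'
#' @param ... named vectors/lists of candidate values.
#' @return List of named lists.
#' @examples
#' param_grid(C = c(1, 10), gamma = c("scale", 1e-3))
#' @export
param_grid <- function(...) {
  args <- list(...)
  if (!length(args)) return(list(list()))
  idx <- expand.grid(lapply(args, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(idx)), function(r)
    stats::setNames(lapply(names(args), function(nm) args[[nm]][[idx[r, nm]]]),
                    names(args)))
}

#' Default hyperparameter grids
#'
#' Standard desk-scale grids for the selector/predictor combinations:
#' feature counts k in \{25, 50, 100\}, principal components in
#' \{5, 10, 20, 40\}, RBF cost C in \{0.1, 1, 10, 100\} and gamma in
#' \{"scale" (= 1/M after standardisation), 1e-3, 1e-4\}, kNN neighbours in
#' \{3, 5, 11\}, tree depth in \{3, 5, 30\}, 200 forest trees, AdaBoost
#' stumps in \{50, 100, 200\}.
#'
#' @param selector selector type: `"anova_f"`, `"pca"`, `"none"`, `"fixed"`.
#' @param predictor predictor type: `"svc_rbf"`, `"svr_rbf"`, `"knn"`,
#'   `"dtree"`, `"rforest"`, `"adaboost"`.
#' @return List of settings, see [param_grid()].
#' @export
default_param_grid <- function(selector, predictor) {
  sel <- switch(selector,
    anova_f = list(k = c(25, 50, 100)),
    pca = list(n_pc = c(5, 10, 20, 40)),
    none = list(), fixed = list(),
    stop("unknown selector: ", selector, call. = FALSE))
  prd <- switch(predictor,
    svc_rbf = ,
    svr_rbf = list(C = c(0.1, 1, 10, 100), gamma = list("scale", 1e-3, 1e-4)),
    knn = list(k_nb = c(3, 5, 11)),
    dtree = list(depth = c(3, 5, 30)),
    rforest = list(n_trees = 200),
    adaboost = list(n_stumps = c(50, 100, 200)),
    stop("unknown predictor: ", predictor, call. = FALSE))
  do.call(param_grid, c(sel, prd))
}

#' Specify a scaler/selector/predictor pipeline
#'
#' Every pipeline standardises features to zero mean and unit variance
#' (statistics learned from training rows only), applies a feature-selection
#' transformer and fits a final predictor. The hyperparameter grid is
#' searched by [inner_tune()] within a 5-fold group cross-validation.
#'
#' @param selector `"anova_f"`, `"pca"`, `"none"` or `"fixed"`.
#' @param predictor `"svc_rbf"`, `"svr_rbf"`, `"knn"`, `"dtree"`,
#'   `"rforest"` or `"adaboost"`.
#' @param grid list of candidate settings; defaults to
#'   [default_param_grid()].
#' @param fixed_indices feature indices, required when `selector = "fixed"`.
#' @param inner_folds folds of the inner group CV.
#' @return Object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(selector = "anova_f", predictor = "svc_rbf",
                          grid = default_param_grid(selector, predictor),
                          fixed_indices = NULL, inner_folds = 5L) {
  selector <- match.arg(selector, c("anova_f", "pca", "none", "fixed"))
  predictor <- match.arg(predictor, c("svc_rbf", "svr_rbf", "knn", "dtree",
                                      "rforest", "adaboost"))
  if (selector == "fixed" && is.null(fixed_indices))
    stop("selector 'fixed' requires fixed_indices", call. = FALSE)
  if (!length(grid)) stop("grid must be non-empty", call. = FALSE)
  structure(list(selector = selector, predictor = predictor, grid = grid,
                 fixed_indices = fixed_indices,
                 inner_folds = as.integer(inner_folds)),
            class = "pipeline_spec")
}

resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- mean(apply(X, 2L, stats::var))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else as.numeric(gamma)
}

#' Fit a pipeline at one hyperparameter setting
#'
#' Learns the standardiser and the feature selection from `(X, y)` and fits
#' the final predictor. Classification is detected from a factor/character
#' `y`.
#'
#' @param X training feature matrix.
#' @param y training labels (factor/character) or numeric target.
#' @param spec a [pipeline_spec()].
#' @param setting named list of hyperparameters (one element of the grid).
#' @param seed integer seed (used by stochastic predictors).
#' @return Object of class `fitted_pipeline`.
#' @export
fit_pipeline <- function(X, y, spec, setting = spec$grid[[1]], seed = 1L) {
  X <- as.matrix(X)
  classification <- is.factor(y) || is.character(y)
  if (classification) y <- factor(y)

  col_stats <- function(M) {
    center <- colMeans(M)
    scale_ <- sqrt(colMeans(M^2) - center^2) * sqrt(nrow(M) / (nrow(M) - 1))
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    list(center = center, scale = scale_)
  }

  sel <- list(type = spec$selector)
  if (spec$selector %in% c("anova_f", "fixed")) {
    # the F score is scale-invariant, so select on the raw columns and
    # standardise only the selected ones (the fitted statistics are still
    # training-only)
    if (spec$selector == "anova_f") {
      f <- if (classification) anova_f_classif(X, y) else anova_f_regress(X, y)
      sel$indices <- select_top_k(f, min(setting$k, ncol(X)))
    } else {
      sel$indices <- spec$fixed_indices
    }
    Xsub <- X[, sel$indices, drop = FALSE]
    st <- col_stats(Xsub)
    Xt <- sweep(sweep(Xsub, 2L, st$center), 2L, st$scale, "/")
  } else {
    st <- col_stats(X)
    Xs <- sweep(sweep(X, 2L, st$center), 2L, st$scale, "/")
    if (spec$selector == "pca") {
      n_pc <- min(setting$n_pc, ncol(Xs), nrow(Xs) - 1L)
      pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE, rank. = n_pc)
      sel$rotation <- pc$rotation
      Xt <- pc$x
    } else {
      Xt <- Xs
    }
  }
  center <- st$center
  scale_ <- st$scale

  set.seed(as.integer(seed))
  model <- switch(spec$predictor,
    svc_rbf = e1071::svm(Xt, y, type = "C-classification", kernel = "radial",
                         cost = setting$C, gamma = resolve_gamma(setting$gamma, Xt),
                         scale = FALSE),
    svr_rbf = e1071::svm(Xt, y, type = "eps-regression", kernel = "radial",
                         cost = setting$C, gamma = resolve_gamma(setting$gamma, Xt),
                         epsilon = max(0.1 * stats::sd(y), 1e-6),
                         scale = FALSE),
    knn = list(train = Xt, cl = y, k_nb = setting$k_nb),
    dtree = {
      colnames(Xt) <- paste0("V", seq_len(ncol(Xt)))
      df <- data.frame(Xt)
      df$.y <- y
      rpart::rpart(.y ~ ., df,
                   method = if (classification) "class" else "anova",
                   control = rpart::rpart.control(maxdepth = setting$depth,
                                                  cp = 0.001))
    },
    rforest = randomForest::randomForest(Xt, y, ntree = setting$n_trees),
    adaboost = fit_adaboost_stumps(Xt, y, n_stumps = setting$n_stumps))

  structure(list(spec = spec, setting = setting, classification = classification,
                 center = center, scale = scale_, selection = sel,
                 n_input = ncol(X), model = model,
                 levels = if (classification) levels(y)),
            class = "fitted_pipeline")
}

transform_features <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != fit$n_input)
    stop(sprintf("feature mismatch: pipeline was fitted on %d columns, got %d",
                 fit$n_input, ncol(X)), call. = FALSE)
  sel <- fit$selection
  if (!is.null(sel$indices)) {
    Xsub <- X[, sel$indices, drop = FALSE]
    sweep(sweep(Xsub, 2L, fit$center), 2L, fit$scale, "/")
  } else {
    Xs <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, "/")
    if (!is.null(sel$rotation)) Xs %*% sel$rotation else Xs
  }
}

#' @export
predict.fitted_pipeline <- function(object, newdata, ...) {
  Xt <- transform_features(object, newdata)
  out <- switch(object$spec$predictor,
    svc_rbf = ,
    svr_rbf = stats::predict(object$model, Xt),
    knn = class::knn(object$model$train, Xt, object$model$cl,
                     k = object$model$k_nb),
    dtree = {
      colnames(Xt) <- paste0("V", seq_len(ncol(Xt)))
      stats::predict(object$model, newdata = data.frame(Xt),
                     type = if (object$classification) "class" else "vector")
    },
    rforest = stats::predict(object$model, Xt),
    adaboost = predict_adaboost_stumps(object$model, Xt))
  if (object$classification) factor(as.character(out), levels = object$levels)
  else as.numeric(out)
}

# Deterministic assignment of groups to inner folds: groups are shuffled with
# the supplied seed and dealt round-robin.
group_folds <- function(groups, n_folds, seed) {
  ug <- unique(groups)
  if (length(ug) < n_folds)
    stop("fewer groups than folds in the inner CV", call. = FALSE)
  set.seed(as.integer(seed))
  ug <- sample(ug)
  fold_of <- stats::setNames(rep_len(seq_len(n_folds), length(ug)), ug)
  unname(fold_of[groups])
}

#' Tune a pipeline by inner group cross-validation
#'
#' Scores every grid setting by k-fold group CV on the training data
#' (classification: accuracy; regression: RMSE), picks the best setting
#' (ties resolved in grid order) and refits the pipeline on the full
#' training data at that setting.
#'
#' @param X,y training data.
#' @param groups protein identifier per row; whole groups move between folds.
#' @param spec a [pipeline_spec()].
#' @param seed integer seed controlling fold assignment and stochastic fits.
#' @return A `fitted_pipeline` with `inner_scores` (per-setting CV score) and
#'   `best_setting` attached.
#' @export
inner_tune <- function(X, y, groups, spec, seed = 1L) {
  X <- as.matrix(X)
  classification <- is.factor(y) || is.character(y)
  if (classification) y <- factor(y)
  folds <- group_folds(groups, spec$inner_folds, seed)
  scores <- numeric(length(spec$grid))
  for (gi in seq_along(spec$grid)) {
    setting <- spec$grid[[gi]]
    preds <- rep(NA_real_, length(y))
    cls_preds <- rep(NA_character_, length(y))
    for (f in seq_len(spec$inner_folds)) {
      tr <- folds != f
      fit <- fit_pipeline(X[tr, , drop = FALSE],
                          if (classification) droplevels(y[tr]) else y[tr],
                          spec, setting, seed = seed + f)
      p <- predict(fit, X[!tr, , drop = FALSE])
      if (classification) cls_preds[!tr] <- as.character(p)
      else preds[!tr] <- p
    }
    scores[gi] <- if (classification) mean(cls_preds == as.character(y))
    else -sqrt(mean((preds - y)^2))
  }
  best <- which.max(scores)
  fit <- fit_pipeline(X, y, spec, spec$grid[[best]], seed = seed)
  fit$inner_scores <- scores
  fit$best_setting <- spec$grid[[best]]
  fit
}
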