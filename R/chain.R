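#' Fit the beta-then-alpha regression chain
#'
#' Two-stage chained regression reflecting the negative correlation between
#' sheet and helix content: stage 1 predicts the first target (by default
#' beta-sheet percent) from the selected spectral features; stage 2 predicts
#' the second target (alpha-helix percent) from the same features plus the
#' stage-1 prediction appended as an extra standardised feature.
#'
#' Feature selection is shared by both stages: two independent univariate
#' F tests ([anova_f_regress()]) are run, one per target, the top `k` of each
#' are merged with [combine_chain_features()], and — because this selection
#' lives outside the pipeline — `k` is chosen manually by minimising the
#' training RMSE (summed over both targets) across `k_grid`. Each stage is
#' hyperparameter-tuned by [inner_tune()] on the fixed feature list.
#'
#' @param X training feature matrix.
#' @param targets data frame (or named list) with one numeric column per
#'   target, in chain order; default order is beta then alpha.
#' @param groups protein identifier per training row.
#' @param k_grid candidate per-test feature counts.
#' @param predictor_grid hyperparameter grid for the stage predictors.
#' @param seed integer seed.
#' @return Object of class `fitted_chain`: `stage_models` (named list of
#'   `fitted_pipeline`), `feature_indices` (the merged list), `chain_order`,
#'   `k` (chosen count) and `train_rmse` (per target at the chosen k).
#' @export
fit_regression_chain <- function(X, targets, groups,
                                 k_grid = c(25, 50, 100),
                                 predictor_grid = default_param_grid("fixed", "svr_rbf"),
                                 seed = 1L) {
  X <- as.matrix(X)
  targets <- as.data.frame(targets)
  if (ncol(targets) < 2L) stop("the chain needs two targets", call. = FALSE)
  if (any(k_grid > ncol(X)))
    stop("k exceeds the feature count", call. = FALSE)
  chain_order <- names(targets)

  ## the univariate F score is scale-invariant, so the tests run on the raw
  ## training columns; within nested CV this function only sees training rows
  f_scores <- lapply(targets, function(y) anova_f_regress(X, y))

  best <- NULL
  for (k in k_grid) {
    idx <- Reduce(combine_chain_features,
                  lapply(f_scores, select_top_k, k = k))
    fits <- list()
    rmses <- numeric(ncol(targets))
    Xaug <- X
    for (t in seq_along(chain_order)) {
      spec <- pipeline_spec("fixed", "svr_rbf", grid = predictor_grid,
                            fixed_indices = if (t == 1L) idx
                                            else c(idx, ncol(Xaug)))
      fit <- inner_tune(Xaug, targets[[t]], groups, spec, seed = seed + t)
      pred_train <- predict(fit, Xaug)
      rmses[t] <- rmse(pred_train, targets[[t]])
      fits[[chain_order[t]]] <- fit
      if (t < length(chain_order))
        Xaug <- cbind(Xaug, pred_train)   # chain: feed prediction forward
    }
    if (is.null(best) || sum(rmses) < best$score) {
      best <- list(score = sum(rmses), k = k, idx = idx, fits = fits,
                   rmses = stats::setNames(rmses, chain_order))
    }
  }
  structure(list(stage_models = best$fits, feature_indices = best$idx,
                 chain_order = chain_order, k = best$k,
                 train_rmse = best$rmses),
            class = "fitted_chain")
}

#' Predict all chained targets
#'
#' Applies the chain stages in order, appending each stage's predictions to
#' the feature matrix before the next stage, exactly as during fitting.
#' Outputs are on the percent scale of the training targets and are not
#' clipped unless `clip` is set.
#'
#' @param chain a `fitted_chain`.
#' @param X feature matrix with the same columns as the training frame.
#' @param clip optional two-element range to clip predictions to
#'   (e.g. `c(0, 100)`).
#' @return Data frame of predictions, one column per chained target.
#' @export
predict_chain <- function(chain, X, clip = NULL) {
  X <- as.matrix(X)
  exp_cols <- chain$stage_models[[1]]$n_input
  if (ncol(X) != exp_cols)
    stop(sprintf("feature mismatch: chain was fitted on %d columns, got %d",
                 exp_cols, ncol(X)), call. = FALSE)
  out <- list()
  Xaug <- X
  for (t in seq_along(chain$chain_order)) {
    nm <- chain$chain_order[t]
    p <- predict(chain$stage_models[[nm]], Xaug)
    if (!is.null(clip)) p <- pmin(pmax(p, clip[1]), clip[2])
    out[[nm]] <- p
    if (t < length(chain$chain_order)) Xaug <- cbind(Xaug, p)
  }
  as.data.frame(out)
}

#' Leave-one-protein-out evaluation of the regression chain
#'
#' Runs the chain through an outer LOO-by-protein loop: for each protein, the
#' chain (F tests, feature merge, k choice and stage tuning) is refit on all
#' other proteins and its predictions recorded for the held-out spectra.
#'
#' @param frame a `feature_frame` labelled with the chain targets.
#' @param target_cols label columns in chain order (default beta then alpha).
#' @inheritParams fit_regression_chain
#' @return `nested_cv_result` with per-fold multi-target predictions.
#' @export
run_chain_loo <- function(frame, target_cols = c("beta_pct", "alpha_pct"),
                          k_grid = c(25, 50, 100),
                          predictor_grid = default_param_grid("fixed", "svr_rbf"),
                          seed = 1L) {
  stopifnot(inherits(frame, "feature_frame"))
  targets <- frame$row_meta[target_cols]
  groups <- frame$group_of
  ug <- sort(unique(groups))
  results <- vector("list", length(ug))
  for (fi in seq_along(ug)) {
    te <- groups == ug[fi]
    chain <- fit_regression_chain(frame$matrix[!te, , drop = FALSE],
                                  targets[!te, , drop = FALSE],
                                  groups[!te], k_grid = k_grid,
                                  predictor_grid = predictor_grid,
                                  seed = seed + fi)
    pred <- predict_chain(chain, frame$matrix[te, , drop = FALSE])
    results[[fi]] <- list(test_proteins = ug[fi], rows = which(te),
                          truth = targets[te, , drop = FALSE],
                          predictions = pred, groups = groups[te],
                          selected = chain$feature_indices,
                          setting = list(k = chain$k))
  }
  structure(list(folds = results, task = "regression_chain",
                 label_col = target_cols, levels = NULL),
            class = "nested_cv_result")
}

#' Fit independent sheet-registry regressors
#'
#' Independent ANOVA-F + SVR models for parallel and antiparallel sheet
#' percent. When `override_with_antiparallel` is set, the parallel model's
#' feature list is extended to the union of its own selection and the
#' antiparallel model's selection — encoding the domain knowledge that the
#' antiparallel-selected nodal-region pixels are the physically meaningful
#' ones.
#'
#' @param X training matrix.
#' @param parallel_pct,antiparallel_pct numeric targets (percent).
#' @param groups protein identifier per row.
#' @param k features per F test.
#' @param override_with_antiparallel logical; see above.
#' @param predictor_grid stage hyperparameter grid.
#' @param seed integer seed.
#' @return List with `parallel` and `antiparallel` fitted pipelines and their
#'   feature index lists.
#' @export
fit_sheet_registry_models <- function(X, parallel_pct, antiparallel_pct, groups,
                                      k = 50,
                                      override_with_antiparallel = FALSE,
                                      predictor_grid = default_param_grid("fixed", "svr_rbf"),
                                      seed = 1L) {
  X <- as.matrix(X)
  idx_anti <- select_top_k(anova_f_regress(X, antiparallel_pct), k)
  fits <- list()
  if (stats::sd(parallel_pct) == 0) {
    # degenerate target: constant predictor
    fits$parallel <- structure(list(constant = mean(parallel_pct)),
                               class = "constant_predictor")
    idx_par <- integer(0)
  } else {
    idx_par <- select_top_k(anova_f_regress(X, parallel_pct), k)
    if (override_with_antiparallel)
      idx_par <- combine_chain_features(idx_par, idx_anti)
    spec <- pipeline_spec("fixed", "svr_rbf", grid = predictor_grid,
                          fixed_indices = idx_par)
    fits$parallel <- inner_tune(X, parallel_pct, groups, spec, seed = seed)
  }
  spec <- pipeline_spec("fixed", "svr_rbf", grid = predictor_grid,
                        fixed_indices = idx_anti)
  fits$antiparallel <- inner_tune(X, antiparallel_pct, groups, spec,
                                  seed = seed + 1L)
  fits$parallel_indices <- idx_par
  fits$antiparallel_indices <- idx_anti
  fits
}

#' @export
predict.constant_predictor <- function(object, newdata, ...) {
  rep(object$constant, nrow(as.matrix(newdata)))
}

#' Fit the helix-length classifier
#'
#' ANOVA-F feature selection followed by AdaBoost over decision stumps,
#' tuned by inner group CV (feature count and stump count on the default
#' grid).
#'
#' @param X training matrix.
#' @param helix_class two-level labels (`short_helices` / `long_helices`).
#' @param groups protein identifier per row.
#' @param grid hyperparameter grid.
#' @param seed integer seed.
#' @return A tuned `fitted_pipeline`.
#' @export
fit_helix_length_classifier <- function(X, helix_class, groups,
                                        grid = default_param_grid("anova_f", "adaboost"),
                                        seed = 1L) {
  y <- factor(helix_class)
  if (nlevels(y) < 2L)
    stop("helix-length training set has a single class", call. = FALSE)
  spec <- pipeline_spec("anova_f", "adaboost", grid = grid)
  inner_tune(X, y, groups, spec, seed = seed)
}
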