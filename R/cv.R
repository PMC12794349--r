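#' Define the outer cross-validation plan
#'
#' Two outer-loop designs over protein groups (all spectra of a protein stay
#' together): `loo_by_group` holds out each protein in turn;
#' `random_group_splits` draws `n_splits` random splits holding out
#' `test_frac` of the proteins.
#'
#' @param outer `"loo_by_group"` or `"random_group_splits"`.
#' @param n_splits number of random splits.
#' @param test_frac fraction of proteins held out per split.
#' @param seed integer seed for the random splits.
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(outer = c("loo_by_group", "random_group_splits"),
                    n_splits = 3L, test_frac = 0.2, seed = 1L) {
  outer <- match.arg(outer)
  stopifnot(n_splits >= 1, test_frac > 0, test_frac < 1)
  structure(list(outer = outer, n_splits = as.integer(n_splits),
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "cv_plan")
}

# List of outer folds; each fold is a character vector of held-out proteins.
outer_folds <- function(plan, groups) {
  ug <- sort(unique(groups))
  if (plan$outer == "loo_by_group") {
    lapply(ug, identity)
  } else {
    n_test <- max(1L, round(plan$test_frac * length(ug)))
    lapply(seq_len(plan$n_splits), function(s) {
      set.seed(plan$seed + s - 1L)
      sample(ug, n_test)
    })
  }
}

frame_labels <- function(frame, label_col) {
  if (!label_col %in% names(frame$row_meta))
    stop("frame is missing label column '", label_col,
         "'; run label_frame() first", call. = FALSE)
  frame$row_meta[[label_col]]
}

#' Run a nested group cross-validation
#'
#' For each outer fold, the pipeline is tuned by [inner_tune()] on the
#' training rows only (standardiser and feature selection are refit inside
#' every fold) and evaluated on the held-out protein(s). Returns per-fold
#' predictions and, for classification, the assembled confusion matrix.
#'
#' @param frame a labelled `feature_frame` (see [label_frame()]).
#' @param spec a [pipeline_spec()].
#' @param plan a [cv_plan()].
#' @param label_col name of the label column in `frame$row_meta`; defaults to
#'   the first label attached by [label_frame()].
#' @param seed integer seed for inner-fold assignment and stochastic fits.
#' @return Object of class `nested_cv_result`: list with `folds` (per fold:
#'   held-out proteins, row indices, truth, predictions, selected feature
#'   indices, chosen setting) and `task` (`"classification"` or
#'   `"regression"`).
#' @export
run_nested_cv <- function(frame, spec, plan, label_col = NULL, seed = 1L) {
  stopifnot(inherits(frame, "feature_frame"), inherits(plan, "cv_plan"))
  if (is.null(label_col)) label_col <- attr(frame, "label_cols")[1]
  y <- frame_labels(frame, label_col)
  classification <- is.factor(y) || is.character(y)
  if (classification) y <- factor(y)
  groups <- frame$group_of
  folds <- outer_folds(plan, groups)
  results <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    test_proteins <- folds[[fi]]
    te <- groups %in% test_proteins
    fit <- inner_tune(frame$matrix[!te, , drop = FALSE],
                      if (classification) droplevels(y[!te]) else y[!te],
                      groups[!te], spec, seed = seed + fi)
    pred <- predict(fit, frame$matrix[te, , drop = FALSE])
    results[[fi]] <- list(test_proteins = test_proteins,
                          rows = which(te),
                          truth = y[te],
                          predictions = pred,
                          groups = groups[te],
                          selected = fit$selection$indices,
                          setting = fit$best_setting)
  }
  structure(list(folds = results,
                 task = if (classification) "classification" else "regression",
                 label_col = label_col,
                 levels = if (classification) levels(y)),
            class = "nested_cv_result")
}
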