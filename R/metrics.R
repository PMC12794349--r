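#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace / total` and expected agreement
#' `p_e = sum(row_c * col_c) / total^2`. Returns 0 when `p_e = 1` (a single
#' cell carries all counts) by convention.
#'
#' @param confusion square count matrix, rows = truth, columns = predicted.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (!nrow(confusion) || total <= 0)
    stop("confusion matrix must carry counts", call. = FALSE)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square", call. = FALSE)
  p_o <- sum(diag(confusion)) / total
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - p_e) < 1e-12) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, per-class precision/recall/F1 and their macro averages. A class
#' never predicted gets precision 0 and a class absent from the truth gets
#' recall 0; such classes are flagged in `degenerate`.
#'
#' @param confusion square count matrix, rows = truth, columns = predicted.
#' @return List with `accuracy`, `kappa`, `per_class` (data frame) and
#'   `macro` (named vector), plus `degenerate` class names.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  stopifnot(total > 0, nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  classes <- rownames(confusion)
  if (is.null(classes)) classes <- paste0("class_", seq_len(nrow(confusion)))
  list(accuracy = sum(tp) / total,
       kappa = cohens_kappa(confusion),
       per_class = data.frame(class = classes, precision = precision,
                              recall = recall, f1 = f1, row.names = NULL),
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
       degenerate = classes[pred_n == 0 | true_n == 0])
}

#' Root mean squared error
#'
#' @param predicted,truth equal-length numeric vectors.
#' @return `sqrt(mean((predicted - truth)^2))`; in percentage points when the
#'   inputs are percentages.
#' @export
rmse <- function(predicted, truth) {
  if (length(predicted) != length(truth) || !length(truth))
    stop("predicted and truth must be equal non-zero length", call. = FALSE)
  sqrt(mean((as.numeric(predicted) - as.numeric(truth))^2))
}

#' Pooled standard deviation across replicate groups
#'
#' `sqrt(sum_i (n_i - 1) s_i^2 / sum_i (n_i - 1))` over the per-group sample
#' standard deviations s_i: the spread of predictions across the repeated
#' spectra of each protein. Groups of fewer than two values are dropped with
#' a warning.
#'
#' @param groups list of numeric vectors (one per protein).
#' @return Pooled SD (>= 0).
#' @export
s_pooled <- function(groups) {
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    warning(sum(sizes < 2L), " group(s) of size < 2 excluded from s_pooled")
    groups <- groups[sizes >= 2L]
  }
  if (!length(groups))
    stop("no groups of size >= 2 for s_pooled", call. = FALSE)
  df <- lengths(groups) - 1L
  vars <- vapply(groups, stats::var, 0)
  sqrt(sum(df * vars) / sum(df))
}

#' Build a confusion matrix on fixed class levels
#'
#' @param truth,predicted class vectors.
#' @param levels class levels fixing row/column order.
#' @return Square count matrix, rows = truth.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(predicted))))
  table(factor(as.character(truth), levels = levels),
        factor(as.character(predicted), levels = levels))
}

#' Summarise a nested-CV run into an evaluation report
#'
#' For classification: per-protein accuracy, pooled confusion matrix,
#' aggregate accuracy/kappa/precision/recall/F1, plus the unweighted average
#' of per-protein accuracies (the convention used when quoting LOO results
#' protein by protein). For regression (including the chain): per-protein
#' mean prediction and SD per target, pooled RMSE and pooled prediction SD
#' per target.
#'
#' @param result a `nested_cv_result`.
#' @return Object of class `eval_report`.
#' @export
loo_report <- function(result) {
  stopifnot(inherits(result, "nested_cv_result"))
  folds <- result$folds
  if (result$task == "classification") {
    truth <- unlist(lapply(folds, function(f) as.character(f$truth)))
    pred <- unlist(lapply(folds, function(f) as.character(f$predictions)))
    grp <- unlist(lapply(folds, `[[`, "groups"))
    conf <- confusion_matrix(truth, pred, result$levels)
    per_protein <- vapply(split(seq_along(grp), grp),
                          function(i) mean(pred[i] == truth[i]), 0)
    metrics <- classification_metrics(conf)
    structure(list(task = "classification",
                   per_protein = per_protein,
                   mean_protein_accuracy = mean(per_protein),
                   aggregate = metrics, confusion = conf),
              class = "eval_report")
  } else {
    to_df <- function(p) if (is.data.frame(p)) p else
      stats::setNames(data.frame(p), result$label_col)
    truth <- do.call(rbind, lapply(folds, function(f) to_df(f$truth)))
    pred <- do.call(rbind, lapply(folds, function(f) to_df(f$predictions)))
    grp <- unlist(lapply(folds, `[[`, "groups"))
    targets <- names(truth)
    per_target <- lapply(targets, function(t) {
      by_protein <- split(pred[[t]], grp)
      data.frame(protein_id = names(by_protein),
                 mean_prediction = vapply(by_protein, mean, 0),
                 prediction_sd = vapply(by_protein, stats::sd, 0),
                 truth = vapply(split(truth[[t]], grp), function(v) v[1], 0),
                 row.names = NULL)
    })
    names(per_target) <- targets
    agg <- data.frame(
      target = targets,
      rmse = vapply(targets, function(t) rmse(pred[[t]], truth[[t]]), 0),
      s_pooled = vapply(targets, function(t)
        suppressWarnings(s_pooled(split(pred[[t]], grp))), 0),
      row.names = NULL)
    structure(list(task = "regression", per_protein = per_target,
                   aggregate = agg),
              class = "eval_report")
  }
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$task == "classification") {
    cat(sprintf("<eval_report> classification: accuracy %.3f, kappa %.3f, mean per-protein accuracy %.3f\n",
                x$aggregate$accuracy, x$aggregate$kappa,
                x$mean_protein_accuracy))
  } else {
    cat("<eval_report> regression:\n")
    print(x$aggregate)
  }
  invisible(x)
}

#' Per-class mean amplitude at selected features
#'
#' Mean spectral amplitude of each class at each selected feature — the
#' summary used to show that selected (nodal-region) pixels move from
#' positive through near zero to negative across alpha-enriched, mixed and
#' beta-enriched spectra.
#'
#' @param frame a `feature_frame` labelled with `class`.
#' @param selected feature column indices.
#' @param class_col label column name.
#' @return Matrix classes x selected features of mean amplitudes; empty
#'   classes appear as NA rows and are named in the `flagged` attribute.
#' @export
class_amplitude_summary <- function(frame, selected, class_col = "class") {
  stopifnot(inherits(frame, "feature_frame"))
  if (any(selected < 1L | selected > ncol(frame$matrix)))
    stop("selected indices out of range", call. = FALSE)
  cls <- frame$row_meta[[class_col]]
  levels <- sort(unique(as.character(cls)))
  out <- t(vapply(levels, function(l) {
    rows <- which(cls == l)
    if (!length(rows)) return(rep(NA_real_, length(selected)))
    colMeans(frame$matrix[rows, selected, drop = FALSE])
  }, numeric(length(selected))))
  attr(out, "flagged") <- levels[rowSums(is.na(out)) > 0]
  out
}
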