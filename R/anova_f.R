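## ANOVA-F feature scoring and top-k selection. These are the univariate
## filters the pipelines use to pick spectral pixels; infinite F-values
## (zero residual variance) are mapped to a large finite sentinel so that
## ranking stays total.

F_SENTINEL <- 1e12

#' Per-feature one-way ANOVA F statistic (classification targets)
#'
#' For each column of `X`, the ratio of between-class to within-class mean
#' squares of the feature across the class labels `y`. Features that are
#' constant within every class but differ between classes score the sentinel
#' `1e12`; features with zero between-class sum of squares score 0.
#'
#' @param X numeric matrix, rows = spectra, columns = features.
#' @param y class labels (factor or character), at least 2 classes with at
#'   least 2 rows each.
#' @return Numeric vector of F values, one per column.
#' @export
anova_f_classif <- function(X, y) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop("need at least two classes for the ANOVA-F score", call. = FALSE)
  if (any(table(y) < 2L))
    stop("every class needs at least two rows", call. = FALSE)
  n <- nrow(X)
  k <- nlevels(y)
  grand <- colMeans(X)
  ssb <- numeric(ncol(X))
  ssw <- numeric(ncol(X))
  for (lev in levels(y)) {
    rows <- which(y == lev)
    gm <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + length(rows) * (gm - grand)^2
    ssw <- ssw + colSums((X[rows, , drop = FALSE] -
                            matrix(gm, length(rows), ncol(X), byrow = TRUE))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb <= 0] <- 0
  f[!is.finite(f)] <- F_SENTINEL
  f
}

#' Per-feature F statistic for a numeric target (regression targets)
#'
#' Scores each column by its Pearson correlation with `y` through
#' `F = r^2 / (1 - r^2) * (n - 2)`, the F statistic of the univariate linear
#' regression. Zero-variance features score 0; perfectly correlated features
#' score the sentinel `1e12`.
#'
#' @param X numeric matrix.
#' @param y numeric target with non-zero variance, `length(y) >= 3`.
#' @return Numeric vector of F values, one per column.
#' @export
anova_f_regress <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stop("need at least 3 rows", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("target has zero variance; F score undefined", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  r <- rep(0, ncol(X))
  ok <- is.finite(sds) & sds > 0
  if (any(ok)) r[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], y))
  r2 <- pmin(r^2, 1)
  f <- r2 / (1 - r2) * (n - 2)
  f[!is.finite(f)] <- F_SENTINEL
  f[f > F_SENTINEL] <- F_SENTINEL
  f
}

#' Select the k top-scoring features
#'
#' Indices of the k largest scores, ordered by descending score with ties
#' broken by ascending column index.
#'
#' @param f numeric score vector.
#' @param k number of features to keep (1 <= k <= length(f)).
#' @return Integer vector of column indices, length k.
#' @export
select_top_k <- function(f, k) {
  if (!is.numeric(k) || k < 1) stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  if (k > length(f)) stop("k exceeds the feature count", call. = FALSE)
  order(-f, seq_along(f))[seq_len(k)]
}

#' Combine chained selection lists
#'
#' Deduplicated union of two index lists, preserving first-seen order: all of
#' `idx_a` in order, then the entries of `idx_b` not already present. Used to
#' merge the feature lists of the two independent F tests feeding the
#' regression chain.
#'
#' @param idx_a,idx_b integer index vectors.
#' @return Integer vector, the ordered union.
#' @export
combine_chain_features <- function(idx_a, idx_b) {
  out <- c(idx_a, idx_b)
  out[!duplicated(out)]
}
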