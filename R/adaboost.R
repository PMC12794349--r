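## AdaBoost.M1 over single-split decision stumps (binary classification).
## Each boosting round fits the best weighted threshold rule over all
## features by exhaustive search, then re-weights the training rows so the
## next stump concentrates on the misclassified ones.

# Best weighted stump: returns feature index, threshold, polarity (+1 means
# "predict level 2 when x > threshold") and its weighted error.
best_stump <- function(X, y01, w) {
  n <- nrow(X)
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- y01[ord]; ws <- w[ord]
    cum1 <- cumsum(ws * ys)          # class-1 weight at or below position i
    cum0 <- cumsum(ws * (1 - ys))
    tot1 <- cum1[n]; tot0 <- cum0[n]
    # cut index i in 1..n+1 places the threshold below position i (i = 1:
    # everything "above"; i = n+1: everything "below")
    err_plus <- c(tot0, cum1 + (tot0 - cum0))   # predict class 1 above the cut
    err_min <- pmin(err_plus, (tot0 + tot1) - err_plus)
    # cuts between tied values are not realisable threshold rules
    invalid <- c(FALSE, xs[-n] == xs[-1], FALSE)
    err_min[invalid] <- Inf
    i <- which.min(err_min)
    e <- err_min[i]
    if (e < best$err - 1e-12) {
      th <- if (i == 1L) xs[1] - 1
      else if (i == n + 1L) xs[n] + 1
      else (xs[i - 1L] + xs[i]) / 2
      ep <- err_plus[i]
      best <- list(err = e, feature = j, threshold = th,
                   polarity = if (ep <= (tot0 + tot1) - ep) 1 else -1)
    }
  }
  best
}

#' Fit an AdaBoost ensemble of decision stumps
#'
#' Binary AdaBoost.M1: each round selects the single-feature threshold rule
#' with the lowest weighted training error, weights it by
#' `0.5 * log((1 - err) / err)`, and re-weights the rows. Boosting stops
#' early when a stump is perfect or no better than chance.
#'
#' @param X numeric training matrix.
#' @param y two-level factor (or coercible).
#' @param n_stumps maximum number of boosting rounds.
#' @return Object of class `adaboost_stumps`.
#' @export
fit_adaboost_stumps <- function(X, y, n_stumps = 100L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("AdaBoost stumps require exactly two classes", call. = FALSE)
  y01 <- as.integer(y) - 1L
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_stumps)) {
    st <- best_stump(X, y01, w)
    pred <- as.integer((X[, st$feature] > st$threshold) == (st$polarity > 0))
    err <- max(st$err, 1e-10)
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    miss <- pred != y01
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
    if (st$err <= 0) break
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y)),
            class = "adaboost_stumps")
}

#' @rdname fit_adaboost_stumps
#' @param model a fitted `adaboost_stumps`.
#' @param newdata matrix of rows to classify.
#' @return `predict_adaboost_stumps` returns a factor of predicted classes.
#' @export
predict_adaboost_stumps <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  score <- rep(0, nrow(newdata))
  for (m in seq_along(model$stumps)) {
    st <- model$stumps[[m]]
    vote <- ifelse((newdata[, st$feature] > st$threshold) == (st$polarity > 0),
                   1, -1)
    score <- score + model$alphas[m] * vote
  }
  factor(model$levels[ifelse(score > 0, 2L, 1L)], levels = model$levels)
}
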