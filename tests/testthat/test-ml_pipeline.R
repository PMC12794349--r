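test_that("classification F scores match a per-column one-way ANOVA", {
  set.seed(1)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- rep(c("a", "b", "c"), each = 4)
  f <- anova_f_classif(X, y)
  oracle <- apply(X, 2, function(x) {
    unname(anova(lm(x ~ factor(y)))[["F value"]][1])
  })
  expect_equal(f, oracle, tolerance = 1e-10)

  # constant feature: zero between-class variation by convention
  Xc <- cbind(X, 1)
  expect_equal(anova_f_classif(Xc, y)[7], 0)

  # near-perfect separator dominates the ranking
  Xs <- cbind(X, c(rep(0, 4), rep(1, 4), rep(2, 4)) + rnorm(12, sd = 1e-8))
  f <- anova_f_classif(Xs, y)
  expect_identical(select_top_k(f, 1), 7L)
  expect_error(anova_f_classif(X, rep("a", 12)), "two classes")
})

test_that("regression F scores match the univariate linear-model F statistic", {
  set.seed(2)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10)
  f <- anova_f_regress(X, y)
  oracle <- apply(X, 2, function(x) {
    unname(summary(lm(y ~ x))$fstatistic["value"])
  })
  expect_equal(f, oracle, tolerance = 1e-8)

  # exact linear feature hits the sentinel and ranks first
  Xl <- cbind(X, 3 * y - 1)
  fl <- anova_f_regress(Xl, y)
  expect_identical(select_top_k(fl, 1), 6L)
  expect_equal(fl[6], 1e12)

  # orthogonal feature scores zero
  x_orth <- residuals(lm(rnorm(10) ~ y))
  expect_lt(anova_f_regress(cbind(x_orth), y)[1], 1e-20)
  expect_error(anova_f_regress(X, rep(1, 10)), "zero variance")
})

test_that("top-k selection is a sort with index tie-breaks", {
  expect_identical(select_top_k(c(3, 1, 2), 2), c(1L, 3L))
  expect_identical(select_top_k(rep(1, 5), 3), c(1L, 2L, 3L))
  set.seed(3)
  f <- runif(100)
  expect_setequal(select_top_k(f, 50), order(f, decreasing = TRUE)[1:50])
  expect_error(select_top_k(f, 0), "positive")
  expect_error(select_top_k(f, 101), "exceeds")
})

test_that("chain feature union deduplicates preserving first-seen order", {
  a <- c(5L, 2L, 9L); b <- c(2L, 7L, 5L, 1L)
  expect_identical(combine_chain_features(a, b), c(5L, 2L, 9L, 7L, 1L))
  expect_identical(combine_chain_features(a, a), a)
  expect_identical(length(combine_chain_features(1:5, 6:10)), 10L)
  # |A U B| = |A| + |B| - |A n B| over random index lists
  set.seed(4)
  for (i in 1:25) {
    a <- sample(50, sample(1:20, 1))
    b <- sample(50, sample(1:20, 1))
    expect_length(combine_chain_features(a, b),
                  length(a) + length(b) - length(intersect(a, b)))
  }
})

test_that("a 40+40 union with 33 shared features yields 47", {
  idx_a <- 1:40
  idx_b <- c(1:33, 101:107)
  expect_length(combine_chain_features(idx_a, idx_b), 47L)
})

test_that("single-setting tuning equals a direct fit and is deterministic", {
  lf <- small_labelled_frame("class")
  spec <- pipeline_spec("anova_f", "svc_rbf",
                        grid = param_grid(k = 50, C = 10, gamma = list("scale")))
  tuned <- inner_tune(lf$matrix, lf$row_meta$class, lf$group_of, spec, seed = 5)
  direct <- fit_pipeline(lf$matrix, lf$row_meta$class, spec, spec$grid[[1]],
                         seed = 5)
  expect_identical(predict(tuned, lf$matrix), predict(direct, lf$matrix))

  tuned2 <- inner_tune(lf$matrix, lf$row_meta$class, lf$group_of, spec, seed = 5)
  expect_identical(tuned$best_setting, tuned2$best_setting)
  expect_identical(predict(tuned, lf$matrix), predict(tuned2, lf$matrix))
  expect_error(inner_tune(lf$matrix[1:18, ], lf$row_meta$class[1:18],
                          lf$group_of[1:18], spec), "fewer groups")
})

test_that("a separable two-class frame reaches perfect inner accuracy", {
  lf <- small_labelled_frame("class", noise = 0)
  keep <- lf$row_meta$class != "mixed"
  spec <- pipeline_spec("anova_f", "svc_rbf",
                        grid = param_grid(k = c(25, 50), C = c(1, 10),
                                          gamma = list("scale")))
  # 4 proteins left; use 4 inner folds
  spec$inner_folds <- 4L
  fit <- inner_tune(lf$matrix[keep, ], droplevels(factor(lf$row_meta$class[keep])),
                    lf$group_of[keep], spec, seed = 6)
  expect_equal(max(fit$inner_scores), 1)
})

test_that("nested CV respects group boundaries and refits on training rows only", {
  lf <- small_labelled_frame("class")
  spec <- pipeline_spec("anova_f", "svc_rbf",
                        grid = param_grid(k = 25, C = c(1, 10),
                                          gamma = list("scale")))
  plan <- cv_plan("loo_by_group")
  res <- run_nested_cv(lf, spec, plan, seed = 9)
  expect_length(res$folds, 6)
  for (fi in seq_along(res$folds)) {
    f <- res$folds[[fi]]
    # group integrity: held-out protein absent from implied training set
    expect_setequal(unique(f$groups), f$test_proteins)
    tr <- !(lf$group_of %in% f$test_proteins)
    expect_identical(sort(unique(c(lf$group_of[tr], f$test_proteins))),
                     sort(unique(lf$group_of)))
    # no leakage: selection is reproducible from training rows alone
    refit <- inner_tune(lf$matrix[tr, ], factor(lf$row_meta$class[tr]),
                        lf$group_of[tr], spec, seed = 9 + fi)
    expect_identical(f$selected, refit$selection$indices)
    expect_identical(f$setting, refit$best_setting)
  }

  # random group splits: seeded fold membership is reproducible
  plan_r <- cv_plan("random_group_splits", n_splits = 3, test_frac = 0.34,
                    seed = 21)
  spec_r <- spec
  spec_r$inner_folds <- 4L      # four training proteins remain per split
  r1 <- run_nested_cv(lf, spec_r, plan_r, seed = 2)
  r2 <- run_nested_cv(lf, spec_r, plan_r, seed = 2)
  expect_identical(lapply(r1$folds, `[[`, "test_proteins"),
                   lapply(r2$folds, `[[`, "test_proteins"))
  for (f in r1$folds)
    expect_length(f$test_proteins, 2)  # 34% of 6 proteins
})

test_that("noiseless archetype classes are recovered perfectly by LOO", {
  lf <- small_labelled_frame("class", noise = 0)
  spec <- pipeline_spec("anova_f", "svc_rbf",
                        grid = param_grid(k = 50, C = c(1, 10, 100),
                                          gamma = list("scale")))
  res <- run_nested_cv(lf, spec, cv_plan("loo_by_group"), seed = 3)
  rep <- loo_report(res)
  expect_equal(rep$aggregate$accuracy, 1)
  expect_equal(rep$mean_protein_accuracy, 1)
})

test_that("the chain recovers targets that are linear in a few features", {
  set.seed(12)
  n <- 80
  X <- matrix(rnorm(n * 12), n, 12)
  groups <- rep(sprintf("g%02d", 1:10), each = 8)
  beta <- 40 + 10 * X[, 3] - 6 * X[, 7]
  alpha <- 50 - 0.8 * beta + 5 * X[, 11]
  targets <- data.frame(beta_pct = beta, alpha_pct = alpha)
  chain <- fit_regression_chain(X, targets, groups, k_grid = c(3),
                                predictor_grid = param_grid(C = c(10, 100),
                                                            gamma = list("scale")),
                                seed = 1)
  expect_lt(chain$train_rmse["beta_pct"], 0.15 * sd(beta))
  expect_lt(chain$train_rmse["alpha_pct"], 0.15 * sd(alpha))
  # prediction on the training rows reproduces the reported training RMSE
  pred <- predict_chain(chain, X)
  expect_equal(rmse(pred$beta_pct, beta),
               unname(chain$train_rmse["beta_pct"]), tolerance = 1e-9)

  # reversed chain order also fits
  rev_chain <- fit_regression_chain(X, targets[, 2:1], groups, k_grid = c(3),
                                    predictor_grid = param_grid(C = 10,
                                                                gamma = list("scale")),
                                    seed = 1)
  expect_s3_class(rev_chain, "fitted_chain")
  expect_identical(rev_chain$chain_order, c("alpha_pct", "beta_pct"))

  # union bound: with k features per test the merged list is at most 2k
  chain40 <- fit_regression_chain(cbind(X, matrix(rnorm(n * 60), n)), targets,
                                  groups, k_grid = c(40),
                                  predictor_grid = param_grid(C = 10,
                                                              gamma = list("scale")),
                                  seed = 1)
  expect_lte(length(chain40$feature_indices), 80)
  expect_error(fit_regression_chain(X, targets, groups, k_grid = c(100)),
               "exceeds")

  # chained prediction respects stage order: stage-2 consumes stage-1 output
  expect_identical(chain$chain_order, c("beta_pct", "alpha_pct"))
  expect_identical(names(predict_chain(chain, X)), chain$chain_order)
  expect_error(predict_chain(chain, X[, 1:5]), "mismatch")
})

test_that("sheet-registry override extends the parallel feature list", {
  lf <- small_labelled_frame("sheet_registry", noise = 0)
  fits <- fit_sheet_registry_models(lf$matrix, lf$row_meta$parallel_pct,
                                    lf$row_meta$antiparallel_pct, lf$group_of,
                                    k = 20, override_with_antiparallel = TRUE,
                                    predictor_grid = param_grid(C = 10,
                                                                gamma = list("scale")),
                                    seed = 2)
  if (sd(lf$row_meta$parallel_pct) == 0) {
    expect_s3_class(fits$parallel, "constant_predictor")
  } else {
    expect_true(all(fits$antiparallel_indices %in% fits$parallel_indices))
  }

  # all-zero parallel targets give a constant zero predictor
  fits0 <- fit_sheet_registry_models(lf$matrix, rep(0, nrow(lf$matrix)),
                                     lf$row_meta$antiparallel_pct, lf$group_of,
                                     k = 20,
                                     predictor_grid = param_grid(C = 10,
                                                                 gamma = list("scale")),
                                     seed = 2)
  expect_equal(rmse(predict(fits0$parallel, lf$matrix),
                    rep(0, nrow(lf$matrix))), 0)
})

test_that("adaboost stumps match the exhaustive single-threshold oracle", {
  set.seed(17)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- factor(ifelse(X[, 2] + rnorm(40, sd = 0.6) > 0, "pos", "neg"))
  model <- fit_adaboost_stumps(X, y, n_stumps = 1)
  acc <- mean(predict_adaboost_stumps(model, X) == y)

  # oracle: best accuracy of any threshold rule on any single feature
  best <- 0
  for (j in 1:4) for (th in sort(unique(X[, j]))) {
    for (pol in c(1, -1)) {
      pred <- if (pol > 0) X[, j] > th else X[, j] <= th
      best <- max(best, mean((as.integer(y) - 1L) == as.integer(pred)))
    }
  }
  expect_equal(acc, best)

  # boosting a separable 1-feature set reaches perfect training accuracy
  X1 <- matrix(seq(-1, 1, length.out = 30))
  y1 <- factor(ifelse(X1[, 1] > 0.1, "long", "short"))
  m1 <- fit_adaboost_stumps(X1, y1, n_stumps = 5)
  expect_equal(mean(predict_adaboost_stumps(m1, X1) == y1), 1)

  # seeded determinism through the pipeline wrapper
  lf <- small_labelled_frame("helix_length", specs = sample_structures(8, seed = 2))
  grid <- param_grid(k = 25, n_stumps = c(10, 25))
  expect_length(unique(lf$row_meta$helix_length_class), 2)
  f1 <- fit_helix_length_classifier(lf$matrix, lf$row_meta$helix_length_class,
                                    lf$group_of, grid = grid, seed = 4)
  f2 <- fit_helix_length_classifier(lf$matrix, lf$row_meta$helix_length_class,
                                    lf$group_of, grid = grid, seed = 4)
  expect_identical(predict(f1, lf$matrix), predict(f2, lf$matrix))
  expect_error(fit_helix_length_classifier(lf$matrix,
                                           rep("short_helices", nrow(lf$matrix)),
                                           lf$group_of), "single class")
})
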