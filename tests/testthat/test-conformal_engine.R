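test_that("all-knn removes nothing from perfectly separated classes", {
  toy <- make_toy_classes(12, sep = 50, seed = 2)
  rb <- rebalance(toy$X, toy$y, method = "all-knn")
  expect_equal(length(rb$kept), nrow(toy$X))
})

test_that("instance hardness threshold leaves balanced input unchanged", {
  toy <- make_toy_classes(10, sep = 1, seed = 3)
  rb <- rebalance(toy$X, toy$y, method = "instance-hardness-threshold")
  expect_equal(as.vector(table(rb$y)), c(10L, 10L))
  expect_equal(length(rb$kept), 20L)
})

test_that("rebalancing an overlapping 23/11 cohort shrinks only the majority", {
  set.seed(4)
  y <- factor(c(rep("survivor", 23), rep("non-survivor", 11)),
              levels = c("survivor", "non-survivor"))
  X <- cbind(f1 = rnorm(34) + (y == "non-survivor") * 0.5,
             f2 = rnorm(34))
  for (method in c("all-knn", "instance-hardness-threshold")) {
    rb <- rebalance(X, y, method = method, seed = 9)
    expect_equal(sum(rb$y == "non-survivor"), 11L, label = method)
    expect_lt(sum(rb$y == "survivor"), 23L)
    expect_gte(sum(rb$y == "survivor"), 11L)
  }
  expect_warning(rebalance(X[c(1, 2, 24), ], y[c(1, 2, 24)]), "fewer than 2")
})

test_that("k-best selection ranks planted effects above noise and is stable", {
  toy <- make_toy_classes(30, n_noise = 20, sep = 3, seed = 5)
  sel <- select_k_best(toy$X, toy$y, k = 2)
  expect_setequal(sel, c("s1", "s2"))
  # identity at k = feature count
  expect_setequal(select_k_best(toy$X, toy$y, k = ncol(toy$X)),
                  colnames(toy$X))
  # constant features are never preferred over varying ones
  Xc <- cbind(toy$X, const = 1)
  expect_false("const" %in% select_k_best(Xc, toy$y, k = ncol(Xc) - 1))
  # regression scoring
  y_num <- toy$X[, "s1"] * 2 + rnorm(60, sd = 0.1)
  expect_equal(select_k_best(toy$X, y_num, k = 1), "s1")
})

test_that("the conformal p-value and calibration quantile follow the rank conventions", {
  # (#scores >= alpha + 1) / (n + 1)
  expect_equal(protomort:::conformal_pvalue(0.25, c(0.1, 0.2, 0.3, 0.4)),
               3 / 5)
  expect_equal(protomort:::conformal_pvalue(0.05, c(0.1, 0.2, 0.3, 0.4)), 1)
  expect_equal(protomort:::conformal_pvalue(0.5, c(0.1, 0.2, 0.3, 0.4)),
               1 / 5)
  # ties count as at least as nonconforming
  expect_equal(protomort:::conformal_pvalue(0.2, c(0.1, 0.2, 0.3, 0.4)),
               4 / 5)
  # smallest score at rank ceiling((n+1) * confidence)
  expect_equal(protomort:::calib_quantile(c(1, 2, 3, 4), 0.8), 4)
  expect_equal(protomort:::calib_quantile(c(1, 2, 3, 4), 0.5), 3)
  expect_equal(protomort:::calib_quantile(c(1, 2, 3, 4), 0.95), 4)
})

test_that("classifier bundles are reproducible and their p-values aggregate by median", {
  toy <- make_toy_classes(15, sep = 1.5, seed = 6)
  cfg <- model_config(seed = 46, n_trees = 100)
  b1 <- fit_acp_classifier(toy$X, toy$y, cfg)
  b2 <- fit_acp_classifier(toy$X, toy$y, cfg)
  p1 <- predict_set(b1, toy$X)
  p2 <- predict_set(b2, toy$X)
  expect_identical(p1, p2)

  sub <- attr(p1, "submodel_pvalues")
  for (ci in 1:2) {
    agg <- p1[[ci]]
    lo <- apply(sub[, ci, ], 1, min)
    hi <- apply(sub[, ci, ], 1, max)
    expect_true(all(agg >= lo - 1e-12 & agg <= hi + 1e-12))
    expect_true(all(agg >= 0 & agg <= 1))
  }
  expect_true(all(p1$conclusive == (nchar(gsub("[^|]", "", p1$set)) == 0 &
                                      p1$set != "")))
})

test_that("prediction sets threshold aggregated p-values at 1 - confidence", {
  toy <- make_toy_classes(25, sep = 4, seed = 8)
  cfg <- model_config(seed = 46, n_trees = 100)
  b <- fit_acp_classifier(toy$X, toy$y, cfg)
  pr <- predict_set(b, toy$X)
  thr <- 1 - cfg$confidence
  in_surv <- pr$p_survivor > thr
  in_dead <- pr$p_non_survivor > thr
  want <- ifelse(in_surv & in_dead, "survivor|non-survivor",
                 ifelse(in_surv, "survivor",
                        ifelse(in_dead, "non-survivor", "")))
  expect_equal(pr$set, want)
  # strongly separated training data is mostly conclusive and correct
  expect_gt(mean(pr$conclusive), 0.5)
  concl <- pr$conclusive
  expect_gt(mean(pr$set[concl] == as.character(toy$y)[concl]), 0.9)
})

test_that("a constant outcome yields near-degenerate intervals containing it", {
  toy <- make_toy_classes(10, seed = 10)
  y <- rep(1000, 20)
  b <- fit_acp_regressor(toy$X, y, model_config(n_trees = 50))
  iv <- predict_interval(b, toy$X)
  expect_true(all(iv$lo <= 1000 & 1000 <= iv$hi))
  expect_lt(max(iv$hi - iv$lo), 1e-6)
})

test_that("regression intervals are reproducible and ordered", {
  set.seed(11)
  n <- 40
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 800 + 200 * X[, "a"] + rnorm(n, sd = 50)
  y <- pmax(y, 1)
  cfg <- model_config(n_trees = 100, seed = 46)
  i1 <- predict_interval(fit_acp_regressor(X, y, cfg), X)
  i2 <- predict_interval(fit_acp_regressor(X, y, cfg), X)
  expect_identical(i1, i2)
  expect_true(all(i1$lo <= i1$predicted & i1$predicted <= i1$hi))
  expect_true(all(i1$conclusive))
})

test_that("cross-validation with folds = n predicts every sample exactly once", {
  toy <- make_toy_classes(5, n_noise = 2, seed = 12)
  cfg <- model_config(n_trees = 50, k_best = 2, seed = 46,
                      rebalance = "none")
  cv <- cross_validate(toy$X, toy$y, cfg, folds = 10L, n_perm = 2L)
  expect_equal(nrow(cv$predictions), 10L)
  expect_equal(sort(cv$predictions$row), 1:10)
  expect_equal(sort(unique(cv$fold)), 1:10)
})

test_that("cross-validated importances separate signal from noise", {
  toy <- make_toy_classes(20, n_noise = 6, sep = 3, seed = 13)
  cfg <- model_config(n_trees = 100, k_best = 4, seed = 46,
                      rebalance = "none")
  cv <- cross_validate(toy$X, toy$y, cfg, folds = 5L, n_perm = 10L)
  expect_equal(cv$task, "classification")
  imp <- cv$importance
  expect_true(all(c("s1", "s2") %in% names(imp)[1:3]))
  # signal features selected in every fold
  expect_true(all(vapply(cv$selected, function(f) "s1" %in% f, TRUE)))
})

test_that("label permutation nulls out accuracy and importances", {
  toy <- make_toy_classes(20, n_noise = 6, sep = 3, seed = 14)
  y_perm <- with(list(), {set.seed(99); sample(toy$y)})
  cfg <- model_config(n_trees = 100, k_best = 4, seed = 46,
                      rebalance = "none")
  cv <- cross_validate(toy$X, y_perm, cfg, folds = 5L, n_perm = 10L)
  perf <- confusion_metrics(cv$predictions, as.character(y_perm))
  # conclusive accuracy hovers near chance for balanced permuted labels
  if (!is.na(perf$se) && !is.na(perf$sp)) {
    acc <- (perf$tp + perf$tn) / max(1, perf$tp + perf$tn + perf$fp + perf$fn)
    expect_lt(acc, 0.8)
  }
  # per-fold accuracy moves in steps of 1/8, so individual importances are
  # coarse; their average over features should sit near zero
  expect_lt(abs(mean(cv$importance)), 0.15)
  expect_lt(max(abs(cv$importance)), 0.35)
})
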