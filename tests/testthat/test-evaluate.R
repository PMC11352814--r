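mk_preds <- function(set, conclusive) {
  data.frame(set = set, conclusive = conclusive, stringsAsFactors = FALSE)
}

test_that("confusion metrics handle the all-correct and mixed-coverage cases", {
  truth <- c(rep("non-survivor", 4), rep("survivor", 6))
  pr <- mk_preds(truth, rep(TRUE, 10))
  s <- confusion_metrics(pr, truth)
  expect_equal(s$se, 1); expect_equal(s$sp, 1)
  expect_equal(s$mcc, 1); expect_equal(s$coverage, 1)

  # TP 7, FN 2, TN 17, FP 0, 8 inconclusive of 34
  truth <- c(rep("non-survivor", 9), rep("survivor", 17), rep("survivor", 5),
             rep("non-survivor", 3))
  set <- c(rep("non-survivor", 7), rep("survivor", 2), rep("survivor", 17),
           rep("survivor|non-survivor", 8))
  concl <- c(rep(TRUE, 26), rep(FALSE, 8))
  s <- confusion_metrics(mk_preds(set, concl), truth)
  expect_equal(s$tp, 7L); expect_equal(s$fn, 2L)
  expect_equal(s$tn, 17L); expect_equal(s$fp, 0L)
  expect_equal(s$se, 7 / 9, tolerance = 1e-12)
  expect_equal(s$sp, 1)
  expect_equal(s$coverage, 26 / 34, tolerance = 1e-12)
})

test_that("zero conclusive predictions are flagged, random ones give MCC near 0", {
  truth <- rep(c("survivor", "non-survivor"), 10)
  expect_warning(
    s <- confusion_metrics(mk_preds(rep("survivor|non-survivor", 20),
                                    rep(FALSE, 20)), truth),
    "no conclusive")
  expect_true(is.na(s$se))
  expect_equal(s$coverage, 0)

  set.seed(31)
  mccs <- replicate(40, {
    truth <- sample(c("survivor", "non-survivor"), 60, replace = TRUE)
    guess <- sample(c("survivor", "non-survivor"), 60, replace = TRUE)
    confusion_metrics(mk_preds(guess, rep(TRUE, 60)), truth)$mcc
  })
  expect_lt(abs(mean(mccs)), 0.07)
})

test_that("MCC is invariant under a simultaneous class and prediction swap", {
  truth <- c(rep("non-survivor", 8), rep("survivor", 12))
  set.seed(5)
  guess <- sample(c("survivor", "non-survivor"), 20, replace = TRUE)
  m1 <- confusion_metrics(mk_preds(guess, rep(TRUE, 20)), truth,
                          positive = "non-survivor")$mcc
  m2 <- confusion_metrics(mk_preds(guess, rep(TRUE, 20)), truth,
                          positive = "survivor")$mcc
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("prevalence re-adjustment reproduces the Bayes identities", {
  a <- adjust_prevalence(0.78, 1.00, 0.47)
  expect_equal(a$acc, 0.78 * 0.47 + 1.00 * 0.53, tolerance = 1e-12)
  expect_equal(round(a$acc, 2), 0.90)
  expect_equal(round(a$npv, 2), 0.84)
  expect_equal(a$ppv, 1)

  b <- adjust_prevalence(1.00, 0.90, 0.47)
  expect_equal(round(b$ppv, 2), 0.90)
  expect_equal(round(b$acc, 2), 0.95)

  p <- adjust_prevalence(1, 1, 0.3)
  expect_equal(c(p$ppv, p$npv, p$acc), c(1, 1, 1))
  expect_error(adjust_prevalence(0.9, 0.9, 1.2), "prevalence")
})

test_that("re-adjustment at the empirical prevalence recovers the raw confusion metrics", {
  set.seed(8)
  truth <- sample(c("survivor", "non-survivor"), 50, replace = TRUE,
                  prob = c(0.7, 0.3))
  guess <- ifelse(runif(50) < 0.8, truth,
                  ifelse(truth == "survivor", "non-survivor", "survivor"))
  s <- confusion_metrics(mk_preds(guess, rep(TRUE, 50)), truth)
  adj <- adjust_prevalence(s$se, s$sp, s$prevalence_conclusive)
  expect_equal(adj$ppv, s$tp / (s$tp + s$fp), tolerance = 1e-12)
  expect_equal(adj$npv, s$tn / (s$tn + s$fn), tolerance = 1e-12)
  expect_equal(adj$acc, (s$tp + s$tn) / 50, tolerance = 1e-12)
})

test_that("accuracy is linear and predictive values monotone in prevalence", {
  grid <- seq(0.05, 0.95, by = 0.05)
  vals <- lapply(grid, function(p) adjust_prevalence(0.8, 0.9, p))
  acc <- vapply(vals, `[[`, 0, "acc")
  ppv <- vapply(vals, `[[`, 0, "ppv")
  npv <- vapply(vals, `[[`, 0, "npv")
  expect_equal(diff(acc, differences = 2), rep(0, length(grid) - 2),
               tolerance = 1e-10)
  expect_true(all(diff(ppv) >= -1e-12))
  expect_true(all(diff(npv) <= 1e-12))
})

test_that("regression metrics follow their definitions", {
  y <- c(1, 2, 3, 4)
  m <- regression_metrics(y, yhat_fit = c(1.1, 1.9, 3.2, 3.8))
  expect_equal(m$r2, 1 - 0.10 / 5.0, tolerance = 1e-12)

  perfect <- regression_metrics(y, yhat_fit = y, yhat_oof = y,
                                intervals = data.frame(lo = y - 1, hi = y + 1))
  expect_equal(perfect$r2, 1); expect_equal(perfect$q2, 1)
  expect_equal(perfect$conformal_accuracy, 1)

  # out-of-fold mean-only predictions can never beat the mean: Q2 <= 0
  set.seed(2)
  yy <- rnorm(30)
  loo_means <- vapply(1:30, function(i) mean(yy[-i]), 0)
  m2 <- regression_metrics(yy, yhat_oof = loo_means)
  expect_lte(m2$q2, 0)

  expect_warning(mc <- regression_metrics(rep(3, 5), yhat_fit = rep(3, 5)),
                 "constant")
  expect_true(is.na(mc$r2))
})

test_that("cohort rates reproduce yearly cumulative and stratified mortality", {
  md <- data.frame(
    patient = paste0("P", 1:34),
    status = c(rep("survivor", 23), rep("non-survivor", 11)),
    days_survival = c(rep(1460L, 23),
                      c(200, 300, 500, 600, 700, 900, 1000, 1100, 1200,
                        1300, 1400)),
    frequent_exacerbator = c(rep(TRUE, 7), rep(FALSE, 16),
                             rep(TRUE, 7), rep(FALSE, 4)),
    stringsAsFactors = FALSE
  )
  r <- cohort_rates(md)
  expect_equal(unname(r$yearly_mortality_pct["year4"]), 32)
  expect_equal(r$fe_mortality_pct, 50)
  expect_equal(r$nonfe_mortality_pct, 20)
  expect_true(all(diff(r$yearly_mortality_pct) >= 0))

  md0 <- md; md0$status <- "survivor"; md0$days_survival <- 1460L
  expect_equal(unname(cohort_rates(md0)$yearly_mortality_pct),
               rep(0, 4))

  md_na <- md; md_na$days_survival[1] <- NA
  expect_warning(cohort_rates(md_na), "excluded")
})

test_that("model summaries carry re-adjusted values at both prevalences", {
  truth <- c(rep("non-survivor", 9), rep("survivor", 17))
  set <- c(rep("non-survivor", 7), rep("survivor", 2), rep("survivor", 17))
  s <- confusion_metrics(mk_preds(set, rep(TRUE, 26)), truth)
  row <- summarize_model(s)
  expect_equal(row$acc_reported,
               adjust_prevalence(s$se, s$sp, 0.47)$acc, tolerance = 1e-12)
  expect_equal(row$npv_cohort,
               adjust_prevalence(s$se, s$sp, 0.32)$npv, tolerance = 1e-12)
})
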