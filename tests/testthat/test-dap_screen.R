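test_that("quantitative test handles identity and textbook cases", {
  r <- quantitative_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$log2fc, 0)
  expect_equal(r$p_value, 1, tolerance = 1e-9)

  # pooled-variance t computed by hand: diff 4, s2 = 5/3, t = 4.3818, 6 df
  r <- quantitative_test(c(10, 11, 12, 13), c(14, 15, 16, 17))
  expect_equal(r$test, "t")
  expect_equal(r$statistic, 4 / sqrt((5 / 3) * (1 / 4 + 1 / 4)),
               tolerance = 1e-6)
  expect_equal(r$statistic, 4.38178, tolerance = 1e-4)
  expect_equal(r$p_value, 2 * pt(-r$statistic, df = 6), tolerance = 1e-9)
  expect_equal(r$log2fc, 4)
})

test_that("percent change and log2FC are a bijection", {
  expect_equal(quant_pct <- (2^(-0.2264) - 1) * 100, -14.52, tolerance = 1e-3)
  r <- quantitative_test(c(5, 6, 7, 8), c(5.2, 6.2, 6.9, 8.1))
  expect_equal(log2(1 + r$pct_change / 100), r$log2fc, tolerance = 1e-6)
  # inversion on a grid of effects
  for (fc in c(-3, -0.2264, -0.01, 0.4, 2.5)) {
    pct <- (2^fc - 1) * 100
    expect_equal(log2(1 + pct / 100), fc, tolerance = 1e-10)
  }
})

test_that("phi coefficient matches the direct 2x2 formula and its sign convention", {
  # 9/23 survivors detected, 0/11 non-survivors: less present in deceased
  expect_equal(phi_coefficient(9, 23, 0, 11), -0.4149, tolerance = 1e-4)
  expect_equal(phi_coefficient(9, 23, 0, 11), oracle_phi(9, 23, 0, 11))
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    expect_equal(phi_coefficient(a, n1, b, n2), oracle_phi(a, n1, b, n2),
                 tolerance = 1e-12)
  }
})

test_that("degenerate detection tables give phi 0 and p 1", {
  r <- qualitative_test(0, 23, 0, 11)
  expect_equal(r$mcc, 0)
  expect_equal(r$p_value, 1)
  r <- qualitative_test(23, 23, 11, 11)
  expect_equal(r$mcc, 0)
  expect_equal(r$p_value, 1)
})

test_that("Barnard p-values agree with the enumeration oracle", {
  cases <- list(c(9, 23, 0, 11), c(19, 23, 2, 11), c(3, 10, 9, 12),
                c(0, 8, 5, 7), c(12, 25, 12, 25), c(1, 5, 4, 5))
  for (cs in cases) {
    got <- barnard_test(cs[1], cs[2], cs[3], cs[4])$p_value
    want <- oracle_barnard(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, want, tolerance = 1e-3,
                 label = paste("table", paste(cs, collapse = "/")))
  }
})

test_that("swapping the groups negates phi and preserves the Barnard p", {
  set.seed(7)
  for (i in 1:10) {
    n1 <- sample(3:23, 1); n2 <- sample(3:11, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    r1 <- qualitative_test(a, n1, b, n2)
    r2 <- qualitative_test(b, n2, a, n1)
    expect_equal(r1$mcc, -r2$mcc, tolerance = 1e-12)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
    expect_gte(r1$p_value, 0)
    expect_lte(r1$p_value, 1)
  }
})

test_that("screening partitions proteins into disjoint branches", {
  coh <- generate_cohort(cohort_spec(n_proteins_lcms = 60, n_proteins_mux = 10,
                                     n_quant_dap = 5, n_qual_dap = 5,
                                     seed = 13))
  pm <- impute_min95(compute_coverage_and_route(coh$abundance,
                                                coh$metadata$status))
  res <- screen_all(pm)
  expect_equal(nrow(res), 70L)
  expect_equal(anyDuplicated(res$protein), 0L)
  expect_true(all(res$branch %in% c("quantitative", "qualitative", "excluded")))
  # quantitative records carry log2FC, qualitative carry MCC, never both
  expect_true(all(is.na(res$mcc[res$branch == "quantitative"])))
  expect_true(all(is.na(res$log2fc[res$branch == "qualitative"])))
  # emitted percent changes invert to their log2FC
  q <- res[res$branch == "quantitative", ]
  expect_equal(log2(1 + q$pct_change / 100), q$log2fc, tolerance = 1e-6)
  expect_equal(attr(res, "n_dap"), sum(res$significant))
})

test_that("without missingness the qualitative branch is empty", {
  coh <- generate_cohort(cohort_spec(n_proteins_lcms = 30, n_proteins_mux = 0,
                                     missing_rate = 0, censor_quantile = 0,
                                     detect_prob_present = 1,
                                     detect_prob_absent = 1, seed = 17))
  pm <- impute_min95(compute_coverage_and_route(coh$abundance,
                                                coh$metadata$status))
  res <- screen_all(pm)
  expect_equal(sum(res$branch == "qualitative"), 0L)
})

test_that("strong planted presence/absence patterns reach qualitative significance", {
  coh <- generate_cohort(cohort_spec(n_proteins_lcms = 30, n_proteins_mux = 0,
                                     n_quant_dap = 0, n_qual_dap = 5,
                                     detect_prob_present = 1,
                                     detect_prob_absent = 0,
                                     missing_rate = 0, censor_quantile = 0,
                                     seed = 19))
  pm <- impute_min95(compute_coverage_and_route(coh$abundance,
                                                coh$metadata$status))
  res <- screen_all(pm)
  planted <- res[res$protein %in% coh$truth$qualitative$protein, ]
  expect_true(all(planted$branch == "qualitative"))
  expect_true(all(planted$significant))
  # recovered direction matches the planted one
  want <- coh$truth$qualitative$direction[
    match(planted$protein, coh$truth$qualitative$protein)]
  expect_equal(planted$direction, want)
})
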