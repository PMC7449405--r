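# Transformation, linear models, meta-analysis and multiple-testing
# thresholds.

test_that("rank inverse normal transformation follows the Blom formula", {
  out <- rank_inverse_normal(c(5, 1, 9))
  # rank 2 of 3 -> (2 - 3/8) / 3.25 = 0.5 -> qnorm(0.5) = 0
  expect_equal(out[1], 0)
  expect_equal(out[2], qnorm((1 - 3 / 8) / 3.25))
  expect_equal(out[3], qnorm((3 - 3 / 8) / 3.25))

  x <- c(3.2, -1, 7, 7, 0.5, 12, -4)
  y <- rank_inverse_normal(x)
  expect_equal(cor(x, y, method = "spearman"), 1)
  # symmetric ranks map symmetrically about zero (odd n, no ties)
  expect_equal(sum(rank_inverse_normal(c(10, 20, 30, 40, 50))), 0)
  # ties get average ranks -> equal transformed values
  expect_equal(y[3], y[4])

  expect_error(rank_inverse_normal(c(2, 2, 2)), "identical")
  expect_error(rank_inverse_normal(c(1, 2)), "at least 3")
  expect_error(rank_inverse_normal(c(1, 2, NA)), "finite")
})

test_that("fit_linear_model is exact OLS with rank-deficiency detection", {
  x <- seq(-3, 3, length.out = 20)
  fit <- suppressWarnings(fit_linear_model(2 * x, data.frame(x = x)))
  expect_equal(fit$beta[fit$term == "x"], 2)
  expect_equal(fit$se[fit$term == "x"], 0, tolerance = 1e-10)

  fit0 <- fit_linear_model(c(4, 6, 11), data.frame(z = c(0, 0, 0))[, 0, drop = FALSE])
  expect_equal(fit0$beta[1], 7)  # intercept-only: the sample mean

  expect_error(fit_linear_model(rnorm(10),
                                data.frame(a = 1:10, b = 2 * (1:10))),
               "collinear.*b")

  # formula interface
  d <- data.frame(y = 3 + 1.5 * (1:10), x = 1:10)
  ff <- suppressWarnings(fit_linear_model(y ~ x, d))
  expect_equal(ff$beta[ff$term == "x"], 1.5)
})

test_that("fixed-effects meta matches hand inverse-variance computation", {
  single <- fixed_effects_meta(data.frame(cohort = "a", beta = 0.3, se = 0.1))
  expect_equal(single$beta_pooled, 0.3)
  expect_equal(single$se_pooled, 0.1)

  two <- fixed_effects_meta(data.frame(cohort = c("a", "b"),
                                       beta = c(0.2, 0.6), se = c(0.1, 0.2)))
  expect_equal(two$beta_pooled, (100 * 0.2 + 25 * 0.6) / 125)  # 0.28
  expect_equal(two$se_pooled, 125^-0.5)                        # ~0.08944

  # equal-se studies pool to the arithmetic mean
  eq <- fixed_effects_meta(data.frame(cohort = letters[1:4],
                                      beta = c(0.1, 0.3, -0.2, 0.6),
                                      se = 0.15))
  expect_equal(eq$beta_pooled, mean(c(0.1, 0.3, -0.2, 0.6)))

  # pooled variance never exceeds the smallest study variance
  expect_lte(two$se_pooled, min(0.1, 0.2))
  expect_error(fixed_effects_meta(data.frame(cohort = "a", beta = 1, se = 0)),
               "positive")
})

test_that("meta of a study with itself k times shrinks the SE by sqrt(k)", {
  est <- data.frame(cohort = paste0("rep", 1:9), beta = 0.42, se = 0.11)
  m <- fixed_effects_meta(est)
  expect_equal(m$beta_pooled, 0.42)
  expect_equal(m$se_pooled, 0.11 / 3)
})

test_that("DerSimonian-Laird matches its literal transcription to 1e-10", {
  est <- data.frame(cohort = c("g", "e", "m"),
                    beta = c(0.45, 0.10, 0.80),
                    se = c(0.05, 0.12, 0.09))
  mine <- random_effects_meta(est)
  oracle <- oracle_dl_meta(est$beta, est$se)
  expect_equal(mine$beta_pooled, oracle$beta, tolerance = 1e-10)
  expect_equal(mine$se_pooled, oracle$se, tolerance = 1e-10)
  expect_equal(mine$tau2, oracle$tau2, tolerance = 1e-10)
  expect_equal(mine$q_stat, oracle$q, tolerance = 1e-10)
  expect_gt(mine$tau2, 0)

  # independent cross-check against the reference meta-analysis package
  rma <- metafor::rma(yi = est$beta, sei = est$se, method = "DL")
  expect_equal(mine$beta_pooled, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(mine$se_pooled, rma$se, tolerance = 1e-8)
  expect_equal(mine$tau2, rma$tau2, tolerance = 1e-8)
})

test_that("homogeneous studies truncate tau^2 to zero (random = fixed)", {
  same <- data.frame(cohort = c("a", "b", "c"), beta = 0.3, se = 0.1)
  re <- random_effects_meta(same)
  fe <- fixed_effects_meta(same)
  expect_equal(re$tau2, 0)
  expect_equal(re$beta_pooled, fe$beta_pooled)
  expect_equal(re$se_pooled, fe$se_pooled)

  # mild heterogeneity with Q <= k-1 also truncates
  mild <- data.frame(cohort = c("a", "b"), beta = c(0.30, 0.31), se = 0.2)
  re2 <- random_effects_meta(mild)
  expect_equal(re2$tau2, 0)
  expect_equal(re2$se_pooled, fixed_effects_meta(mild)$se_pooled)

  expect_error(random_effects_meta(same[1, ]), "at least 2")
})

test_that("random-effects SE is never below the fixed-effects SE", {
  for (s in 1:5) {
    est <- adipoquant:::with_seed(s, data.frame(
      cohort = letters[1:4], beta = rnorm(4, 0.3, 0.4),
      se = runif(4, 0.05, 0.3)))
    expect_gte(random_effects_meta(est)$se_pooled + 1e-12,
               fixed_effects_meta(est)$se_pooled)
  }
})

test_that("I^2 follows the truncated (Q - df)/Q formula", {
  expect_equal(i_squared(5, 5), 0)
  expect_equal(i_squared(10, 5), 50)
  expect_equal(i_squared(3, 5), 0)
  expect_error(i_squared(3, 0), "df")
})

test_that("Bonferroni thresholds reproduce the printed values", {
  expect_equal(bonferroni_threshold(0.05, 19, signif_digits = 2), 2.6e-3)
  expect_equal(bonferroni_threshold(5e-8, 2), 2.5e-8)
  expect_equal(bonferroni_threshold(0.05, 6, signif_digits = 1), 0.008)
  expect_equal(bonferroni_threshold(0.07, 1), 0.07)
})

test_that("meta_association recovers planted effects across cohorts", {
  tabs <- lapply(1:3, function(i)
    simulate_cohort_phenotypes(cohort_spec(n_samples = 400L, seed = 100L + i,
                                           cohort = paste0("c", i))))
  data <- do.call(rbind, tabs)
  depot <- meta_association(data, response = "mean_area", term = "depotvisc",
                            covariates = c("sex", "age", "BMI"))
  expect_equal(nrow(depot$per_cohort), 3L)
  expect_lt(abs(depot$meta$beta_pooled - (-0.55)), 3 * depot$meta$se_pooled)
  expect_s3_class(depot$meta, "meta_result")
  expect_equal(depot$meta$model, "random")
})
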