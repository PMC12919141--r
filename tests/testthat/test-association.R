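test_that("trait models recover coefficients and flag separation", {
  withr::with_seed(40, {
    n <- 2000
    d <- tibble::tibble(participant = as.character(1:n),
                        score = rnorm(n),
                        age = runif(n, 40, 90),
                        sex = factor(sample(c("female", "male"), n, TRUE)))
    d$y <- 2 * d$score + rnorm(n, 0, 0.01)
    fit <- fit_trait_model(d, "y", "score", covariates = c("age", "sex"))
    expect_equal(fit$estimate, 2, tolerance = 0.01)
    expect_equal(fit$family, "gaussian")
    # binary trait routes to logistic regression
    d$bin <- rbinom(n, 1, plogis(d$score))
    fitb <- fit_trait_model(d, "bin", "score", covariates = c("age", "sex"))
    expect_equal(fitb$family, "binomial")
    expect_equal(fitb$estimate, 1, tolerance = 0.2)
    expect_false(fitb$separation)
    # perfect separation is flagged, not silently converged
    d$sep <- as.integer(d$score > 0)
    fits <- fit_trait_model(d, "sep", "score", covariates = NULL)
    expect_true(fits$separation)
    expect_error(fit_trait_model(dplyr::mutate(d, score = 1), "y", "score",
                                 covariates = NULL),
                 "constant")
  })
})

test_that("null predictors are calibrated at the nominal level", {
  withr::with_seed(41, {
    pvals <- replicate(200, {
      d <- tibble::tibble(y = rnorm(60), score = rnorm(60))
      fit_trait_model(d, "y", "score", covariates = NULL)$p_value
    })
    expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.045)
  })
})

test_that("cross-validation hits the noiseless limit and is reproducible", {
  d <- make_mini_cohort(n = 300, p = 5, n_signal = 2, beta = 1,
                        noise_sd = 1e-8, seed = 42)
  d$score <- d$P001 + d$P002
  cv1 <- cross_validate(d, "trait", "score", seed = 7)
  cv2 <- cross_validate(d, "trait", "score", seed = 7)
  expect_identical(tibble::as_tibble(cv1), tibble::as_tibble(cv2))
  expect_equal(nrow(cv1), 10)
  expect_gte(mean(cv1$r2), 0.99)
  g <- glance(cv1)
  expect_equal(g$mean_r2, mean(cv1$r2))
})

test_that("binary cross-validation reports AUC and pseudo-R2 and redraws", {
  withr::with_seed(43, {
    n <- 250
    d <- tibble::tibble(participant = as.character(1:n), score = rnorm(n))
    d$y <- rbinom(n, 1, plogis(2 * d$score - 2.5))
    cv <- cross_validate(d, "y", "score", n_iter = 5, seed = 3)
    expect_true(all(cv$auc > 0.5))
    expect_true(all(!is.na(cv$pseudo_r2)))
    expect_true(all(is.na(cv$r2)))
  })
})

test_that("paired metric comparison gates on normality and handles degeneracy", {
  a <- c(0.5, 0.52, 0.48, 0.51, 0.49, 0.5, 0.53, 0.47, 0.5, 0.51)
  same <- compare_paired_metrics(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$method, "zero-variance")
  shifted <- compare_paired_metrics(a, a + 0.1)
  expect_equal(shifted$mean_difference, 0.1)
  expect_equal(shifted$method, "zero-variance")
  withr::with_seed(44, {
    b <- a - 0.1 + rnorm(10, 0, 0.005)
    cmp <- compare_paired_metrics(a, b)
    expect_true(cmp$method %in% c("paired t-test", "wilcoxon signed-rank"))
    expect_lt(cmp$p_value, 0.01)
    expect_lt(cmp$mean_difference, 0)
  })
  expect_error(compare_paired_metrics(a, a[1:3]), "equal length")
})

test_that("paired t-test has power at well-separated metric distributions", {
  withr::with_seed(45, {
    hits <- replicate(100, {
      a <- rnorm(10, 0.5, 0.01)
      b <- rnorm(10, 0.4, 0.01)
      cmp <- compare_paired_metrics(a, b)
      cmp$p_value < 0.01
    })
    expect_gte(mean(hits), 0.95)
  })
})

test_that("LMG importances match the orthogonal closed form and sum rule", {
  withr::with_seed(46, {
    n <- 4000
    A <- rnorm(n)
    B <- rnorm(n)
    A <- as.numeric(scale(resid(lm(A ~ B)))) # exactly orthogonal in sample
    y <- 0.6 * A + rnorm(n, 0, sqrt(1 - 0.36))
    d <- tibble::tibble(y = y, A = A, B = B)
    ri <- relative_importance(d, "y", "A", "B", covariates = NULL,
                              n_boot = 100, seed = 2)
    # sum of importances equals the joint incremental R^2
    r2_both <- summary(lm(y ~ A + B))$r.squared
    expect_equal(sum(ri$importance), r2_both, tolerance = 1e-10)
    expect_equal(ri$importance[ri$score == "A"],
                 summary(lm(y ~ A))$r.squared, tolerance = 1e-3)
    expect_lt(ri$importance[ri$score == "B"], 0.01)
  })
  d2 <- tibble::tibble(y = rnorm(50), A = rnorm(50))
  d2$B <- 2 * d2$A + 1
  expect_error(relative_importance(d2, "y", "A", "B", covariates = NULL,
                                   n_boot = 100),
               "collinear")
})

test_that("mediation recovers the product-of-coefficients limits", {
  withr::with_seed(47, {
    n <- 3000
    x <- rbinom(n, 1, 0.5)
    m <- 0.5 * x + rnorm(n, 0, 0.1)
    y <- 0.8 * m + 0.4 * x + rnorm(n, 0, 0.02)
    d <- tibble::tibble(x = x, m = m, y = y)
    md <- mediate(d, "x", "m", "y", n_boot = 100, seed = 5)
    est <- setNames(md$estimates$estimate, md$estimates$quantity)
    expect_lt(abs(est[["prop_mediated"]] - 0.5), 0.03)
    expect_lt(abs(est[["acme"]] - 0.4), 0.03)
    # linear-linear decomposition is exact
    expect_equal(unname(est["total"]), unname(est["acme"] + est["ade"]),
                 tolerance = 1e-10)
    # no exposure -> mediator path: ACME ~ 0 with CI covering 0
    m0 <- rnorm(n)
    y0 <- 0.8 * m0 + 0.4 * x + rnorm(n, 0, 0.5)
    md0 <- mediate(tibble::tibble(x = x, m = m0, y = y0), "x", "m", "y",
                   n_boot = 150, seed = 6)
    acme0 <- md0$estimates[md0$estimates$quantity == "acme", ]
    expect_lt(abs(acme0$estimate), 0.05)
    expect_true(acme0$ci_lower <= 0 && acme0$ci_upper >= 0)
    # full mediation: c' = 0 drives proportion mediated to 1
    y1 <- 0.8 * m + rnorm(n, 0, 0.02)
    md1 <- mediate(tibble::tibble(x = x, m = m, y = y1), "x", "m", "y",
                   n_boot = 100, seed = 7)
    pm1 <- md1$estimates$estimate[md1$estimates$quantity == "prop_mediated"]
    expect_lt(abs(pm1 - 1), 0.03)
  })
  expect_error(mediate(tibble::tibble(x = 1:9, m = rnorm(9), y = rnorm(9)),
                       "x", "m", "y", n_boot = 50),
               "at least 100")
  expect_error(mediate(tibble::tibble(x = rnorm(200), m = 1, y = rnorm(200)),
                       "x", "m", "y", n_boot = 100),
               "constant")
})

test_that("binary-outcome mediation works on the probability scale", {
  withr::with_seed(48, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    m <- 0.8 * x + rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 1 * m + 0.3 * x))
    d <- tibble::tibble(x = x, m = m, y = y)
    md <- mediate(d, "x", "m", "y", n_boot = 100, seed = 9)
    est <- setNames(md$estimates$estimate, md$estimates$quantity)
    expect_gt(est[["acme"]], 0)
    expect_lt(est[["acme"]], 0.4) # a probability-scale difference
    expect_gt(est[["prop_mediated"]], 0.3)
    # reproducible under the same seed
    md2 <- mediate(d, "x", "m", "y", n_boot = 100, seed = 9)
    expect_identical(md$estimates, md2$estimates)
  })
})

test_that("nested cross-validation selects per fold without leakage", {
  d <- make_mini_cohort(n = 250, p = 30, n_signal = 4, beta = 0.7, seed = 49)
  ncv <- nested_cross_validate(d, "trait", sprintf("P%03d", 1:30),
                               covariates = c("age", "sex"),
                               n_iter = 4, seed = 11)
  expect_s3_class(ncv$metrics, "senosig_cv")
  expect_equal(nrow(ncv$metrics), 4)
  expect_length(ncv$panels, 4)
  # fold panels are allowed to differ and are reported per fold
  expect_true(all(vapply(ncv$panels, inherits, TRUE, "senosig_panel")))
})

test_that("cross-study transfer trains on one cohort and tests on the other", {
  da <- make_mini_cohort(n = 350, p = 25, n_signal = 4, beta = 0.8, seed = 50)
  db <- make_mini_cohort(n = 300, p = 25, n_signal = 4, beta = 0.8, seed = 51)
  tr <- cross_study_transfer(da, db, "trait", sprintf("P%03d", 1:25),
                             covariates_a = c("age", "sex"),
                             covariates_b = c("age", "sex"))
  expect_equal(nrow(tr), 2)
  expect_false(any(tr$untrainable))
  expect_true(all(tr$r2 > 0.2))
  # zeroed-signal target cohort: transfer metric collapses
  db0 <- db
  db0$trait <- rnorm(nrow(db0))
  tr0 <- cross_study_transfer(da, db0, "trait", sprintf("P%03d", 1:25),
                              covariates_a = c("age", "sex"),
                              covariates_b = c("age", "sex"))
  if (!any(tr0$untrainable)) {
    expect_lt(tr0$r2[tr0$test == "cohort_b"], 0.1)
  }
})
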