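test_that("a noiseless linear age signal is fit exactly", {
  withr::with_seed(80, {
    n <- 100
    d <- tibble::tibble(participant = as.character(1:n), age = runif(n, 30, 90))
    for (i in 1:5) d[[paste0("P", i)]] <- i * d$age + rnorm(n, 0, 1e-9)
    m <- fit_senoage_model(d, paste0("P", 1:5), signature = "exact")
    expect_equal(glance(m)$r_squared, 1, tolerance = 1e-8)
    # permutation invariance of the fit
    m2 <- fit_senoage_model(d[sample(n), ], paste0("P", 1:5))
    expect_equal(coef(m$fit), coef(m2$fit), tolerance = 1e-6)
  })
})

test_that("rank-deficient panels drop columns with a message", {
  withr::with_seed(81, {
    d <- tibble::tibble(participant = as.character(1:50), age = runif(50, 30, 90),
                        P1 = rnorm(50))
    d$P2 <- 2 * d$P1
    expect_message(m <- fit_senoage_model(d, c("P1", "P2")), "rank-deficient")
    expect_equal(m$dropped, "P2")
  })
})

test_that("gaps absorb intercept and trend and are age-decorrelated", {
  withr::with_seed(82, {
    n <- 200
    d <- tibble::tibble(participant = as.character(1:n), age = runif(n, 30, 90))
    # predicted age identical to chronological age: all gaps 0
    d$Pexact <- d$age
    m <- fit_senoage_model(d, "Pexact", signature = "id")
    g <- compute_gap(d, m)
    expect_equal(g$gap, rep(0, n), tolerance = 1e-8)
    expect_equal(g$seno_age, d$age, tolerance = 1e-8)
    # a constant offset in predictions is absorbed by the trend line
    m_off <- m
    m_off$fit$coefficients["(Intercept)"] <-
      m_off$fit$coefficients["(Intercept)"] + 5
    g_off <- compute_gap(d, m_off)
    expect_equal(g_off$gap, rep(0, n), tolerance = 1e-8)
    # noisy model: gaps mean-zero and decorrelated with age by construction
    d$Pnoisy <- d$age + rnorm(n, 0, 10)
    gn <- compute_gap(d, fit_senoage_model(d, "Pnoisy", signature = "noisy"))
    expect_equal(mean(gn$gap), 0, tolerance = 1e-10)
    expect_lt(abs(cor(gn$gap, d$age)), 1e-8)
  })
})

test_that("gaps are invariant to affine transformation of predictions", {
  withr::with_seed(83, {
    n <- 150
    d <- tibble::tibble(participant = as.character(1:n), age = runif(n, 30, 90))
    d$P1 <- 0.5 * d$age + rnorm(n)
    m <- fit_senoage_model(d, "P1", signature = "s")
    g <- compute_gap(d, m)
    m_aff <- m
    m_aff$fit$coefficients <- 3 * m_aff$fit$coefficients
    m_aff$fit$coefficients["(Intercept)"] <-
      m_aff$fit$coefficients["(Intercept)"] - 40
    g_aff <- compute_gap(d, m_aff)
    expect_equal(g_aff$gap, 3 * g$gap, tolerance = 1e-8)
    expect_equal(cor(g_aff$gap, g$gap), 1, tolerance = 1e-12)
  })
})

test_that("the planted biological-age offset is recovered in the gap", {
  coh <- simulate_cohort(cohort_sim_config(n_participants = 900,
                                           age_range = c(40, 95), seed = 84))
  sel <- select_features(coh$data, "age", coh$truth$smooth_sap,
                         covariates = c("sex", "race"),
                         config = elastic_net_config(seed = 85))
  panel <- rank_and_truncate(sel, "age", "negative_health")
  m <- fit_senoage_model(coh$data, panel, signature = "sap")
  g <- compute_gap(coh$data, m)
  expect_gt(cor(g$gap, coh$truth$delta), 0.5)
})

test_that("gap recovery improves with panel signal strength", {
  cors <- vapply(c(0.01, 0.05, 0.12), function(slope) {
    coh <- simulate_cohort(cohort_sim_config(
      n_participants = 700, age_range = c(40, 95), sap_age_slope = slope,
      seed = 86))
    m <- fit_senoage_model(coh$data, coh$truth$smooth_sap[1:25],
                           signature = "sap")
    g <- compute_gap(coh$data, m)
    cor(g$gap, coh$truth$delta)
  }, 1)
  expect_true(all(diff(cors) > 0))
})

test_that("gap-trait associations exclude age by default", {
  coh <- simulate_cohort(cohort_sim_config(n_participants = 700,
                                           age_range = c(40, 95), seed = 87))
  m <- fit_senoage_model(coh$data, coh$truth$smooth_sap[1:20], signature = "sap")
  g <- compute_gap(coh$data, m)
  fit <- gap_trait_association(g, coh$data, "frailty")
  expect_false(grepl("age", fit$covariates))
  fit_age <- gap_trait_association(g, coh$data, "frailty", include_age = TRUE)
  expect_true(grepl("age", fit_age$covariates))
  # frailty loads on delta, so the gap should associate positively
  expect_gt(fit$estimate, 0)
  expect_lt(fit$p_value, 0.05)
  # a duplicated gap column changes nothing
  fit_dup <- gap_trait_association(g, coh$data, "frailty")
  expect_equal(fit, fit_dup)
})

test_that("seno-age correlation matrices are symmetric with unit diagonal", {
  withr::with_seed(88, {
    n <- 120
    d <- tibble::tibble(participant = as.character(1:n), age = runif(n, 30, 90))
    d$P1 <- 0.5 * d$age + rnorm(n)
    d$P2 <- 0.3 * d$age + rnorm(n)
    g1 <- compute_gap(d, fit_senoage_model(d, "P1", signature = "sig1"))
    g2 <- compute_gap(d, fit_senoage_model(d, "P2", signature = "sig2"))
    g_dup <- dplyr::mutate(g1, signature = "sig1copy")
    cm <- senoage_correlation_matrix(dplyr::bind_rows(g1, g2, g_dup), "gap")
    expect_equal(cm, t(cm))
    expect_equal(unname(diag(cm)), rep(1, 3))
    expect_equal(cm["sig1", "sig1copy"], 1, tolerance = 1e-12)
    # independent signals: gap correlation near zero
    expect_lt(abs(cm["sig1", "sig2"]), 0.3)
    expect_error(senoage_correlation_matrix(g1), "two signatures")
  })
})
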