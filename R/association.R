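# Trait association: covariate-adjusted linear / logistic models for
# composite scores or single proteins, repeated and nested cross-validation,
# cross-study transfer, paired metric comparison with a normality gate,
# LMG relative importance for two scores, and bootstrap causal mediation.

#' Covariate-adjusted trait model
#'
#' Fits `trait ~ predictor + covariates` by ordinary least squares
#' (continuous trait) or maximum-likelihood logistic regression (binary
#' trait) and returns the predictor coefficient.
#'
#' @param cohort Participant-level tibble.
#' @param trait Trait column name.
#' @param predictor Predictor column name (a protein or a composite score).
#' @param covariates Covariate column names.
#' @return One-row tibble: `trait`, `predictor`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `family`, `covariates`, `n`, `separation`
#'   (logical flag for logistic fits with numerically perfect separation).
#' @export
fit_trait_model <- function(cohort, trait, predictor,
                            covariates = c("age", "sex", "race")) {
  check_cols(cohort, c(trait, predictor, covariates), "cohort")
  if (stats::sd(cohort[[predictor]]) == 0) {
    rlang::abort("Predictor is constant.")
  }
  family <- trait_family(cohort[[trait]])
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  f <- stats::as.formula(paste(trait, "~", rhs))
  separation <- FALSE
  if (family == "gaussian") {
    fit <- stats::lm(f, data = cohort)
  } else {
    dat <- cohort
    dat[[trait]] <- as_binary01(dat[[trait]])
    fit <- withCallingHandlers(
      stats::glm(f, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) separation <- TRUE
  }
  sm <- summary(fit)$coefficients
  row <- sm[predictor, ]
  tibble::tibble(
    trait = trait, predictor = predictor,
    estimate = row[[1]], std_error = row[[2]], statistic = row[[3]],
    p_value = row[[4]], family = family,
    covariates = paste(covariates, collapse = ","),
    n = stats::nobs(fit), separation = separation)
}

# Fit trait ~ score (+covariates) on train rows, evaluate on test rows.
eval_split <- function(data, trait, score_col, covariates, train, test) {
  family <- trait_family(data[[trait]])
  rhs <- paste(c(score_col, covariates), collapse = " + ")
  f <- stats::as.formula(paste(trait, "~", rhs))
  if (family == "gaussian") {
    fit <- stats::lm(f, data = data[train, , drop = FALSE])
    pred <- stats::predict(fit, newdata = data[test, , drop = FALSE])
    truth <- data[[trait]][test]
    tibble::tibble(r2 = stats::cor(pred, truth)^2,
                   pseudo_r2 = NA_real_, auc = NA_real_)
  } else {
    dat <- data
    dat[[trait]] <- as_binary01(dat[[trait]])
    fit <- suppressWarnings(
      stats::glm(f, data = dat[train, , drop = FALSE], family = stats::binomial()))
    pred <- stats::predict(fit, newdata = dat[test, , drop = FALSE],
                           type = "response")
    truth <- dat[[trait]][test]
    tibble::tibble(r2 = NA_real_,
                   pseudo_r2 = stats::cor(pred, truth)^2,
                   auc = auc_rank(pred, truth))
  }
}

# Draw a 90/10 split; for binary traits, redraw (capped) until the test fold
# has both outcome classes.
draw_split <- function(y, train_frac, binary, max_redraw = 100) {
  n <- length(y)
  for (i in seq_len(max_redraw)) {
    train <- sort(sample.int(n, floor(train_frac * n)))
    test <- setdiff(seq_len(n), train)
    if (!binary || length(unique(as_binary01(y)[test])) == 2) {
      return(list(train = train, test = test, redraws = i - 1L))
    }
  }
  rlang::abort("Could not draw a test fold with both outcome classes in 100 tries.")
}

#' Repeated hold-out cross-validation of a composite score
#'
#' Performs `n_iter` independent random splits (default ten rounds, 90%
#' train / 10% test). Each round fits `trait ~ score` (plus optional
#' covariates) on the training split and evaluates on the held-out split:
#' R-squared (squared Pearson correlation of prediction and truth) for
#' continuous traits; for binary traits both a pseudo-R-squared (squared
#' correlation of the predicted probability with the outcome) and the AUC.
#' With `mode = "folds"` the iterations instead rotate disjoint folds.
#'
#' @param data Tibble containing the trait and score columns.
#' @param trait Trait column name.
#' @param score_col Score column name.
#' @param covariates Optional covariates included in the prediction model.
#' @param n_iter Number of rounds.
#' @param train_frac Training fraction per round.
#' @param seed RNG seed (split assignment).
#' @param mode `"resample"` (independent splits, default) or `"folds"`.
#' @return Tibble of class `senosig_cv`: one row per iteration with `r2`,
#'   `pseudo_r2`, `auc`; attribute `redraws` counts degenerate binary test
#'   folds that were redrawn.
#' @export
cross_validate <- function(data, trait, score_col = "score", covariates = NULL,
                           n_iter = 10, train_frac = 0.9, seed = 1,
                           mode = c("resample", "folds")) {
  mode <- match.arg(mode)
  check_cols(data, c(trait, score_col, covariates), "data")
  binary <- trait_family(data[[trait]]) == "binomial"
  redraws <- 0L
  res <- withr::with_seed(seed, {
    if (mode == "folds") {
      foldid <- sample(rep(seq_len(n_iter), length.out = nrow(data)))
    }
    purrr::map(seq_len(n_iter), function(i) {
      if (mode == "resample") {
        sp <- draw_split(data[[trait]], train_frac, binary)
        redraws <<- redraws + sp$redraws
      } else {
        sp <- list(train = which(foldid != i), test = which(foldid == i))
      }
      eval_split(data, trait, score_col, covariates, sp$train, sp$test) |>
        dplyr::mutate(iteration = i, .before = 1)
    }) |> dplyr::bind_rows()
  })
  attr(res, "redraws") <- redraws
  class(res) <- c("senosig_cv", class(res))
  res
}

#' Nested cross-validation with fold-specific panel selection
#'
#' Per round, elastic-net feature selection, sign filtering / truncation, and
#' score scaling are all performed on the training 90% only; the held-out 10%
#' is scored with the training panel and scaling statistics. Fold panels may
#' differ across rounds and are returned.
#'
#' @inheritParams cross_validate
#' @param cohort Participant-level tibble.
#' @param candidate_pool Candidate protein columns.
#' @param covariates Covariates for feature selection (unpenalized).
#' @param polarity Trait polarity for the sign filter.
#' @param k Maximum panel size.
#' @param config An [elastic_net_config()].
#' @return List of class `senosig_nested_cv`: `metrics` (a `senosig_cv`
#'   tibble) and `panels` (per-round `senosig_panel`s).
#' @export
nested_cross_validate <- function(cohort, trait, candidate_pool,
                                  covariates = c("age", "sex", "race"),
                                  polarity = "negative_health", k = 25,
                                  config = elastic_net_config(),
                                  n_iter = 10, train_frac = 0.9, seed = 1) {
  binary <- trait_family(cohort[[trait]]) == "binomial"
  panels <- vector("list", n_iter)
  res <- withr::with_seed(seed, {
    purrr::map(seq_len(n_iter), function(i) {
      sp <- draw_split(cohort[[trait]], train_frac, binary)
      train_data <- cohort[sp$train, , drop = FALSE]
      cfg <- config
      cfg$seed <- sub_seed(config$seed, paste0("nested", i))
      sel <- select_features(train_data, trait, candidate_pool, covariates, cfg)
      panel <- rank_and_truncate(sel, trait, polarity, k)
      panels[[i]] <<- panel
      if (nrow(panel$proteins) == 0) {
        return(tibble::tibble(iteration = i, r2 = 0,
                              pseudo_r2 = if (binary) 0 else NA_real_,
                              auc = if (binary) 0.5 else NA_real_,
                              n_panel = 0L))
      }
      stats_train <- panel_scale_stats(train_data, panel$proteins$protein)
      scored <- dplyr::left_join(
        cohort, composite_score(cohort, panel, scale_stats = stats_train),
        by = "participant")
      eval_split(scored, trait, "score", NULL, sp$train, sp$test) |>
        dplyr::mutate(iteration = i, n_panel = nrow(panel$proteins),
                      .before = 1)
    }) |> dplyr::bind_rows()
  })
  metrics <- res
  class(metrics) <- c("senosig_cv", class(metrics))
  structure(list(metrics = metrics, panels = panels),
            class = "senosig_nested_cv")
}

#' Cross-study transfer of a trait panel
#'
#' Selects features independently in each cohort, keeps the intersection,
#' trains the composite-score model wholly on one cohort and evaluates it on
#' the other, in both directions. Scores in the evaluation cohort use that
#' cohort's own scaling statistics (each study is z-scored internally).
#'
#' @param cohort_a,cohort_b Two cohorts sharing a protein namespace.
#' @param trait Trait column present in both.
#' @param candidate_pool Candidate proteins present in both.
#' @param covariates_a,covariates_b Selection covariates per cohort.
#' @param polarity Trait polarity.
#' @param k Maximum panel size.
#' @param config An [elastic_net_config()].
#' @return Tibble with one row per direction: `train`, `test`, `r2`,
#'   `pseudo_r2`, `auc`, `n_features`, `untrainable` (TRUE when the selection
#'   intersection is empty).
#' @export
cross_study_transfer <- function(cohort_a, cohort_b, trait, candidate_pool,
                                 covariates_a = c("age", "sex", "race"),
                                 covariates_b = c("age", "sex"),
                                 polarity = "negative_health", k = 25,
                                 config = elastic_net_config()) {
  cfg_b <- config
  cfg_b$seed <- sub_seed(config$seed, "transfer_b")
  sel_a <- select_features(cohort_a, trait, candidate_pool, covariates_a, config)
  sel_b <- select_features(cohort_b, trait, candidate_pool, covariates_b, cfg_b)
  shared <- intersect(sel_a$protein, sel_b$protein)
  if (length(shared) == 0) {
    return(tibble::tibble(
      train = c("cohort_a", "cohort_b"), test = c("cohort_b", "cohort_a"),
      r2 = NA_real_, pseudo_r2 = NA_real_, auc = NA_real_,
      n_features = 0L, untrainable = TRUE))
  }
  pooled <- sel_a[sel_a$protein %in% shared, , drop = FALSE]
  panel <- rank_and_truncate(pooled, trait, polarity, k)
  one_direction <- function(train_c, test_c, train_lab, test_lab) {
    tr <- dplyr::left_join(train_c, composite_score(train_c, panel),
                           by = "participant")
    te <- dplyr::left_join(test_c, composite_score(test_c, panel),
                           by = "participant")
    both <- dplyr::bind_rows(
      dplyr::select(tr, dplyr::all_of(c("participant", trait, "score"))),
      dplyr::select(te, dplyr::all_of(c("participant", trait, "score"))))
    eval_split(both, trait, "score", NULL,
               seq_len(nrow(tr)), nrow(tr) + seq_len(nrow(te))) |>
      dplyr::mutate(train = train_lab, test = test_lab,
                    n_features = nrow(panel$proteins), untrainable = FALSE,
                    .before = 1)
  }
  dplyr::bind_rows(
    one_direction(cohort_a, cohort_b, "cohort_a", "cohort_b"),
    one_direction(cohort_b, cohort_a, "cohort_b", "cohort_a"))
}

#' Compare paired metric vectors with a normality gate
#'
#' Tests the iteration-matched differences for normality (Shapiro-Wilk); if
#' p > 0.05 a paired t-test is used, otherwise a Wilcoxon signed-rank test
#' with a flag. Identical vectors or zero-variance differences take an
#' explicit degenerate path instead of crashing.
#'
#' @param metrics_a,metrics_b Equal-length paired numeric vectors.
#' @return One-row tibble: `mean_difference`, `shapiro_p`, `method`
#'   (`"paired t-test"`, `"wilcoxon signed-rank"` or `"zero-variance"`),
#'   `p_value`, `normal` (logical gate outcome).
#' @export
compare_paired_metrics <- function(metrics_a, metrics_b) {
  if (length(metrics_a) != length(metrics_b)) {
    rlang::abort("Paired metric vectors must have equal length.")
  }
  d <- metrics_b - metrics_a
  if (stats::sd(d) == 0) {
    return(tibble::tibble(
      mean_difference = mean(d), shapiro_p = NA_real_,
      method = "zero-variance", p_value = if (all(d == 0)) 1 else NA_real_,
      normal = NA))
  }
  sw <- stats::shapiro.test(d)$p.value
  if (sw > 0.05) {
    tt <- stats::t.test(metrics_b, metrics_a, paired = TRUE)
    tibble::tibble(mean_difference = mean(d), shapiro_p = sw,
                   method = "paired t-test", p_value = tt$p.value,
                   normal = TRUE)
  } else {
    wt <- stats::wilcox.test(metrics_b, metrics_a, paired = TRUE, exact = FALSE)
    tibble::tibble(mean_difference = mean(d), shapiro_p = sw,
                   method = "wilcoxon signed-rank", p_value = wt$p.value,
                   normal = FALSE)
  }
}

# R^2 of lm(y ~ X) via least squares on a model matrix (fast path for LMG
# and its bootstrap).
r2_of <- function(y, X) {
  if (ncol(X) == 0) return(0)
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' LMG relative importance of two composite scores
#'
#' Decomposes the trait variance explained by two scores into per-score
#' importances by averaging each score's R-squared increment over both
#' orderings of the pair, with the covariates always in the base model (the
#' LMG decomposition restricted to two focal regressors). The two importances
#' sum to the joint incremental R-squared of adding both scores to the
#' covariate-only model. Percentile bootstrap confidence intervals.
#'
#' @param data Tibble with the trait, both scores, and covariates.
#' @param trait Continuous trait column.
#' @param score_a,score_b Score column names.
#' @param covariates Covariate column names (always in the base model).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param conf_level Confidence level.
#' @param seed RNG seed.
#' @return Tibble with one row per score: `score`, `importance`, `ci_lower`,
#'   `ci_upper`.
#' @export
relative_importance <- function(data, trait, score_a, score_b,
                                covariates = c("sex", "race"),
                                n_boot = 1000, conf_level = 0.95, seed = 1) {
  check_cols(data, c(trait, score_a, score_b, covariates), "data")
  if (abs(stats::cor(data[[score_a]], data[[score_b]])) >= 1 - 1e-12) {
    rlang::abort("The two scores are collinear (|r| = 1).")
  }
  cov_mm <- if (length(covariates) > 0) {
    stats::model.matrix(
      stats::as.formula(paste("~", paste(covariates, collapse = "+"))),
      data)[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow(data), 0)
  }
  A <- data[[score_a]]; B <- data[[score_b]]; y <- data[[trait]]
  lmg_pair <- function(y, A, B, C) {
    r_c <- r2_of(y, C)
    r_ca <- r2_of(y, cbind(C, A)); r_cb <- r2_of(y, cbind(C, B))
    r_cab <- r2_of(y, cbind(C, A, B))
    c(a = ((r_ca - r_c) + (r_cab - r_cb)) / 2,
      b = ((r_cb - r_c) + (r_cab - r_ca)) / 2)
  }
  est <- lmg_pair(y, A, B, cov_mm)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(y), replace = TRUE)
      lmg_pair(y[idx], A[idx], B[idx], cov_mm[idx, , drop = FALSE])
    }, c(a = 0, b = 0))
  })
  alpha <- (1 - conf_level) / 2
  tibble::tibble(
    score = c(score_a, score_b),
    importance = unname(est),
    ci_lower = apply(boots, 1, stats::quantile, alpha),
    ci_upper = apply(boots, 1, stats::quantile, 1 - alpha))
}

# Point estimates of ACME/ADE/total by the potential-outcomes plug-in
# estimator, averaged over exposure arms. Linear outcome: closed-form plug-in
# (equals product-of-coefficients). Binary outcome: probability-scale
# counterfactual estimator integrating over the mediator residual
# distribution with fixed standard-normal `draws`. Operates on raw vectors /
# a covariate model matrix for speed inside the bootstrap.
mediate_point <- function(x, m, y, C, out_family, control = 0, treat = 1,
                          draws = NULL) {
  n <- length(y)
  Xm <- cbind(1, x, C)
  fm <- stats::lm.fit(Xm, m)
  cm <- fm$coefficients
  sig_m <- sqrt(sum(fm$residuals^2) / (n - ncol(Xm)))
  cov_part_m <- if (ncol(C) > 0) as.numeric(C %*% cm[-(1:2)]) else 0
  m_mean <- function(xv) cm[1] + cm[2] * xv + cov_part_m

  Xy <- cbind(1, x, m, C)
  if (out_family == "gaussian") {
    fy <- stats::lm.fit(Xy, y)
    cy <- fy$coefficients
  } else {
    cy <- suppressWarnings(
      stats::glm.fit(Xy, y, family = stats::binomial())$coefficients)
  }
  cov_part_y <- if (ncol(C) > 0) as.numeric(C %*% cy[-(1:3)]) else 0
  eta <- function(xv, mvec) cy[1] + cy[2] * xv + cy[3] * mvec + cov_part_y
  EY <- function(x_val, m_from) {
    mu <- m_mean(m_from)
    if (out_family == "gaussian") {
      mean(eta(x_val, mu)) # linear in m: plug-in is exact
    } else {
      # integrate plogis over the mediator residual distribution
      mean(stats::plogis(outer(eta(x_val, mu), cy[3] * sig_m * draws, "+")))
    }
  }
  y11 <- EY(treat, treat); y10 <- EY(treat, control)
  y01 <- EY(control, treat); y00 <- EY(control, control)
  acme <- ((y11 - y10) + (y01 - y00)) / 2
  ade <- ((y11 - y01) + (y10 - y00)) / 2
  total <- y11 - y00
  c(acme = acme, ade = ade, total = total,
    prop_mediated = if (total != 0) acme / total else NA_real_)
}

#' Bootstrap causal mediation analysis
#'
#' Potential-outcomes mediation: a linear mediator model
#' `mediator ~ exposure + covariates` and a linear or logistic outcome model
#' `outcome ~ exposure + mediator + covariates`. The average causal mediation
#' effect (ACME, indirect), average direct effect (ADE), total effect, and
#' proportion mediated (ACME / total) are computed by the plug-in
#' counterfactual estimator averaged over exposure arms; for binary outcomes
#' the mediator residual distribution is integrated by simulation on the
#' probability scale. Confidence intervals are nonparametric percentile
#' bootstrap.
#'
#' @param data Participant-level tibble.
#' @param exposure Exposure column (binary 0/1, logical, 2-level factor, or
#'   continuous; `control` / `treat` set the contrast).
#' @param mediator Continuous mediator column (e.g. a composite score).
#' @param outcome Outcome column (continuous or binary).
#' @param covariates Covariates for both models.
#' @param n_boot Bootstrap iterations (>= 100; default 1000).
#' @param control,treat Exposure values contrasted.
#' @param nsim Mediator-integration draws for binary outcomes.
#' @param conf_level Confidence level.
#' @param seed RNG seed.
#' @return List of class `senosig_mediation` with `estimates` (tibble:
#'   `quantity`, `estimate`, `ci_lower`, `ci_upper`) and settings.
#' @export
mediate <- function(data, exposure, mediator, outcome, covariates = NULL,
                    n_boot = 1000, control = 0, treat = 1, nsim = 100,
                    conf_level = 0.95, seed = 1) {
  check_cols(data, c(exposure, mediator, outcome, covariates), "data")
  if (n_boot < 100) rlang::abort("`n_boot` must be at least 100.")
  if (stats::sd(data[[mediator]]) == 0) rlang::abort("Mediator is constant.")
  if (is.factor(data[[exposure]]) || is.logical(data[[exposure]])) {
    data[[exposure]] <- as_binary01(data[[exposure]])
  }
  x <- as.numeric(data[[exposure]])
  m <- as.numeric(data[[mediator]])
  out_family <- trait_family(data[[outcome]])
  y <- as_binary01(data[[outcome]])
  C <- if (length(covariates) > 0) {
    stats::model.matrix(
      stats::as.formula(paste("~", paste(covariates, collapse = "+"))),
      data)[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow(data), 0)
  }
  draws <- if (out_family == "binomial") {
    withr::with_seed(sub_seed(seed, "draws"), stats::rnorm(nsim))
  } else NULL
  est <- mediate_point(x, m, y, C, out_family, control, treat, draws)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(y), replace = TRUE)
      mediate_point(x[idx], m[idx], y[idx], C[idx, , drop = FALSE],
                    out_family, control, treat, draws)
    }, est)
  })
  alpha <- (1 - conf_level) / 2
  estimates <- tibble::tibble(
    quantity = names(est),
    estimate = unname(est),
    ci_lower = apply(boots, 1, stats::quantile, alpha, na.rm = TRUE),
    ci_upper = apply(boots, 1, stats::quantile, 1 - alpha, na.rm = TRUE))
  structure(list(estimates = estimates, n_boot = n_boot,
                 exposure = exposure, mediator = mediator, outcome = outcome,
                 conf_level = conf_level),
            class = "senosig_mediation")
}

#' @export
print.senosig_mediation <- function(x, ...) {
  cat(sprintf("<senosig_mediation> %s -> %s -> %s (%d bootstrap iterations)\n",
              x$exposure, x$mediator, x$outcome, x$n_boot))
  print(x$estimates)
  invisible(x)
}
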