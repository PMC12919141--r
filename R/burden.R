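# Burden scoring: elastic-net feature selection with unpenalized covariates,
# polarity sign filtering with top-25 truncation, z-scored mean composite
# senescence-burden scores, and the High-Impact Panel.

#' Elastic-net configuration
#'
#' @param alpha Elastic-net mixing parameter (0 = ridge, 1 = lasso); the
#'   default 0.5 mixes the two penalties equally.
#' @param lambda_rule `"1se"` (largest penalty within one standard error of
#'   the CV minimum; default) or `"min"` (the CV minimum). The one-SE rule is
#'   the default because the CV-minimum on signal-free candidates routinely
#'   admits spurious features, while the one-SE fit returns an essentially
#'   empty selection under the null at no cost in recall.
#' @param n_cv_folds Cross-validation folds for the penalty path.
#' @param standardize Standardize features internally for penalization.
#' @param seed Seed fixing the CV fold assignment.
#' @return List of class `elastic_net_config`.
#' @export
elastic_net_config <- function(alpha = 0.5, lambda_rule = c("1se", "min"),
                               n_cv_folds = 10, standardize = TRUE, seed = 1) {
  check_fraction(alpha, "alpha")
  structure(list(alpha = alpha, lambda_rule = match.arg(lambda_rule),
                 n_cv_folds = check_count(n_cv_folds, "n_cv_folds", 3L),
                 standardize = isTRUE(standardize), seed = seed),
            class = "elastic_net_config")
}

# Build the design matrix: covariate dummies first (unpenalized), candidate
# proteins after (penalized).
build_design <- function(data, candidates, covariates) {
  check_cols(data, c(candidates, covariates), "cohort")
  if (length(covariates) > 0) {
    mm <- stats::model.matrix(
      stats::as.formula(paste("~", paste(covariates, collapse = "+"))), data)
    mm <- mm[, -1, drop = FALSE]
  } else {
    mm <- matrix(numeric(0), nrow(data), 0)
  }
  x <- cbind(mm, as.matrix(data[, candidates, drop = FALSE]))
  list(x = x, n_cov = ncol(mm))
}

#' Select trait-associated proteins by elastic net
#'
#' Fits a cross-validated elastic net of the trait on the candidate proteins
#' with the covariates included unpenalized, and returns the proteins with
#' nonzero coefficients at the chosen penalty. Coefficients are reported both
#' on the original scale and on the standardized (per-SD) scale; effect-size
#' ordering downstream uses the standardized scale so it is free of the
#' proteins' measurement units.
#'
#' @param cohort Participant-level tibble.
#' @param trait Trait column name; the model family is inferred (gaussian for
#'   continuous, binomial for binary traits).
#' @param candidate_pool Character vector of candidate protein columns.
#' @param covariates Covariate column names, included unpenalized.
#' @param config An [elastic_net_config()].
#' @return Tibble `protein`, `coefficient`, `std_coefficient`, `sign`, with
#'   attributes `lambda` and `family`.
#' @export
select_features <- function(cohort, trait, candidate_pool,
                            covariates = c("age", "sex", "race"),
                            config = elastic_net_config()) {
  check_cols(cohort, trait, "cohort")
  y <- cohort[[trait]]
  family <- trait_family(y)
  if (family == "binomial") y <- as_binary01(y)
  des <- build_design(cohort, candidate_pool, covariates)
  pf <- c(rep(0, des$n_cov), rep(1, length(candidate_pool)))
  foldid <- withr::with_seed(
    config$seed, sample(rep(seq_len(config$n_cv_folds), length.out = nrow(des$x))))
  cvfit <- glmnet::cv.glmnet(des$x, y, family = family, alpha = config$alpha,
                             penalty.factor = pf, foldid = foldid,
                             standardize = config$standardize)
  lambda <- if (config$lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  beta <- as.numeric(stats::coef(cvfit, s = lambda))[-1] # drop intercept
  prot_beta <- beta[des$n_cov + seq_along(candidate_pool)]
  sds <- vapply(candidate_pool, function(p) stats::sd(cohort[[p]]), 1)
  out <- tibble::tibble(
    protein = candidate_pool,
    coefficient = prot_beta,
    std_coefficient = prot_beta * sds) |>
    dplyr::filter(.data$coefficient != 0) |>
    dplyr::mutate(sign = sign(.data$std_coefficient))
  attr(out, "lambda") <- lambda
  attr(out, "family") <- family
  out
}

#' Sign-filter, rank, and truncate a selected protein set into a panel
#'
#' Applies the trait-polarity sign filter (for negative-health traits such as
#' frailty or kidney disease only positively associated proteins are kept;
#' for positive-health traits such as walking pace or grip strength only
#' inversely associated proteins are kept), orders by absolute effect size
#' descending, and keeps at most `k` proteins. Ties at the cut are broken by
#' larger absolute effect, then lexicographic protein identifier.
#'
#' @param selected Tibble from [select_features()].
#' @param trait Trait label carried on the panel.
#' @param polarity `"negative_health"` or `"positive_health"`.
#' @param k Maximum panel size (default 25).
#' @param effect_col Column used as the effect size for ordering.
#' @return List of class `senosig_panel`: `trait`, `polarity`, `proteins`
#'   (tibble with `protein`, `effect`, `sign`, in panel order).
#' @export
rank_and_truncate <- function(selected, trait = NA_character_,
                              polarity = c("negative_health", "positive_health"),
                              k = 25, effect_col = "std_coefficient") {
  polarity <- match.arg(polarity)
  check_count(k, "k")
  keep <- if (nrow(selected) == 0) {
    selected
  } else if (polarity == "negative_health") {
    selected[selected[[effect_col]] > 0, , drop = FALSE]
  } else {
    selected[selected[[effect_col]] < 0, , drop = FALSE]
  }
  ord <- order(-abs(keep[[effect_col]]), keep$protein)
  keep <- keep[ord, , drop = FALSE][seq_len(min(k, nrow(keep))), , drop = FALSE]
  structure(
    list(trait = trait, polarity = polarity,
         proteins = tibble::tibble(protein = keep$protein,
                                   effect = keep[[effect_col]],
                                   sign = sign(keep[[effect_col]]))),
    class = "senosig_panel")
}

#' Composite senescence-burden score
#'
#' Per participant, the mean of per-protein z-scores over the panel proteins:
#' z = (x - cohort mean) / cohort sample SD (n - 1 denominator). Zero-variance
#' proteins are excluded from the mean with a warning.
#'
#' @param cohort Participant-level tibble with an identifier column
#'   `participant`.
#' @param panel A `senosig_panel` or a character vector of protein columns.
#' @param scale_stats Optional list with named numeric `center` and `scale`
#'   (e.g. from a training subset) used instead of cohort statistics; used by
#'   nested validation and cross-study transfer to avoid leakage.
#' @return Tibble `participant`, `score`.
#' @export
composite_score <- function(cohort, panel, scale_stats = NULL) {
  proteins <- if (inherits(panel, "senosig_panel")) panel$proteins$protein else panel
  if (length(proteins) < 1) rlang::abort("Panel is empty.")
  check_cols(cohort, c("participant", proteins), "cohort")
  x <- as.matrix(cohort[, proteins, drop = FALSE])
  if (is.null(scale_stats)) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
  } else {
    center <- scale_stats$center[proteins]
    scl <- scale_stats$scale[proteins]
  }
  keep <- scl > 0
  if (!all(keep)) {
    if (!any(keep)) rlang::abort("All panel proteins have zero variance.")
    rlang::warn(sprintf("%d zero-variance panel protein(s) excluded from the score.",
                        sum(!keep)))
  }
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2, scl[keep], "/")
  tibble::tibble(participant = cohort$participant, score = rowMeans(z))
}

# Scaling statistics of a cohort for a protein set, for leakage-free scoring.
panel_scale_stats <- function(cohort, proteins) {
  x <- as.matrix(cohort[, proteins, drop = FALSE])
  list(center = colMeans(x), scale = apply(x, 2, stats::sd))
}

#' High-Impact Panel
#'
#' Proteins selected for at least half (ceiling) of a stated trait list.
#'
#' @param panels Named list (one entry per trait) of `senosig_panel` objects
#'   or character protein vectors.
#' @return Character vector of HIP proteins (sorted).
#' @export
high_impact_panel <- function(panels) {
  if (length(panels) < 2) rlang::abort("At least two trait panels are required.")
  sets <- purrr::map(panels, function(p) {
    if (inherits(p, "senosig_panel")) p$proteins$protein else p
  })
  threshold <- ceiling(length(sets) / 2)
  counts <- table(unlist(purrr::map(sets, unique), use.names = FALSE))
  sort(names(counts)[counts >= threshold])
}

#' @export
print.senosig_panel <- function(x, ...) {
  cat(sprintf("<senosig_panel> trait=%s polarity=%s, %d protein(s)\n",
              x$trait, x$polarity, nrow(x$proteins)))
  print(x$proteins, n = 5)
  invisible(x)
}
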