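# Seno-age models: per-signature age prediction on elastic-net-selected
# panels, residual seno-age gaps (mean-zero and age-decorrelated by
# construction), gap-trait associations, and inter-signature correlations.

#' Fit a seno-age model
#'
#' Ordinary least squares of chronological age on the abundances of a panel
#' of signature proteins (selection and estimation are separated: the panel
#' comes from elastic-net feature selection with trait = age, the prediction
#' model is unpenalized). Rank-deficient columns are dropped with a message.
#'
#' @param cohort Participant-level tibble.
#' @param panel A `senosig_panel` (derived with trait = age) or a character
#'   vector of protein columns (at most 25 predictors by convention).
#' @param age_col Chronological-age column.
#' @param signature Signature label carried on predictions.
#' @return List of class `senosig_senoage_model`: `fit` (lm), `proteins`,
#'   `dropped`, `signature`, `age_col`.
#' @export
fit_senoage_model <- function(cohort, panel, age_col = "age",
                              signature = "signature") {
  proteins <- if (inherits(panel, "senosig_panel")) panel$proteins$protein else panel
  if (length(proteins) < 1) rlang::abort("Panel is empty.")
  check_cols(cohort, c(age_col, proteins), "cohort")
  f <- stats::as.formula(paste(
    age_col, "~", paste(sprintf("`%s`", proteins), collapse = " + ")))
  fit <- stats::lm(f, data = cohort)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased) > 0) {
    rlang::inform(sprintf("Dropped %d rank-deficient column(s): %s",
                          length(aliased),
                          paste(gsub("`", "", aliased), collapse = ", ")))
  }
  structure(list(fit = fit, proteins = proteins,
                 dropped = gsub("`", "", aliased),
                 signature = signature, age_col = age_col),
            class = "senosig_senoage_model")
}

#' Predicted seno-ages and residual seno-age gaps
#'
#' Predicts each participant's seno-age from the fitted model, then removes
#' the cohort-level trend of predicted seno-age on chronological age (an
#' ordinary least-squares line refit in the scoring cohort). The residual is
#' the seno-age gap: positive for participants whose circulating proteome
#' looks older than their chronological age, negative for younger. Gaps are
#' mean-zero and uncorrelated with chronological age on the scoring cohort by
#' construction, and invariant to affine transformations of the predicted
#' ages.
#'
#' @param cohort Participant-level tibble (any cohort sharing the model's
#'   protein columns; the trend line is refit here).
#' @param model A `senosig_senoage_model`.
#' @return Tibble `participant`, `signature`, `seno_age`, `gap`.
#' @export
compute_gap <- function(cohort, model) {
  stopifnot(inherits(model, "senosig_senoage_model"))
  check_cols(cohort, c("participant", model$age_col, model$proteins), "cohort")
  pred <- stats::predict(model$fit, newdata = cohort)
  if (stats::sd(pred) == 0) {
    rlang::abort("Predicted seno-age is constant; gap undefined.")
  }
  trend <- stats::lm(pred ~ age, data = tibble::tibble(pred = pred,
                                                       age = cohort[[model$age_col]]))
  tibble::tibble(
    participant = cohort$participant,
    signature = model$signature,
    seno_age = unname(pred),
    gap = unname(stats::resid(trend)))
}

#' Association of a seno-age gap with a clinical trait
#'
#' Reuses [fit_trait_model()] with the gap as predictor. Chronological age is
#' excluded from the covariates by default because the gap is already
#' age-decorrelated; set `include_age = TRUE` to re-include it.
#'
#' @param gaps Tibble from [compute_gap()] (one signature).
#' @param cohort Participant-level tibble with the trait and covariates.
#' @param trait Trait column name.
#' @param covariates Covariates (age excluded unless `include_age`).
#' @param include_age Re-include chronological age as a covariate.
#' @return One-row tibble as [fit_trait_model()], with a `signature` column.
#' @export
gap_trait_association <- function(gaps, cohort, trait,
                                  covariates = c("sex", "race"),
                                  include_age = FALSE) {
  check_cols(gaps, c("participant", "signature", "gap"), "gaps")
  if (dplyr::n_distinct(gaps$signature) != 1) {
    rlang::abort("`gaps` must contain a single signature.")
  }
  covs <- if (include_age) unique(c(covariates, "age")) else setdiff(covariates, "age")
  d <- dplyr::left_join(cohort, gaps[, c("participant", "gap")], by = "participant")
  fit_trait_model(d, trait, "gap", covs) |>
    dplyr::mutate(signature = gaps$signature[1], .before = 1)
}

#' Inter-signature correlation matrix of seno-ages or gaps
#'
#' Pearson correlations across signatures on the shared participant set.
#'
#' @param records Stacked [compute_gap()] tibbles across >= 2 signatures.
#' @param value `"gap"` or `"seno_age"`.
#' @return Symmetric correlation matrix (signature x signature).
#' @export
senoage_correlation_matrix <- function(records, value = c("gap", "seno_age")) {
  value <- match.arg(value)
  check_cols(records, c("participant", "signature", value), "records")
  wide <- tidyr::pivot_wider(records[, c("participant", "signature", value)],
                             names_from = "signature",
                             values_from = tidyselect::all_of(value))
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (ncol(wide) < 3) rlang::abort("At least two signatures are required.")
  if (nrow(wide) < 3) rlang::abort("At least 3 shared participants are required.")
  stats::cor(as.matrix(wide[, -1, drop = FALSE]))
}
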