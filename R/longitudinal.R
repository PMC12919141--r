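# Longitudinal models: left-truncated (delayed entry) stratified Cox
# proportional hazards on the age scale, Schoenfeld-residual diagnostics,
# and quartile lifetime-trajectory curves with delayed-entry Kaplan-Meier.

#' Left-truncated stratified Cox model
#'
#' Fits `Surv(entry_age, exit_age, status) ~ predictor + strata(...)` by
#' stratified partial likelihood with delayed entry: a participant enters the
#' risk set at their proteomics measurement age, and age is the time scale.
#' Efron tie handling by default.
#'
#' @param data Tibble with survival columns and the predictor.
#' @param predictor Predictor column name (protein or composite score).
#' @param entry,exit,status Column names of entry age, exit (event or
#'   censoring) age, and event status (1 = event).
#' @param strata Stratification columns (e.g. sex, race), or NULL.
#' @param ties `"efron"` (default) or `"exact"`/`"breslow"`.
#' @return List of class `senosig_cox`: `tidy` (one-row tibble `log_hr`,
#'   `std_error`, `statistic`, `p_value`, `n`, `n_events`, `monotone`
#'   likelihood flag) and the underlying `survival::coxph` `fit`.
#' @export
fit_cox_left_truncated <- function(data, predictor, entry = "entry_age",
                                   exit, status, strata = c("sex", "race"),
                                   ties = "efron") {
  check_cols(data, c(predictor, entry, exit, status, strata), "data")
  if (any(data[[exit]] <= data[[entry]])) {
    rlang::abort("All exit ages must exceed entry ages.")
  }
  if (sum(data[[status]]) == 0) rlang::abort("No events in the data.")
  st <- if (length(strata) > 0) {
    paste0(" + ", paste(sprintf("strata(%s)", strata), collapse = " + "))
  } else ""
  f <- stats::as.formula(sprintf("survival::Surv(%s, %s, %s) ~ %s%s",
                                 entry, exit, status, predictor, st))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  row <- sm$coefficients[predictor, ]
  if (abs(row[["coef"]]) > 15) monotone <- TRUE
  structure(
    list(tidy = tibble::tibble(
           predictor = predictor,
           log_hr = row[["coef"]],
           std_error = row[["se(coef)"]],
           statistic = row[["z"]],
           p_value = row[["Pr(>|z|)"]],
           n = fit$n, n_events = fit$nevent,
           monotone = monotone),
         fit = fit),
    class = "senosig_cox")
}

#' Schoenfeld-residual proportional-hazards test
#'
#' Score test of association between scaled Schoenfeld residuals and event
#' time (identity time transform by default); a small p-value indicates a
#' proportional-hazards violation.
#'
#' @param cox A `senosig_cox` object (or a `coxph` fit).
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return Tibble `term`, `chisq`, `df`, `p_value` (one row per predictor
#'   plus GLOBAL).
#' @export
schoenfeld_test <- function(cox, transform = "identity") {
  fit <- if (inherits(cox, "senosig_cox")) cox$fit else cox
  if (fit$nevent < 2) rlang::abort("At least 2 events are required.")
  z <- survival::cox.zph(fit, transform = transform)
  tab <- z$table
  tibble::tibble(term = rownames(tab), chisq = tab[, "chisq"],
                 df = tab[, "df"], p_value = tab[, "p"])
}

#' Quartile lifetime trajectories of a composite score
#'
#' Assigns participants to score quartiles (ties broken by score rank, then
#' participant identifier, so membership is deterministic) and estimates
#' delayed-entry Kaplan-Meier survival on the age scale for the top and
#' bottom quartiles, reported as cumulative incidence 1 - S(age).
#'
#' @param data Tibble with `participant`, survival columns, and scores merged
#'   in (column `score_col`).
#' @param score_col Score column name.
#' @param entry,exit,status Survival column names.
#' @return List of class `senosig_trajectories`: `curves` (tibble `age`,
#'   `quartile`, `cum_incidence`, `n_at_risk`, `n_event`) and `groups`
#'   (tibble `participant`, `quartile` for Q1/Q4 members), `group_sizes`.
#' @export
quartile_trajectories <- function(data, score_col = "score",
                                  entry = "entry_age", exit, status) {
  check_cols(data, c("participant", score_col, entry, exit, status), "data")
  s <- data[[score_col]]
  if (stats::sd(s) == 0) rlang::abort("All scores are identical; quartiles undefined.")
  ord <- order(s, data$participant)
  q <- integer(nrow(data))
  q[ord] <- ceiling(4 * seq_along(ord) / nrow(data))
  sel <- q %in% c(1L, 4L)
  d <- data[sel, , drop = FALSE]
  d$quartile <- factor(ifelse(q[sel] == 1L, "Q1 (lowest)", "Q4 (highest)"))
  sf <- survival::survfit(
    stats::as.formula(sprintf("survival::Surv(%s, %s, %s) ~ quartile",
                              entry, exit, status)),
    data = d)
  strata_lab <- rep(sub("^quartile=", "", names(sf$strata)),
                    sf$strata %||% length(sf$time))
  curves <- tibble::tibble(
    age = sf$time, quartile = strata_lab,
    cum_incidence = 1 - sf$surv,
    n_at_risk = sf$n.risk, n_event = sf$n.event)
  structure(
    list(curves = curves,
         groups = tibble::tibble(participant = d$participant,
                                 quartile = d$quartile),
         group_sizes = table(d$quartile)),
    class = "senosig_trajectories")
}
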