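# Lifespan dynamics: decade-balanced downsampling with a standardized
# mean-difference balance report, the sliding-window differential-abundance
# scan (adjacent 10-year age windows at 1-year centers), sex stratification,
# and peak detection.

#' Decade-balanced downsampling with a balance report
#'
#' Draws, without replacement, the same number of participants from each
#' decade of life within `age_range`, split evenly by sex, and reports the
#' standardized mean difference (SMD) of each numeric balance covariate
#' between the selected subsample and the eligible pool.
#'
#' @param cohort Participant-level tibble with `age` and `sex` columns.
#' @param age_range Eligible age range (inclusive); decades are the 10-year
#'   bins starting at the lower bound.
#' @param n_per_decade Participants drawn per decade.
#' @param sex_balance Female fraction per decade.
#' @param balance_covariates Numeric columns reported in the SMD table.
#' @param seed RNG seed.
#' @return List of class `senosig_downsample`: `subsample` (tibble) and
#'   `balance` (tibble `covariate`, `mean_selected`, `mean_pool`, `smd`).
#' @export
balanced_downsample <- function(cohort, age_range = c(50, 90),
                                n_per_decade = 120, sex_balance = 0.5,
                                balance_covariates = "age", seed = 1) {
  check_cols(cohort, c("age", "sex", balance_covariates), "cohort")
  check_count(n_per_decade, "n_per_decade")
  eligible <- cohort[cohort$age >= age_range[1] & cohort$age <= age_range[2], ,
                     drop = FALSE]
  breaks <- seq(age_range[1], age_range[2], by = 10)
  decade <- findInterval(eligible$age, breaks, rightmost.closed = TRUE)
  n_f <- round(n_per_decade * sex_balance)
  n_m <- n_per_decade - n_f
  want <- c(female = n_f, male = n_m)
  picks <- withr::with_seed(seed, {
    unlist(lapply(seq_len(length(breaks) - 1), function(d) {
      unlist(lapply(c("female", "male"), function(s) {
        rows <- which(decade == d & eligible$sex == s)
        need <- want[[s]]
        if (length(rows) < need) {
          rlang::abort(sprintf(
            "Stratum decade [%d,%d) x %s has %d eligible participants; %d needed.",
            breaks[d], breaks[d] + 10, s, length(rows), need))
        }
        sample(rows, need)
      }))
    }))
  })
  subsample <- eligible[sort(picks), , drop = FALSE]
  balance <- purrr::map(balance_covariates, function(v) {
    xs <- subsample[[v]]; xp <- eligible[[v]]
    pooled_sd <- sqrt((stats::var(xs) + stats::var(xp)) / 2)
    tibble::tibble(covariate = v, mean_selected = mean(xs),
                   mean_pool = mean(xp),
                   smd = if (pooled_sd > 0) (mean(xs) - mean(xp)) / pooled_sd else 0)
  }) |> dplyr::bind_rows()
  structure(list(subsample = subsample, balance = balance),
            class = "senosig_downsample")
}

# Window membership at center t, width w: lower [t-w, t), upper [t, t+w).
# Half-open so a participant exactly at the center belongs to the upper
# window; every participant in [t-w, t+w) is in exactly one window.
window_indicator <- function(age, center, width) {
  in_lower <- age >= center - width & age < center
  in_upper <- age >= center & age < center + width
  ifelse(in_upper, 1, ifelse(in_lower, 0, NA))
}

#' Sliding-window differential-abundance scan
#'
#' At each 1-year center t, compares protein abundances between the adjacent
#' age windows \code{[t-w, t)} and \code{[t, t+w)} with a covariate-adjusted
#' linear model (coefficient of the upper-window indicator), applies BH
#' across proteins within the center, and counts proteins elevated
#' (positive coefficient, q < threshold) and depressed. Centers with an empty
#' window are skipped with a warning.
#'
#' @param cohort Participant-level tibble with `age` and protein columns.
#' @param proteins Protein columns to scan.
#' @param centers Window centers (default 60 to 80 by 1 year).
#' @param width Window half-width in years (default 10).
#' @param covariates Covariates adjusted for in each window model.
#' @param q_threshold BH-adjusted significance threshold.
#' @param groups Optional named list of protein groupings (e.g. SAP vs
#'   non-SAP) for per-group counts.
#' @return List of class `senosig_deswan`: `counts` (per center and group:
#'   `n_elevated`, `n_depressed`, `n_tested`), `results` (per center x
#'   protein: `estimate`, `p_value`, `q_value`), `skipped` centers.
#' @export
deswan_scan <- function(cohort, proteins, centers = 60:80, width = 10,
                        covariates = NULL, q_threshold = 0.05, groups = NULL) {
  check_cols(cohort, c("age", proteins, covariates), "cohort")
  skipped <- numeric(0)
  res <- purrr::map(centers, function(ct) {
    ind <- window_indicator(cohort$age, ct, width)
    keep <- !is.na(ind)
    if (sum(ind[keep] == 0) == 0 || sum(ind[keep] == 1) == 0) {
      skipped <<- c(skipped, ct)
      rlang::warn(sprintf("Center %s skipped: an empty comparison window.", ct))
      return(NULL)
    }
    d <- cohort[keep, , drop = FALSE]
    upper <- ind[keep]
    if (length(covariates) > 0) {
      mm <- stats::model.matrix(
        stats::as.formula(paste("~", paste(covariates, collapse = "+"))), d)
      X <- cbind(mm, upper = upper)
    } else {
      X <- cbind(1, upper = upper)
    }
    Y <- as.matrix(d[, proteins, drop = FALSE])
    fit <- stats::lm.fit(X, Y)
    cf <- as.matrix(fit$coefficients)
    res <- as.matrix(fit$residuals)
    j <- ncol(X)
    est <- cf[j, ]
    rss <- colSums(res^2)
    dfree <- nrow(X) - fit$rank
    xtx_inv_jj <- chol2inv(chol(crossprod(X)))[j, j]
    se <- sqrt(rss / dfree * xtx_inv_jj)
    tval <- est / se
    p <- 2 * stats::pt(abs(tval), dfree, lower.tail = FALSE)
    tibble::tibble(center = ct, protein = proteins, estimate = unname(est),
                   p_value = unname(p),
                   q_value = stats::p.adjust(unname(p), method = "BH"))
  }) |> dplyr::bind_rows()
  if (nrow(res) == 0) rlang::abort("All centers were skipped.")
  groups <- groups %||% list(all = proteins)
  counts <- purrr::imap(groups, function(ps, g) {
    res |>
      dplyr::filter(.data$protein %in% ps) |>
      dplyr::group_by(.data$center) |>
      dplyr::summarise(
        group = g,
        n_elevated = sum(.data$estimate > 0 & .data$q_value < q_threshold),
        n_depressed = sum(.data$estimate < 0 & .data$q_value < q_threshold),
        n_tested = dplyr::n(), .groups = "drop")
  }) |> dplyr::bind_rows()
  structure(list(counts = counts, results = res, skipped = skipped,
                 q_threshold = q_threshold),
            class = "senosig_deswan")
}

#' Peak center of a sliding-window scan
#'
#' The center with the maximal elevated-protein count; ties are resolved to
#' the smallest center and flagged. Skipped centers are ignored.
#'
#' @param scan A `senosig_deswan` object.
#' @param group Protein group to use.
#' @return One-row tibble: `peak_age`, `n_elevated`, `tie` (logical).
#' @export
deswan_peak <- function(scan, group = "all") {
  cnt <- scan$counts[scan$counts$group == group, , drop = FALSE]
  if (nrow(cnt) == 0) rlang::abort(sprintf("Unknown group `%s`.", group))
  mx <- max(cnt$n_elevated)
  at <- cnt$center[cnt$n_elevated == mx]
  tibble::tibble(peak_age = min(at), n_elevated = mx, tie = length(at) > 1)
}

#' Sex-stratified sliding-window scan with per-sex peaks
#'
#' Runs [deswan_scan()] independently for each sex and reports the per-sex
#' peak ages (ties flagged and resolved to the smallest center).
#'
#' @inheritParams deswan_scan
#' @return List of class `senosig_deswan_by_sex`: `scans` (named per-sex
#'   `senosig_deswan`), `peaks` (tibble `sex`, `peak_age`, `n_elevated`,
#'   `tie`).
#' @export
sex_stratified_scan <- function(cohort, proteins, centers = 60:80, width = 10,
                                covariates = NULL, q_threshold = 0.05,
                                groups = NULL) {
  sexes <- levels(factor(cohort$sex))
  scans <- stats::setNames(purrr::map(sexes, function(s) {
    deswan_scan(cohort[cohort$sex == s, , drop = FALSE], proteins, centers,
                width, covariates, q_threshold, groups)
  }), sexes)
  peak_group <- if (is.null(groups)) "all" else names(groups)[1]
  peaks <- purrr::imap(scans, function(sc, s) {
    dplyr::mutate(deswan_peak(sc, peak_group), sex = s, .before = 1)
  }) |> dplyr::bind_rows()
  structure(list(scans = scans, peaks = peaks),
            class = "senosig_deswan_by_sex")
}
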