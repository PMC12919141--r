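# Synthetic-data generators: a multi-induction senescence catalog, a
# plasma-proteomics cohort with planted mediation / hazard / change-point
# structure, and a tissue atlas with planted section enrichment. Every
# generator is deterministic given its config seed, and returns the planted
# truth alongside the data so downstream estimators can be scored against it.

default_cell_types <- function() {
  c("renal_epithelial", "small_airway_epithelial", "skeletal_myoblast",
    "astrocyte", "osteoblast", "coronary_artery_endothelial",
    "preadipocyte", "vascular_smooth_muscle", "PBMC",
    "keratinocyte_neonatal", "melanocyte_neonatal",
    "umbilical_vein_endothelial", "fibroblast_neonatal",
    "lung_fibroblast_fetal")
}

#' Adult (non-neonatal, non-fetal) cell types of the default catalog universe
#'
#' The neonatal and fetal cell types are excluded from exclusivity and
#' health-domain analyses because they are unlikely to contribute to adult
#' aging signatures.
#'
#' @return Character vector of nine cell-type labels.
#' @export
adult_cell_types <- function() {
  setdiff(default_cell_types(),
          c("keratinocyte_neonatal", "melanocyte_neonatal",
            "umbilical_vein_endothelial", "fibroblast_neonatal",
            "lung_fibroblast_fetal"))
}

#' Configuration for the synthetic senescence catalog
#'
#' Describes a catalog of replicate-level log2 protein intensities for
#' senescent and proliferating arms of each (cell type, induction) condition,
#' with planted cell-type-exclusive and core senescence proteins. Planted
#' members receive the full effect in every induction of their cell type, so
#' they qualify under the two-induction rule in expectation.
#'
#' @param n_proteins Number of proteins in the catalog.
#' @param cell_types Character vector of cell-type labels (default: the 14
#'   catalog cell types).
#' @param inductions Induction labels; the first is treated as ionizing
#'   radiation by downstream defaults.
#' @param n_replicates Replicates per condition arm.
#' @param frac_exclusive Fraction of `n_proteins` planted as exclusive members
#'   of each cell type (disjoint across cell types).
#' @param n_core Number of planted core proteins, each a member of at least
#'   `k_core` cell types.
#' @param k_core Minimum cell-type membership of planted core proteins.
#' @param effect_log2fc Mean planted log2 fold-change (senescent vs
#'   proliferating) for members, applied in every induction of their cell type.
#' @param noise_sd Replicate-level standard deviation of log2 intensities.
#' @param baseline_mean Mean baseline log2 intensity.
#' @param seed RNG seed; fixes the output exactly.
#' @return A list of class `catalog_sim_config`.
#' @export
catalog_sim_config <- function(n_proteins = 400,
                               cell_types = default_cell_types(),
                               inductions = c("IR", "ETO"),
                               n_replicates = 4,
                               frac_exclusive = 0.04,
                               n_core = 25,
                               k_core = 9,
                               effect_log2fc = 1.5,
                               noise_sd = 0.5,
                               baseline_mean = 20,
                               seed = 1) {
  check_count(n_proteins, "n_proteins")
  check_count(n_replicates, "n_replicates", min = 2L)
  check_fraction(frac_exclusive, "frac_exclusive")
  check_count(n_core + 1L, "n_core", min = 1L) # allow 0
  check_count(k_core, "k_core")
  if (length(cell_types) < 1L || length(inductions) < 2L) {
    rlang::abort("Need at least one cell type and two inductions.")
  }
  if (k_core > length(cell_types)) {
    rlang::abort("`k_core` cannot exceed the number of cell types.")
  }
  n_exclusive <- round(frac_exclusive * n_proteins)
  if (length(cell_types) * n_exclusive + n_core > n_proteins) {
    rlang::abort(
      "Planted exclusive and core sets exceed `n_proteins`; they must be disjoint.")
  }
  structure(
    list(n_proteins = as.integer(n_proteins), cell_types = cell_types,
         inductions = inductions, n_replicates = as.integer(n_replicates),
         frac_exclusive = frac_exclusive, n_core = as.integer(n_core),
         k_core = as.integer(k_core), effect_log2fc = effect_log2fc,
         noise_sd = noise_sd, baseline_mean = baseline_mean, seed = seed),
    class = "catalog_sim_config")
}

#' Simulate a multi-induction senescence catalog
#'
#' Generates replicate-level log2 intensities for proliferating and senescent
#' arms of every (cell type, induction) condition. Planted members (exclusive
#' per cell type, plus core proteins shared by at least `k_core` cell types)
#' have expected log2 fold-change `effect_log2fc` in every induction of their
#' cell types; all other proteins have expected log2 fold-change 0.
#'
#' @param config A [catalog_sim_config()].
#' @return A list of class `senosig_catalog` with elements
#'   `abundance` (long tibble: protein, cell_type, induction, arm, replicate,
#'   log2_intensity), and `truth` (class `senosig_truth`: planted `membership`
#'   tibble, `exclusive` named list, `core` character vector, and the config).
#' @export
simulate_catalog <- function(config = catalog_sim_config()) {
  stopifnot(inherits(config, "catalog_sim_config"))
  withr::with_seed(config$seed, {
    proteins <- sprintf("P%04d", seq_len(config$n_proteins))
    n_ex <- round(config$frac_exclusive * config$n_proteins)
    idx <- 0L
    exclusive <- list()
    membership <- list()
    for (ct in config$cell_types) {
      if (n_ex > 0) {
        ex <- proteins[idx + seq_len(n_ex)]
        idx <- idx + n_ex
      } else {
        ex <- character(0)
      }
      exclusive[[ct]] <- ex
      if (length(ex)) membership[[ct]] <- tibble::tibble(protein = ex, cell_type = ct)
    }
    core <- if (config$n_core > 0) proteins[idx + seq_len(config$n_core)] else character(0)
    n_ct <- length(config$cell_types)
    core_rows <- purrr::map(core, function(p) {
      size <- sample(seq(config$k_core, n_ct), 1L)
      tibble::tibble(protein = p, cell_type = sample(config$cell_types, size))
    })
    membership <- dplyr::bind_rows(c(membership, core_rows)) |>
      dplyr::distinct()
    if (nrow(membership) == 0) {
      membership <- tibble::tibble(protein = character(0), cell_type = character(0))
    }

    baseline <- stats::setNames(
      stats::rnorm(config$n_proteins, config$baseline_mean, 2), proteins)

    grid <- tidyr::expand_grid(
      cell_type = config$cell_types,
      induction = config$inductions,
      arm = c("proliferating", "senescent"),
      replicate = seq_len(config$n_replicates),
      protein = proteins)
    member_key <- paste(membership$protein, membership$cell_type)
    is_member <- paste(grid$protein, grid$cell_type) %in% member_key
    mu <- baseline[grid$protein] +
      ifelse(is_member & grid$arm == "senescent", config$effect_log2fc, 0)
    grid$log2_intensity <- mu + stats::rnorm(nrow(grid), 0, config$noise_sd)

    truth <- structure(
      list(membership = membership,
           exclusive = exclusive,
           core = core,
           proteins = proteins,
           config = config),
      class = "senosig_truth")
    structure(list(abundance = grid, truth = truth), class = "senosig_catalog")
  })
}

#' Configuration for the synthetic plasma-proteomics cohort
#'
#' Plants the statistical structure the downstream analyses assume:
#' abundances of senescence-associated proteins (SAPs) drift with biological
#' age (chronological age plus a per-participant offset delta), a mediation
#' path sex -> senescence burden -> outcome, proportional-hazards onset and
#' death ages with delayed entry at the measurement age, and a step-like
#' change in a subset of SAPs at a (possibly sex-specific) change-point age.
#'
#' @param n_participants Cohort size.
#' @param age_range Two-element numeric, minimum and maximum age in years.
#' @param sex_balance Fraction of female participants.
#' @param aging_offset_sd SD (tau, years) of the per-participant biological
#'   age offset delta ~ Normal(0, tau).
#' @param sap_age_slope Abundance change per year of biological age for
#'   planted SAPs (log2-intensity units, protein noise SD is 1).
#' @param burden_loading Loading of the planted burden (mediator) on SAP
#'   abundances.
#' @param mediation_coeffs Named numeric `c(a=, b=, c_prime=)`: sex -> burden,
#'   burden (per SD) -> outcome, and direct sex -> outcome effects on the
#'   outcome link scale.
#' @param outcome_intercept Intercept of the logistic outcome model.
#' @param hazard_log_hr Planted log hazard ratio per SD of burden (applies to
#'   both onset and death endpoints).
#' @param hazard_shape,hazard_median_age Weibull shape and median event age at
#'   burden 0 for the death endpoint (onset uses `hazard_median_age + 3`).
#' @param changepoint_age Age of the planted step change; a single number, or
#'   a named vector `c(female=, male=)` for sex-specific change-points.
#' @param changepoint_effect Step height (log2-intensity units).
#' @param n_changepoint_proteins Number of planted SAPs carrying the step.
#' @param censor_age Administrative censoring age.
#' @param n_proteins Number of cohort proteins when no catalog truth is
#'   supplied (standalone use).
#' @param n_sap Number of planted SAPs in standalone use. The first
#'   `n_changepoint_proteins` of the planted SAPs carry the step change only;
#'   the remaining ("smooth") SAPs carry the gradual age drift and the
#'   burden loading.
#' @param seed RNG seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_participants = 1000,
                              age_range = c(22, 96),
                              sex_balance = 0.5,
                              aging_offset_sd = 5,
                              sap_age_slope = 0.05,
                              burden_loading = 0.4,
                              mediation_coeffs = c(a = 0.5, b = 0.8, c_prime = 0.4),
                              outcome_intercept = -1.5,
                              hazard_log_hr = 0.5,
                              hazard_shape = 5,
                              hazard_median_age = 85,
                              changepoint_age = 70,
                              changepoint_effect = 0.6,
                              n_changepoint_proteins = 50,
                              censor_age = 100,
                              n_proteins = 250,
                              n_sap = 100,
                              seed = 1) {
  check_count(n_participants, "n_participants", min = 10L)
  check_fraction(sex_balance, "sex_balance")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    rlang::abort("`age_range` must be c(min, max) with min < max.")
  }
  req <- c("a", "b", "c_prime")
  if (!all(req %in% names(mediation_coeffs))) {
    rlang::abort("`mediation_coeffs` must be named c(a=, b=, c_prime=).")
  }
  structure(
    list(n_participants = as.integer(n_participants), age_range = age_range,
         sex_balance = sex_balance, aging_offset_sd = aging_offset_sd,
         sap_age_slope = sap_age_slope, burden_loading = burden_loading,
         mediation_coeffs = mediation_coeffs[req],
         outcome_intercept = outcome_intercept,
         hazard_log_hr = hazard_log_hr, hazard_shape = hazard_shape,
         hazard_median_age = hazard_median_age,
         changepoint_age = changepoint_age,
         changepoint_effect = changepoint_effect,
         n_changepoint_proteins = as.integer(n_changepoint_proteins),
         censor_age = censor_age, n_proteins = as.integer(n_proteins),
         n_sap = as.integer(n_sap), seed = seed),
    class = "cohort_sim_config")
}

# Draw an event age from a Weibull proportional-hazards model conditional on
# survival past `entry` (delayed entry): inverse transform of the conditional
# survival function.
weibull_onset <- function(entry, shape, median_age, log_hr_z, u) {
  lambda0 <- log(2) / median_age^shape
  lambda <- lambda0 * exp(log_hr_z)
  (entry^shape - log(u) / lambda)^(1 / shape)
}

#' Simulate a plasma-proteomics cohort with planted truth
#'
#' Generates participant ages, sex, race, protein abundances, continuous and
#' binary clinical traits, and left-truncated survival endpoints, following
#' the planted structure described in [cohort_sim_config()]. When `truth`
#' (from [simulate_catalog()]) is supplied, cohort proteins align with the
#' catalog proteins and planted SAPs are the catalog's planted members;
#' otherwise a standalone protein universe is created.
#'
#' @param config A [cohort_sim_config()].
#' @param truth Optional `senosig_truth` from [simulate_catalog()].
#' @return A list of class `senosig_cohort` with elements `data` (tibble: one
#'   row per participant with covariates, traits, survival columns, and one
#'   column per protein) and `truth` (planted per-participant `delta`,
#'   `mediator`, SAP sets, coefficients, and change-point ages).
#' @export
simulate_cohort <- function(config = cohort_sim_config(), truth = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "senosig_truth"))
    proteins <- truth$proteins
    sap <- sort(unique(truth$membership$protein))
    if (length(sap) == 0) {
      rlang::abort("Catalog truth has no planted members; cannot plant cohort signal.")
    }
  } else {
    proteins <- sprintf("P%04d", seq_len(config$n_proteins))
    if (config$n_sap > config$n_proteins) {
      rlang::abort("`n_sap` cannot exceed `n_proteins`.")
    }
    sap <- proteins[seq_len(config$n_sap)]
  }
  if (config$n_changepoint_proteins > length(sap)) {
    rlang::abort("`n_changepoint_proteins` exceeds the number of planted SAPs.")
  }
  withr::with_seed(config$seed, {
    n <- config$n_participants
    id <- sprintf("S%05d", seq_len(n))
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- factor(ifelse(stats::runif(n) < config$sex_balance, "female", "male"),
                  levels = c("female", "male"))
    male <- as.numeric(sex == "male")
    race <- factor(sample(c("groupA", "groupB", "groupC"), n, replace = TRUE,
                          prob = c(0.6, 0.25, 0.15)))
    delta <- stats::rnorm(n, 0, config$aging_offset_sd)
    bio_age <- age + delta

    a <- config$mediation_coeffs[["a"]]
    b <- config$mediation_coeffs[["b"]]
    c_prime <- config$mediation_coeffs[["c_prime"]]
    mediator <- a * male + stats::rnorm(n)
    m_std <- as.numeric(scale(mediator))

    # Planted SAPs are partitioned: the change-point proteins carry the
    # step-like wave at the change-point age; the remaining ("smooth") SAPs
    # carry the gradual biological-age drift and the burden loading.
    cp_proteins <- sap[seq_len(config$n_changepoint_proteins)]
    smooth_sap <- setdiff(sap, cp_proteins)
    cp_age <- config$changepoint_age
    cp_by_sex <- length(cp_age) == 2 && all(c("female", "male") %in% names(cp_age))
    cp_i <- if (cp_by_sex) {
      ifelse(sex == "female", cp_age[["female"]], cp_age[["male"]])
    } else {
      rep(cp_age[[1]], n)
    }
    # The step is locked to chronological age: the planted wave emulates a
    # population-level phenomenon detected against calendar-age windows, and
    # tying it to the biological-age offset would only smear the change-point
    # by the offset SD.
    step_i <- config$changepoint_effect * as.numeric(age >= cp_i)

    mid_age <- mean(config$age_range)
    X <- matrix(stats::rnorm(n * length(proteins)), n, length(proteins),
                dimnames = list(NULL, proteins))
    # Heterogeneous per-protein slopes and burden loadings (mean equal to the
    # configured values): real SASP proteins differ in age sensitivity, and
    # the heterogeneity is what makes the age factor and the burden factor
    # separately identifiable from the protein panel.
    if (length(smooth_sap) > 0) {
      slopes <- config$sap_age_slope * stats::runif(length(smooth_sap), 0.5, 1.5)
      loads <- config$burden_loading * stats::runif(length(smooth_sap), 0, 2)
      X[, smooth_sap] <- X[, smooth_sap] +
        outer(bio_age - mid_age, slopes) + outer(mediator, loads)
    }
    if (length(cp_proteins) > 0) X[, cp_proteins] <- X[, cp_proteins] + step_i

    frailty <- 0.03 * (bio_age - mid_age) + 0.35 * m_std + stats::rnorm(n, 0, 0.5)
    walking_pace <- 1.4 - 0.012 * (bio_age - mid_age) - 0.15 * m_std +
      stats::rnorm(n, 0, 0.2)
    p_diab <- stats::plogis(config$outcome_intercept + b * m_std + c_prime * male)
    diabetes <- stats::rbinom(n, 1, p_diab)

    z <- m_std
    death_age <- weibull_onset(age, config$hazard_shape, config$hazard_median_age,
                               config$hazard_log_hr * z, stats::runif(n))
    onset_age <- weibull_onset(age, config$hazard_shape,
                               config$hazard_median_age + 3,
                               config$hazard_log_hr * z, stats::runif(n))
    death_status <- as.integer(death_age <= config$censor_age)
    death_exit <- pmin(death_age, config$censor_age)
    onset_status <- as.integer(onset_age <= config$censor_age)
    onset_exit <- pmin(onset_age, config$censor_age)

    data <- dplyr::bind_cols(
      tibble::tibble(
        participant = id, age = age, sex = sex, race = race,
        entry_age = age, frailty = frailty, walking_pace = walking_pace,
        diabetes = diabetes,
        death_age = death_exit, death_status = death_status,
        diabetes_onset_age = onset_exit, diabetes_onset_status = onset_status),
      tibble::as_tibble(X))

    cohort_truth <- structure(
      list(delta = stats::setNames(delta, id),
           mediator = stats::setNames(mediator, id),
           sap = sap, smooth_sap = smooth_sap,
           changepoint_proteins = cp_proteins,
           changepoint_age = cp_age,
           mediation_coeffs = config$mediation_coeffs,
           hazard_log_hr = config$hazard_log_hr,
           proteins = proteins, config = config),
      class = "senosig_cohort_truth")
    structure(list(data = data, truth = cohort_truth),
              class = "senosig_cohort")
  })
}

#' Simulate a tissue-atlas table with planted section enrichment
#'
#' Produces categorical immunohistochemistry-style expression levels (not
#' detected / low / medium / high) per protein per tissue section. Each
#' signature gets one "matched" section in which its member proteins are
#' enriched for medium/high levels by `enrichment` over the baseline
#' probability.
#'
#' @param signatures Named list: cell type -> character vector of proteins.
#' @param n_unmatched_sections Number of unmatched background sections.
#' @param base_prob Baseline probability of a medium/high call.
#' @param enrichment Added medium/high probability for signature proteins in
#'   their matched section.
#' @param seed RNG seed.
#' @return A tibble with columns `protein`, `section`, `level` and an
#'   attribute `matched_sections` (named character: cell type -> section).
#' @export
simulate_tissue_atlas <- function(signatures, n_unmatched_sections = 6,
                                  base_prob = 0.3, enrichment = 0.35,
                                  seed = 1) {
  if (!is.list(signatures) || length(signatures) == 0 ||
      is.null(names(signatures)) || any(!nzchar(names(signatures)))) {
    rlang::abort("`signatures` must be a non-empty named list of protein sets.")
  }
  if (all(lengths(signatures) == 0)) {
    rlang::abort("All signatures are empty.")
  }
  check_fraction(base_prob, "base_prob")
  withr::with_seed(seed, {
    proteins <- sort(unique(unlist(signatures)))
    matched <- stats::setNames(paste0(names(signatures), "_matched"),
                               names(signatures))
    sections <- c(unname(matched),
                  if (n_unmatched_sections > 0)
                    sprintf("section_U%02d", seq_len(n_unmatched_sections)))
    grid <- tidyr::expand_grid(protein = proteins, section = sections)
    p_hi <- rep(base_prob, nrow(grid))
    for (ct in names(signatures)) {
      hit <- grid$section == matched[[ct]] & grid$protein %in% signatures[[ct]]
      p_hi[hit] <- pmin(1, base_prob + enrichment)
    }
    hi <- stats::runif(nrow(grid)) < p_hi
    lvl <- ifelse(hi,
                  ifelse(stats::runif(nrow(grid)) < 0.5, "medium", "high"),
                  ifelse(stats::runif(nrow(grid)) < 0.5, "not detected", "low"))
    out <- grid |>
      dplyr::mutate(level = factor(lvl, levels = c("not detected", "low",
                                                   "medium", "high")))
    attr(out, "matched_sections") <- matched
    out
  })
}
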