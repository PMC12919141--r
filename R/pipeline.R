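# End-to-end orchestration: one seeded configuration drives simulate ->
# derive -> score -> associate -> sliding-window scan -> survival ->
# seno-age, writing TSV/JSON artifacts and a manifest (seeds, input hashes,
# per-stage row counts). Structured log lines go to stderr; results are
# only ever written to files.

#' Pipeline configuration
#'
#' Assembles the settings for [run_pipeline()]. All stages derive their seeds
#' deterministically from `seed`, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param seed Master seed.
#' @param catalog Arguments for [catalog_sim_config()]. The demo default uses
#'   8 replicates per arm so the derived signatures are well populated; the
#'   generator's own default (4) reflects typical catalog designs.
#' @param cohort Arguments for [cohort_sim_config()].
#' @param cohort_b Arguments overriding `cohort` for the second (transfer)
#'   cohort, or NULL to skip cross-study transfer.
#' @param traits Named list: trait -> polarity (`"negative_health"` /
#'   `"positive_health"`). Traits must exist in the simulated cohort.
#' @param k_core Core-signature membership threshold.
#' @param rule Two-induction rule (see [classify_senescence_status()]).
#' @param covariates Trait-model covariates.
#' @param n_boot Bootstrap iterations for mediation.
#' @param n_cv_iter Cross-validation rounds.
#' @param deswan Arguments for the sliding-window stage: `age_range`,
#'   `n_per_decade`, `centers`, `width`.
#' @return List of class `senosig_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            catalog = list(n_replicates = 8),
                            cohort = list(),
                            cohort_b = list(n_participants = 500),
                            traits = list(frailty = "negative_health",
                                          walking_pace = "positive_health",
                                          diabetes = "negative_health"),
                            k_core = 9,
                            rule = "ir_plus_chemical",
                            covariates = c("age", "sex", "race"),
                            n_boot = 200,
                            n_cv_iter = 10,
                            deswan = list(age_range = c(50, 90),
                                          n_per_decade = 120,
                                          centers = 60:80, width = 10)) {
  known_traits <- c("frailty", "walking_pace", "diabetes")
  bad <- setdiff(names(traits), known_traits)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Unknown trait(s) in config: %s. Simulated cohorts provide: %s.",
      paste(bad, collapse = ", "), paste(known_traits, collapse = ", ")))
  }
  bad_pol <- setdiff(unlist(traits), c("negative_health", "positive_health"))
  if (length(bad_pol) > 0) {
    rlang::abort(sprintf("Unknown polarity: %s.", paste(bad_pol, collapse = ", ")))
  }
  structure(list(seed = seed, catalog = catalog, cohort = cohort,
                 cohort_b = cohort_b, traits = traits, k_core = k_core,
                 rule = rule, covariates = covariates, n_boot = n_boot,
                 n_cv_iter = n_cv_iter, deswan = deswan),
            class = "senosig_pipeline_config")
}

# Elastic-net selection preferring the conservative one-SE rule, falling
# back to the CV-minimum penalty when the one-SE selection is empty (the
# pipeline always wants a usable panel when signal exists).
select_with_fallback <- function(data, trait, pool, covariates, seed) {
  sel <- select_features(data, trait, pool, covariates,
                         elastic_net_config(seed = seed))
  if (nrow(sel) == 0) {
    sel <- select_features(data, trait, pool, covariates,
                           elastic_net_config(lambda_rule = "min", seed = seed))
  }
  sel
}

log_stage <- function(stage, ...) {
  message(sprintf("[senosig %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(stage, ...)))
}

#' Run the full senescence-signature pipeline
#'
#' Executes simulate -> derive -> score -> associate -> sliding-window scan
#' -> survival -> seno-age on synthetic inputs and writes all result tables
#' (TSV), signature sets and mediation results (JSON), and a manifest with
#' seeds, MD5 hashes and row counts. Idempotent: the same config writes
#' byte-identical results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "senosig_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  t0 <- Sys.time()
  written <- character(0)
  emit_tsv <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    written <<- c(written, path)
    path
  }
  emit_json <- function(x, name, ...) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, ...)
    written <<- c(written, path)
    path
  }

  # --- simulate + derive ---------------------------------------------------
  log_stage("simulate: catalog")
  cat_cfg <- do.call(catalog_sim_config,
                     utils::modifyList(list(seed = sub_seed(config$seed, "catalog")),
                                       config$catalog))
  catalog <- simulate_catalog(cat_cfg)
  records <- catalog_differential(catalog)
  emit_tsv(records, "catalog_records.tsv")
  log_stage("derive: signatures (rule=%s, k_core=%d)", config$rule, config$k_core)
  sigs <- derive_signatures(records, k_core = config$k_core, rule = config$rule)
  write_signatures_json(sigs, file.path(out_dir, "signatures.json"))
  written <- c(written, file.path(out_dir, "signatures.json"))
  manifest$stages$derive <- list(
    n_records = nrow(records),
    status_counts = as.list(table(sigs$status$status)))

  log_stage("simulate: cohort")
  coh_cfg <- do.call(cohort_sim_config,
                     utils::modifyList(list(seed = sub_seed(config$seed, "cohort")),
                                       config$cohort))
  cohort <- simulate_cohort(coh_cfg, catalog$truth)
  emit_tsv(cohort$data, "cohort.tsv")
  manifest$stages$cohort <- list(n_participants = nrow(cohort$data))

  sap_pool <- intersect(sigs$status$protein[sigs$status$status == "SAP"],
                        names(cohort$data))
  nonsap_pool <- intersect(sigs$status$protein[sigs$status$status == "non-SAP"],
                           names(cohort$data))
  if (length(sap_pool) < 2 || length(nonsap_pool) < 2) {
    rlang::abort("Stage score failed: too few SAP or non-SAP proteins detected.")
  }

  # --- score ---------------------------------------------------------------
  log_stage("score: panels + composite scores (%d trait(s))", length(config$traits))
  panels <- list(); scores <- list()
  for (trait in names(config$traits)) {
    for (pool_name in c("SAP", "nonSAP")) {
      pool <- if (pool_name == "SAP") sap_pool else nonsap_pool
      sel <- select_with_fallback(cohort$data, trait, pool, config$covariates,
                                  sub_seed(config$seed,
                                           paste0("sel_", trait, pool_name)))
      panel <- rank_and_truncate(sel, trait, config$traits[[trait]])
      key <- paste(trait, pool_name, sep = ".")
      panels[[key]] <- panel
      if (nrow(panel$proteins) > 0) {
        scores[[key]] <- composite_score(cohort$data, panel) |>
          dplyr::mutate(trait = trait, pool = pool_name)
      }
    }
  }
  emit_json(purrr::map(panels, function(p) {
    list(trait = p$trait, polarity = p$polarity, proteins = p$proteins$protein,
         effects = p$proteins$effect)
  }), "panels.json")
  score_tbl <- dplyr::bind_rows(scores)
  emit_tsv(score_tbl, "scores.tsv")
  manifest$stages$score <- list(n_panels = length(panels),
                                n_scores = nrow(score_tbl))

  # --- associate -----------------------------------------------------------
  log_stage("associate: trait models, cross-validation, mediation")
  scored <- cohort$data
  for (key in names(scores)) {
    scored[[paste0("score_", gsub("\\.", "_", key))]] <-
      scores[[key]]$score[match(scored$participant, scores[[key]]$participant)]
  }
  assoc <- purrr::map(names(scores), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    fit_trait_model(scored, parts[1], paste0("score_", gsub("\\.", "_", key)),
                    config$covariates) |>
      dplyr::mutate(pool = parts[2])
  }) |> dplyr::bind_rows()
  emit_tsv(assoc, "associations.tsv")

  cv_rows <- list(); paired <- list()
  for (trait in names(config$traits)) {
    cols <- paste0("score_", trait, c("_SAP", "_nonSAP"))
    cvs <- purrr::map(cols, function(cl) {
      if (!cl %in% names(scored)) return(NULL)
      cross_validate(scored, trait, cl, n_iter = config$n_cv_iter,
                     seed = sub_seed(config$seed, paste0("cv_", trait)))
    })
    names(cvs) <- c("SAP", "nonSAP")
    for (g in names(cvs)) {
      if (!is.null(cvs[[g]])) {
        cv_rows[[paste(trait, g)]] <- dplyr::mutate(
          tibble::as_tibble(cvs[[g]]), trait = trait, pool = g)
      }
    }
    if (!is.null(cvs$SAP) && !is.null(cvs$nonSAP)) {
      metric <- if (trait_family(scored[[trait]]) == "binomial") "auc" else "r2"
      paired[[trait]] <- compare_paired_metrics(cvs$nonSAP[[metric]],
                                                cvs$SAP[[metric]]) |>
        dplyr::mutate(trait = trait, metric = metric, .before = 1)
    }
  }
  emit_tsv(dplyr::bind_rows(cv_rows), "cross_validation.tsv")
  emit_tsv(dplyr::bind_rows(paired), "paired_comparison.tsv")

  med_col <- "score_diabetes_SAP"
  if ("diabetes" %in% names(config$traits) && med_col %in% names(scored)) {
    scored$sex01 <- as_binary01(scored$sex)
    med <- mediate(scored, "sex01", med_col, "diabetes",
                   covariates = setdiff(config$covariates, c("age", "sex")),
                   n_boot = config$n_boot,
                   seed = sub_seed(config$seed, "mediate"))
    emit_json(list(estimates = med$estimates, n_boot = med$n_boot),
              "mediation.json")
  }
  manifest$stages$associate <- list(n_models = nrow(assoc))

  # --- sliding-window scan -------------------------------------------------
  log_stage("deswan: balanced downsample + sliding-window scan")
  ds <- balanced_downsample(cohort$data,
                            age_range = config$deswan$age_range,
                            n_per_decade = config$deswan$n_per_decade,
                            seed = sub_seed(config$seed, "downsample"))
  emit_tsv(ds$balance, "downsample_balance.tsv")
  proteins <- intersect(catalog$truth$proteins, names(cohort$data))
  groups <- list(SAP = sap_pool, nonSAP = nonsap_pool)
  scan <- deswan_scan(ds$subsample, proteins, centers = config$deswan$centers,
                      width = config$deswan$width, covariates = "sex",
                      groups = groups)
  emit_tsv(scan$counts, "deswan_counts.tsv")
  by_sex <- sex_stratified_scan(ds$subsample, proteins,
                                centers = config$deswan$centers,
                                width = config$deswan$width,
                                groups = list(SAP = sap_pool))
  peaks <- dplyr::bind_rows(
    dplyr::mutate(deswan_peak(scan, "SAP"), sex = "pooled", .before = 1),
    by_sex$peaks)
  emit_tsv(peaks, "deswan_peaks.tsv")
  manifest$stages$deswan <- list(n_subsample = nrow(ds$subsample),
                                 peaks = stats::setNames(as.list(peaks$peak_age),
                                                         peaks$sex))

  # --- survival ------------------------------------------------------------
  log_stage("survival: left-truncated Cox + quartile trajectories")
  if (med_col %in% names(scored)) {
    cox_rows <- purrr::map(
      list(c(exit = "diabetes_onset_age", status = "diabetes_onset_status",
             endpoint = "diabetes_onset"),
           c(exit = "death_age", status = "death_status", endpoint = "death")),
      function(ep) {
        cx <- fit_cox_left_truncated(scored, med_col, exit = ep[["exit"]],
                                     status = ep[["status"]])
        ph <- schoenfeld_test(cx)
        dplyr::mutate(cx$tidy, endpoint = ep[["endpoint"]],
                      schoenfeld_p = ph$p_value[ph$term == med_col])
      }) |> dplyr::bind_rows()
    emit_tsv(cox_rows, "cox.tsv")
    traj <- quartile_trajectories(scored, med_col, exit = "diabetes_onset_age",
                                  status = "diabetes_onset_status")
    emit_tsv(traj$curves, "trajectories.tsv")
    manifest$stages$survival <- list(n_events = sum(scored$death_status))
  }

  # --- seno-age ------------------------------------------------------------
  log_stage("senoage: signature age models + gaps")
  sig_pools <- list(core = intersect(sigs$core, names(cohort$data)))
  for (ct in names(sigs$exclusive)) {
    ex <- intersect(sigs$exclusive[[ct]], names(cohort$data))
    if (length(ex) >= 3) sig_pools[[ct]] <- ex
  }
  sig_pools <- sig_pools[lengths(sig_pools) >= 3]
  if (length(sig_pools) == 0) {
    log_stage("senoage: derived signature sets too sparse; using the pooled SAP set")
    sig_pools <- list(SAP_union = sap_pool)
  }
  gap_records <- purrr::imap(sig_pools, function(pool, lab) {
    sel <- select_with_fallback(cohort$data, "age", pool,
                                setdiff(config$covariates, "age"),
                                sub_seed(config$seed, paste0("age_", lab)))
    keep <- if (nrow(sel) > 0) {
      rank_and_truncate(sel, "age", "negative_health")$proteins$protein
    } else character(0)
    if (length(keep) < 2) keep <- pool[seq_len(min(10, length(pool)))]
    model <- fit_senoage_model(cohort$data, keep, signature = lab)
    compute_gap(cohort$data, model)
  }) |> dplyr::bind_rows()
  emit_tsv(gap_records, "senoage.tsv")
  if (nrow(gap_records) > 0 && dplyr::n_distinct(gap_records$signature) >= 2) {
    cm <- senoage_correlation_matrix(gap_records, "seno_age")
    emit_tsv(tibble::as_tibble(cm, rownames = "signature"),
             "senoage_correlations.tsv")
  }
  manifest$stages$senoage <- list(
    n_signatures = if (nrow(gap_records) > 0)
      dplyr::n_distinct(gap_records$signature) else 0L)

  # --- manifest ------------------------------------------------------------
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$files <- purrr::map(sort(unique(written)), function(p) {
    list(name = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done (%.1f s)", manifest$elapsed_s)
  invisible(manifest)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file's top-level keys are passed to [pipeline_config()]; validation
#' (unknown traits, bad polarities) happens immediately, before any
#' computation.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Config file `%s` not found.", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      rlang::abort("Reading YAML configs requires the `yaml` package.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$traits)) raw$traits <- as.list(raw$traits)
  do.call(pipeline_config, raw)
}
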