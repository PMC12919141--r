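# Signature derivation: the two-induction SAP rule, per-cell-type and
# cell-type-exclusive signatures, the core signature, cross-platform
# detection crosstabs, and tissue-atlas support.

# Qualification per (protein, cell type): elevated (log2fc > 0, p_adj < alpha)
# in IR plus >= 1 chemical inducer ("ir_plus_chemical", the default), or in
# any two inductions ("any_two").
qualification_table <- function(records, rule = c("ir_plus_chemical", "any_two"),
                                ir_label = "IR", alpha = 0.05) {
  rule <- match.arg(rule)
  check_cols(records, c("protein", "cell_type", "induction", "log2fc", "p_adj"),
             "records")
  if (any(records$p_adj < 0 | records$p_adj > 1, na.rm = TRUE)) {
    rlang::abort("`p_adj` must lie in [0, 1].")
  }
  rec <- records |>
    dplyr::mutate(elevated = .data$log2fc > 0 & .data$p_adj < alpha)
  rec |>
    dplyr::group_by(.data$protein, .data$cell_type) |>
    dplyr::summarise(
      n_elevated = sum(.data$elevated, na.rm = TRUE),
      ir_elevated = any(.data$elevated & .data$induction == ir_label),
      chem_elevated = any(.data$elevated & .data$induction != ir_label),
      mean_qual_log2fc = if (any(.data$elevated))
        mean(.data$log2fc[.data$elevated]) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      qualifies = if (rule == "ir_plus_chemical") {
        .data$ir_elevated & .data$chem_elevated
      } else {
        .data$n_elevated >= 2L
      })
}

#' Classify proteins as SAP, non-SAP, or inconclusive
#'
#' Applies the two-induction rule: a protein is a senescence-associated
#' protein (SAP) if, in at least one cell type, it is significantly elevated
#' (positive log2 fold-change, BH-adjusted p < `alpha`) in two induction
#' methods; a non-SAP if it is elevated nowhere under any induction; and
#' inconclusive otherwise (elevated somewhere, but never qualifying in two
#' inductions of one cell type). The three statuses partition the protein
#' universe.
#'
#' @param records Differential-record tibble with columns `protein`,
#'   `cell_type`, `induction`, `log2fc`, `p_adj`.
#' @param rule `"ir_plus_chemical"` (ionizing radiation plus at least one
#'   chemical inducer; default) or `"any_two"` (any two inductions).
#' @param ir_label Induction label treated as ionizing radiation.
#' @param alpha Adjusted-p significance threshold.
#' @param universe Optional protein universe; proteins without records are
#'   excluded with a warning, never silently dropped.
#' @return Tibble `protein`, `status` (factor SAP / non-SAP / inconclusive).
#' @export
classify_senescence_status <- function(records,
                                       rule = c("ir_plus_chemical", "any_two"),
                                       ir_label = "IR", alpha = 0.05,
                                       universe = NULL) {
  rule <- match.arg(rule)
  qt <- qualification_table(records, rule, ir_label, alpha)
  if (!is.null(universe)) {
    missing <- setdiff(universe, unique(records$protein))
    if (length(missing) > 0) {
      rlang::warn(sprintf(
        "%d protein(s) in the universe have no differential records and are excluded.",
        length(missing)))
    }
  }
  qt |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      any_qualifies = any(.data$qualifies),
      any_elevated = any(.data$n_elevated > 0),
      .groups = "drop") |>
    dplyr::mutate(status = factor(
      dplyr::case_when(
        .data$any_qualifies ~ "SAP",
        !.data$any_elevated ~ "non-SAP",
        TRUE ~ "inconclusive"),
      levels = c("SAP", "non-SAP", "inconclusive"))) |>
    dplyr::select("protein", "status")
}

#' Cell-type senescence signature
#'
#' Proteins qualifying under the two-induction rule within one cell type,
#' with their mean log2 fold-change over the qualifying (elevated)
#' inductions.
#'
#' @inheritParams classify_senescence_status
#' @param cell_type Cell-type label present in `records`.
#' @return Tibble `protein`, `cell_type`, `mean_log2fc`, sorted by protein.
#' @export
cell_type_signature <- function(records, cell_type,
                                rule = c("ir_plus_chemical", "any_two"),
                                ir_label = "IR", alpha = 0.05) {
  rule <- match.arg(rule)
  if (!cell_type %in% unique(records$cell_type)) {
    rlang::abort(sprintf("Unknown cell type `%s`.", cell_type))
  }
  qualification_table(records[records$cell_type == cell_type, , drop = FALSE],
                      rule, ir_label, alpha) |>
    dplyr::filter(.data$qualifies) |>
    dplyr::arrange(.data$protein) |>
    dplyr::select("protein", "cell_type", mean_log2fc = "mean_qual_log2fc")
}

#' All cell-type signatures of a record table
#'
#' @inheritParams classify_senescence_status
#' @param universe Cell types to include (default: all in `records`).
#' @return Named list: cell type -> character vector of signature proteins.
#' @export
cell_type_signatures <- function(records,
                                 rule = c("ir_plus_chemical", "any_two"),
                                 ir_label = "IR", alpha = 0.05,
                                 universe = NULL) {
  rule <- match.arg(rule)
  universe <- universe %||% sort(unique(records$cell_type))
  qt <- qualification_table(records[records$cell_type %in% universe, , drop = FALSE],
                            rule, ir_label, alpha)
  sets <- split(qt$protein[qt$qualifies], qt$cell_type[qt$qualifies])
  out <- stats::setNames(vector("list", length(universe)), universe)
  for (ct in universe) out[[ct]] <- sort(sets[[ct]] %||% character(0))
  out
}

#' Cell-type-exclusive signature
#'
#' Proteins that are signature members of `cell_type` and of no other cell
#' type in the universe. Proteins absent from another cell type's records are
#' treated as not elevated there.
#'
#' @param signatures Named list of per-cell-type signature protein sets (from
#'   [cell_type_signatures()]).
#' @param cell_type Cell type whose exclusive set is requested.
#' @return Character vector of exclusive proteins (sorted).
#' @export
exclusive_signature <- function(signatures, cell_type) {
  if (!cell_type %in% names(signatures)) {
    rlang::abort(sprintf("Unknown cell type `%s`.", cell_type))
  }
  others <- unlist(signatures[setdiff(names(signatures), cell_type)],
                   use.names = FALSE)
  sort(setdiff(signatures[[cell_type]], others))
}

#' Core senescence signature
#'
#' Proteins that are signature members of at least `k_core` cell types of the
#' universe.
#'
#' @param signatures Named list of per-cell-type signature protein sets.
#' @param k_core Minimum membership count (>= 1).
#' @return Character vector of core proteins (sorted).
#' @export
core_signature <- function(signatures, k_core) {
  check_count(k_core, "k_core")
  if (k_core > length(signatures)) {
    rlang::abort("`k_core` cannot exceed the number of cell types.")
  }
  counts <- table(unlist(signatures, use.names = FALSE))
  sort(names(counts)[counts >= k_core])
}

#' Detection crosstab of senescence status across two panels
#'
#' Cross-tabulates SAP / non-SAP / inconclusive counts among the proteins
#' detected on each of two measurement panels and tests status-composition
#' differences with Fisher's exact test (overall 3x2 and pairwise 2x2 per
#' status pair).
#'
#' @param status Tibble from [classify_senescence_status()].
#' @param panel_a,panel_b Character vectors of detected proteins (subsets of
#'   the catalog universe).
#' @param panel_names Length-2 labels for the panels.
#' @return List with `table` (status x panel counts), `proportions`,
#'   `overall_p` (Fisher exact on the full table), and `pairwise` (tibble of
#'   2x2 Fisher p per status pair).
#' @export
detection_crosstab <- function(status, panel_a, panel_b,
                               panel_names = c("panel_a", "panel_b")) {
  if (length(panel_a) == 0 || length(panel_b) == 0) {
    rlang::abort("Panels must be non-empty.")
  }
  lv <- levels(status$status)
  tab <- sapply(list(panel_a, panel_b), function(p) {
    table(factor(status$status[status$protein %in% p], levels = lv))
  })
  colnames(tab) <- panel_names
  pairs <- utils::combn(lv, 2)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(i) {
    sub <- tab[pairs[, i], , drop = FALSE]
    tibble::tibble(status_1 = pairs[1, i], status_2 = pairs[2, i],
                   p_value = stats::fisher.test(sub)$p.value)
  }) |> dplyr::bind_rows()
  list(table = tab,
       proportions = prop.table(tab, margin = 2),
       overall_p = stats::fisher.test(tab)$p.value,
       pairwise = pairwise)
}

#' Tissue-atlas support of a signature
#'
#' For each tissue section, the proportion of signature proteins present in
#' the atlas that are reported at medium or high expression, with sections
#' ranked in descending order of support.
#'
#' @param signature Character vector of proteins.
#' @param atlas Tibble with columns `protein`, `section`, `level` (levels
#'   "not detected", "low", "medium", "high").
#' @return Tibble `section`, `n_signature`, `n_medium_high`, `proportion`,
#'   `rank`, sorted by descending proportion.
#' @export
tissue_support_proportion <- function(signature, atlas) {
  if (length(signature) == 0) rlang::abort("`signature` is empty.")
  check_cols(atlas, c("protein", "section", "level"), "atlas")
  hit <- atlas[atlas$protein %in% signature, , drop = FALSE]
  if (nrow(hit) == 0) {
    rlang::abort("Signature and atlas share no proteins.")
  }
  hit |>
    dplyr::group_by(.data$section) |>
    dplyr::summarise(
      n_signature = dplyr::n_distinct(.data$protein),
      n_medium_high = dplyr::n_distinct(
        .data$protein[.data$level %in% c("medium", "high")]),
      .groups = "drop") |>
    dplyr::mutate(proportion = .data$n_medium_high / .data$n_signature) |>
    dplyr::arrange(dplyr::desc(.data$proportion), .data$section) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Derive the full signature-set bundle from differential records
#'
#' Convenience wrapper producing, in one call, the status partition, the
#' per-cell-type signatures, the exclusive signatures (pairwise disjoint by
#' construction), and the core signature.
#'
#' @inheritParams classify_senescence_status
#' @param k_core Core membership threshold.
#' @param universe Cell types forming the exclusivity universe (default: all).
#' @return List of class `senosig_signatures`: `status`, `signatures`,
#'   `exclusive`, `core`, plus the parameters used.
#' @export
derive_signatures <- function(records, k_core = 9,
                              rule = c("ir_plus_chemical", "any_two"),
                              ir_label = "IR", alpha = 0.05,
                              universe = NULL) {
  rule <- match.arg(rule)
  sigs <- cell_type_signatures(records, rule, ir_label, alpha, universe)
  exclusive <- stats::setNames(
    purrr::map(names(sigs), ~ exclusive_signature(sigs, .x)), names(sigs))
  structure(
    list(status = classify_senescence_status(records, rule, ir_label, alpha),
         signatures = sigs,
         exclusive = exclusive,
         core = core_signature(sigs, min(k_core, length(sigs))),
         k_core = k_core, rule = rule, alpha = alpha),
    class = "senosig_signatures")
}

#' Serialize signature sets to JSON
#'
#' @param signatures A `senosig_signatures` object or a named list of protein
#'   sets.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures_json <- function(signatures, path) {
  x <- if (inherits(signatures, "senosig_signatures")) {
    c(signatures$signatures,
      stats::setNames(signatures$exclusive,
                      paste0(names(signatures$exclusive), ".exclusive")),
      list(core = signatures$core))
  } else {
    signatures
  }
  jsonlite::write_json(purrr::map(x, sort), path, auto_unbox = FALSE)
  invisible(path)
}
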