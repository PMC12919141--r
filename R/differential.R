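# Stand-in differential-abundance engine: per-protein Welch t-test on log2
# intensities with Benjamini-Hochberg correction within each
# (cell type, induction) stratum. The classification layer downstream is
# agnostic to the engine; precomputed differential-record tables are accepted
# everywhere a record tibble is.

#' Differential abundance between senescent and proliferating arms
#'
#' Per-protein Welch t-test on log2 intensities. The log2 fold-change is the
#' difference of arm means (senescent minus proliferating); p-values are
#' two-sided and BH-adjusted across all proteins of the stratum.
#'
#' @param proliferating,senescent Numeric matrices (proteins x replicates)
#'   with identical rownames, log2 scale.
#' @return Tibble with columns `protein`, `log2fc`, `statistic`, `p_value`,
#'   `p_adj`.
#' @details Degenerate rows with zero variance in both arms get p = 1 when the
#'   arm means are equal and p = 0 when they differ (the difference is then
#'   exact). Rows must match between the two matrices.
#' @export
differential_abundance <- function(proliferating, senescent) {
  if (is.null(rownames(proliferating)) || is.null(rownames(senescent)) ||
      !identical(sort(rownames(proliferating)), sort(rownames(senescent)))) {
    rlang::abort("`proliferating` and `senescent` must share identical protein rownames.")
  }
  if (ncol(proliferating) < 2 || ncol(senescent) < 2) {
    rlang::abort("At least 2 replicates per arm are required.")
  }
  senescent <- senescent[rownames(proliferating), , drop = FALSE]
  n1 <- ncol(proliferating); n2 <- ncol(senescent)
  m1 <- rowMeans(proliferating); m2 <- rowMeans(senescent)
  v1 <- apply(proliferating, 1, stats::var)
  v2 <- apply(senescent, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  log2fc <- m2 - m1
  tstat <- log2fc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(abs(log2fc[degenerate]) < .Machine$double.eps^0.5, 1, 0)
  tstat[degenerate] <- ifelse(p[degenerate] == 1, 0, Inf * sign(log2fc[degenerate]))
  tibble::tibble(
    protein = rownames(proliferating),
    log2fc = unname(log2fc),
    statistic = unname(tstat),
    p_value = unname(p),
    p_adj = stats::p.adjust(unname(p), method = "BH"))
}

#' Differential records for every condition of a simulated catalog
#'
#' Runs [differential_abundance()] for each (cell type, induction) stratum of
#' a [simulate_catalog()] result (or any long abundance tibble with the same
#' columns) and stacks the results into one record table.
#'
#' @param catalog A `senosig_catalog` or its long `abundance` tibble.
#' @return Tibble of differential records: `protein`, `cell_type`,
#'   `induction`, `log2fc`, `statistic`, `p_value`, `p_adj` (BH within each
#'   stratum).
#' @export
catalog_differential <- function(catalog) {
  abundance <- if (inherits(catalog, "senosig_catalog")) catalog$abundance else catalog
  check_cols(abundance, c("protein", "cell_type", "induction", "arm",
                          "replicate", "log2_intensity"), "catalog abundance")
  abundance |>
    dplyr::group_by(.data$cell_type, .data$induction) |>
    dplyr::group_modify(function(d, key) {
      wide <- function(a) {
        m <- tidyr::pivot_wider(d[d$arm == a, c("protein", "replicate", "log2_intensity")],
                                names_from = "replicate",
                                values_from = "log2_intensity")
        out <- as.matrix(m[, -1])
        rownames(out) <- m$protein
        out
      }
      differential_abundance(wide("proliferating"), wide("senescent"))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("protein", "cell_type", "induction", "log2fc",
                  "statistic", "p_value", "p_adj")
}
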