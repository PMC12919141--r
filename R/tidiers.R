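# broom-style tidy()/glance() methods and ggplot2 autoplot() methods for the
# package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_boxplot geom_col labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.senosig_cv <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      dplyr::any_of(c("r2", "pseudo_r2", "auc")),
                      names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
}

#' @exportS3Method generics::glance
glance.senosig_cv <- function(x, ...) {
  tibble::tibble(
    n_iterations = nrow(x),
    mean_r2 = mean(x$r2),
    mean_pseudo_r2 = mean(x$pseudo_r2),
    mean_auc = mean(x$auc))
}

#' @exportS3Method generics::tidy
tidy.senosig_mediation <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.senosig_mediation <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure, mediator = x$mediator, outcome = x$outcome,
    n_boot = x$n_boot, conf_level = x$conf_level)
}

#' @exportS3Method generics::tidy
tidy.senosig_cox <- function(x, ...) x$tidy

#' @exportS3Method generics::glance
glance.senosig_cox <- function(x, ...) {
  tibble::tibble(n = x$fit$n, n_events = x$fit$nevent,
                 concordance = unname(x$fit$concordance["concordance"]))
}

#' @exportS3Method generics::tidy
tidy.senosig_senoage_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = gsub("`", "", rownames(sm)), estimate = sm[, 1],
                 std_error = sm[, 2], statistic = sm[, 3], p_value = sm[, 4])
}

#' @exportS3Method generics::glance
glance.senosig_senoage_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(signature = x$signature, r_squared = sm$r.squared,
                 n_proteins = length(x$proteins),
                 n_dropped = length(x$dropped))
}

#' @exportS3Method generics::glance
glance.senosig_signatures <- function(x, ...) {
  tibble::tibble(
    n_sap = sum(x$status$status == "SAP"),
    n_non_sap = sum(x$status$status == "non-SAP"),
    n_inconclusive = sum(x$status$status == "inconclusive"),
    n_core = length(x$core),
    n_cell_types = length(x$signatures))
}

#' Elevated-count curve of a sliding-window scan
#'
#' @param object A `senosig_deswan` or `senosig_deswan_by_sex`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.senosig_deswan <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = .data$center, y = .data$n_elevated,
                               colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Window center age (years)",
                  y = "Elevated proteins (q < threshold)",
                  colour = "Protein group") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.senosig_deswan_by_sex <- function(object, ...) {
  counts <- purrr::imap(object$scans,
                        function(sc, s) dplyr::mutate(sc$counts, sex = s)) |>
    dplyr::bind_rows()
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$center, y = .data$n_elevated,
                                       colour = .data$sex)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Window center age (years)",
                  y = "Elevated proteins", colour = "Sex") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.senosig_trajectories <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$age, y = .data$cum_incidence,
                               colour = .data$quartile)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Age (years)", y = "Cumulative incidence",
                  colour = "Score quartile") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.senosig_cv <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Held-out metric") +
    ggplot2::theme_minimal()
}
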