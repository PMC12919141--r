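# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows n row_number desc pull distinct count rename
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map2 imap pmap keep
#' @importFrom stats lm glm coef predict resid sd cor quantile p.adjust
#'   pt qt rnorm runif rbinom binomial gaussian as.formula shapiro.test
#'   t.test wilcox.test fisher.test complete.cases setNames plogis qlogis
#'   median model.matrix var terms update
NULL

# Column-presence check with a readable error.
check_cols <- function(data, cols, where = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "Column%s %s not found in %s.",
      if (length(missing) > 1) "s" else "",
      paste0("`", missing, "`", collapse = ", "), where
    ))
  }
  invisible(data)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    rlang::abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(as.numeric(x))
}

# Binary trait detection: logical, 2-level factor, or numeric in {0, 1}.
trait_family <- function(x) {
  if (is.logical(x)) return("binomial")
  if (is.factor(x)) {
    if (nlevels(droplevels(x)) == 2L) return("binomial")
    rlang::abort("Factor traits must have exactly two levels.")
  }
  ux <- unique(x[!is.na(x)])
  if (length(ux) < 2L) rlang::abort("Trait is constant.")
  if (all(ux %in% c(0, 1))) return("binomial")
  "gaussian"
}

as_binary01 <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.factor(x)) return(as.numeric(x) - 1)
  as.numeric(x)
}

# Rank-sum AUC (equivalent to the Wilcoxon statistic).
auc_rank <- function(score, outcome) {
  y <- as_binary01(outcome)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Derive a deterministic sub-seed (< 2^31) from a base seed and a label.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 2654435.0 + h) %% 2147483629
}
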