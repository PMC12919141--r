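# Shared fixture builders. Everything is generated in code at test time.

# A differential-record table from a compact elevation specification:
# `elevated` is a tibble/data.frame with columns protein, cell_type,
# induction listing the records that should qualify (log2fc 1, p_adj 0.01);
# all other (protein x cell_type x induction) combinations get a null record
# (log2fc 0 or negative, p_adj 0.9).
make_records <- function(proteins, cell_types = c("astrocyte", "PBMC"),
                         inductions = c("IR", "ETO"), elevated = NULL,
                         null_log2fc = -0.1) {
  grid <- expand.grid(protein = proteins, cell_type = cell_types,
                      induction = inductions, stringsAsFactors = FALSE)
  grid$log2fc <- null_log2fc
  grid$p_adj <- 0.9
  if (!is.null(elevated) && nrow(elevated) > 0) {
    key <- paste(grid$protein, grid$cell_type, grid$induction)
    hit <- key %in% paste(elevated$protein, elevated$cell_type, elevated$induction)
    grid$log2fc[hit] <- 1
    grid$p_adj[hit] <- 0.01
  }
  tibble::as_tibble(grid)
}

# A small participant table with independent standard-normal proteins and a
# trait linearly generated from the first `n_signal` proteins.
make_mini_cohort <- function(n = 200, p = 20, n_signal = 3, beta = 0.5,
                             noise_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    prot <- sprintf("P%03d", seq_len(p))
    X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, prot))
    d <- tibble::as_tibble(X)
    d$participant <- sprintf("S%04d", seq_len(n))
    d$age <- stats::runif(n, 40, 90)
    d$sex <- factor(sample(c("female", "male"), n, TRUE))
    d$race <- factor(sample(c("groupA", "groupB"), n, TRUE))
    d$trait <- as.numeric(X[, seq_len(n_signal), drop = FALSE] %*%
                            rep(beta, n_signal)) +
      stats::rnorm(n, 0, noise_sd)
    d
  })
}

# Brute-force Fisher exact p for a 2x2 table by full hypergeometric
# enumeration over all tables with the observed margins: the two-sided p is
# the total probability of tables no more probable than the observed one.
fisher_2x2_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
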