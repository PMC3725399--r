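# Exact and nonparametric tests used to flag per-dose increases over the
# unirradiated control.

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test for association in a 2x2 table, as used to
#' compare per-dose aberrant-cell (or exchange) proportions against the
#' control sample. The two-sided p-value sums the probabilities of all
#' tables no more probable than the one observed (the convention of
#' [stats::fisher.test()], which performs the computation).
#'
#' @param a,b,c,d nonnegative integer cell counts, row-wise:
#'   `(a, b)` = (positive, negative) in group 1, `(c, d)` in group 2.
#' @param sided `"two.sided"` (default), `"greater"` (group 1 proportion
#'   exceeds group 2) or `"less"`.
#' @return the exact p-value (numeric scalar).
#' @examples
#' fisher_exact(19, 181, 22, 478, sided = "greater")
#' @export
fisher_exact <- function(a, b, c, d, sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  cnt <- c(a, b, c, d)
  if (length(cnt) != 4L || anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("all four cell counts must be nonnegative integers")
  if (sum(cnt) == 0) stop("degenerate table: all counts zero")
  m <- matrix(as.integer(cnt), 2L, 2L, byrow = TRUE)
  stats::fisher.test(m, alternative = sided)$p.value
}

#' Mann-Whitney U test (rank-sum, midrank ties)
#'
#' The U statistic is computed from midranks of the pooled sample:
#' `U = R_a - n_a (n_a + 1) / 2` with `R_a` the rank sum of `sample_a`.
#' For combined sample sizes up to `exact_limit` the p-value is obtained by
#' complete enumeration of all group-label assignments (exact, valid under
#' ties); above it, by the normal approximation with the tie-corrected
#' variance.
#'
#' @param sample_a,sample_b numeric vectors, both non-empty.
#' @param sided `"two.sided"` (default), `"greater"` (values of `sample_a`
#'   tend to exceed `sample_b`) or `"less"`.
#' @param exact_limit combined-size cutoff below or at which the exact
#'   enumeration is used (default 20).
#' @return list with `U` (for `sample_a`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           sided = c("two.sided", "greater", "less"),
                           exact_limit = 20L) {
  sided <- match.arg(sided)
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  if (anyNA(sample_a) || anyNA(sample_b)) stop("samples must not contain NA")
  na <- length(sample_a); nb <- length(sample_b); N <- na + nb
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled)                      # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2

  if (N <= exact_limit) {
    # enumerate every assignment of na labels to the N pooled values
    combs <- utils::combn(N, na)
    Us <- colSums(matrix(rk[combs], nrow = na)) - na * (na + 1) / 2
    p <- switch(sided,
      two.sided = mean(abs(Us - na * nb / 2) >= abs(U - na * nb / 2) - 1e-9),
      greater   = mean(Us >= U - 1e-9),
      less      = mean(Us <= U + 1e-9))
    return(list(U = U, p = p, method = "exact"))
  }

  mu <- na * nb / 2
  ties <- table(rk)
  tiecor <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- na * nb / 12 * ((N + 1) - tiecor)
  if (sig2 <= 0) {                        # all values tied
    return(list(U = U, p = 1, method = "normal"))
  }
  z <- (U - mu) / sqrt(sig2)
  p <- switch(sided,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater   = stats::pnorm(z, lower.tail = FALSE),
    less      = stats::pnorm(z))
  list(U = U, p = min(1, p), method = "normal")
}
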