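# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, by enumeration or closed form, on a code
# path disjoint from the package implementation.

# Fisher exact p by direct hypergeometric enumeration over the table support
# given fixed margins. Two-sided: sum of probabilities of tables no more
# probable than the observed one.
oracle_fisher <- function(a, b, c, d, sided = "two.sided") {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  support <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- dhyper(support, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  switch(sided,
    two.sided = sum(pr[pr <= p_obs * (1 + 1e-7)]),
    greater   = sum(pr[support >= a]),
    less      = sum(pr[support <= a]))
}

# Mann-Whitney U by direct pair counting (no ranks).
oracle_u <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  sum(cmp)
}

# Exact Mann-Whitney p by complete enumeration of group-label assignments,
# with U computed by pair counting for every assignment.
oracle_mw_p <- function(x, y, sided = "two.sided") {
  pooled <- c(x, y); na <- length(x); N <- length(pooled)
  Uobs <- oracle_u(x, y)
  combs <- utils::combn(N, na)
  Us <- apply(combs, 2, function(idx) oracle_u(pooled[idx], pooled[-idx]))
  mu <- na * (N - na) / 2
  switch(sided,
    two.sided = mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9),
    greater   = mean(Us >= Uobs - 1e-9),
    less      = mean(Us <= Uobs + 1e-9))
}

# Delta-method 95% upper confidence limit for the threshold dose of a
# LINEAR fit: D* = (y - c)/alpha, gradient (-1/alpha, -D*/alpha).
oracle_linear_ucl <- function(est, cov, y_detect, level = 0.95) {
  d <- (y_detect - est[1]) / est[2]
  g <- c(-1 / est[2], -d / est[2])
  d + qnorm(level) * sqrt(drop(t(g) %*% cov %*% g))
}

# A small deterministic scoring table lying exactly on a given curve
# (counts rounded to integers only when round = TRUE).
make_table <- function(doses, n, counts_list) {
  as_scoring_table(data.frame(
    dose_gy = doses, cells_scored = n,
    breaks = counts_list$breaks,
    aberrant_cells = counts_list$aberrant_cells,
    stable_exchanges = counts_list$stable_exchanges,
    unstable_exchanges = counts_list$unstable_exchanges,
    total_aberrations = counts_list$total_aberrations))
}

# Table-1-design count table from a single endpoint count vector (the other
# endpoints kept consistent but inert).
endpoint_table <- function(y, endpoint, doses = c(0, 0.1, 0.25, 0.5, 1),
                           n = c(500, 200, 200, 200, 200)) {
  base <- list(breaks = y, aberrant_cells = pmin(y, n),
               stable_exchanges = 0 * y, unstable_exchanges = 0 * y,
               total_aberrations = y)
  if (endpoint == "aberrant_cells") base$total_aberrations <- pmin(y, n)
  make_table(doses, n, base)
}
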