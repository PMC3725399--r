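# Dose-response model families for aberration yields, maximum-likelihood
# fitting to per-dose count data, and nested-model comparison.
#
# Families (D = dose in Gy, all parameters >= 0 unless noted):
#   LINEAR          Y(D) = c + alpha * D
#   LQ              Y(D) = c + alpha * D + beta * D^2
#   EXP_SATURATION  F(D) = f_max - (f_max - c) * exp(-k * D),  c <= f_max, k > 0
#   HRS_LQ          Y(D) = c + [alpha_r + (alpha_s - alpha_r) exp(-D/d_c)] D
#                          + beta * D^2,  alpha_s >= alpha_r, d_c > 0
# HRS_LQ is the induced-repair (low-dose hyper-radiosensitivity) modification
# of the LQ alpha term: the effective per-Gy slope relaxes from alpha_s at
# D -> 0 to alpha_r beyond the transition dose d_c, and reduces exactly to LQ
# when alpha_s = alpha_r.

.dr_family_names <- c("LINEAR", "LQ", "EXP_SATURATION", "HRS_LQ")

#' Dose-response model family
#'
#' @param name one of `"LINEAR"`, `"LQ"`, `"EXP_SATURATION"`, `"HRS_LQ"`.
#' @param endpoint_kind `"COUNT_PER_CELL"` (per-cell event yield, Poisson
#'   likelihood) or `"CELL_FRACTION"` (fraction of cells, binomial
#'   likelihood, mean bounded in \[0, 1\]).
#' @return a `dr_family` object: parameter names, mean function, constraint
#'   checker and bounds used by [fit_dose_response()].
#' @export
dr_family <- function(name = .dr_family_names,
                      endpoint_kind = c("COUNT_PER_CELL", "CELL_FRACTION")) {
  name <- match.arg(name)
  endpoint_kind <- match.arg(endpoint_kind)
  par_names <- switch(name,
    LINEAR         = c("c", "alpha"),
    LQ             = c("c", "alpha", "beta"),
    EXP_SATURATION = c("c", "f_max", "k"),
    HRS_LQ         = c("c", "alpha_r", "alpha_s", "d_c", "beta"))
  mean_fn <- switch(name,
    LINEAR         = function(p, D) p[[1L]] + p[[2L]] * D,
    LQ             = function(p, D) p[[1L]] + p[[2L]] * D + p[[3L]] * D^2,
    EXP_SATURATION = function(p, D) p[[2L]] - (p[[2L]] - p[[1L]]) * exp(-p[[3L]] * D),
    HRS_LQ         = function(p, D)
      p[[1L]] + (p[[2L]] + (p[[3L]] - p[[2L]]) * exp(-D / p[[4L]])) * D +
        p[[5L]] * D^2)
  check <- switch(name,
    LINEAR         = function(p) all(p >= 0),
    LQ             = function(p) all(p >= 0),
    EXP_SATURATION = function(p) p[[1L]] >= 0 && p[[2L]] >= p[[1L]] &&
      p[[3L]] > 0 && (endpoint_kind != "CELL_FRACTION" || p[[2L]] <= 1),
    HRS_LQ         = function(p) all(p >= 0) && p[[3L]] >= p[[2L]] && p[[4L]] > 0)
  lower <- switch(name,
    LINEAR         = c(1e-9, 0),
    LQ             = c(1e-9, 0, 0),
    EXP_SATURATION = c(1e-9, 1e-6, 1e-6),
    HRS_LQ         = c(1e-9, 0, 0, 1e-3, 0))
  upper <- switch(name,
    EXP_SATURATION = c(Inf, if (endpoint_kind == "CELL_FRACTION") 1 else Inf, Inf),
    rep(Inf, length(par_names)))
  structure(list(name = name, endpoint_kind = endpoint_kind,
                 par_names = par_names, n_par = length(par_names),
                 mean_fn = mean_fn, check = check,
                 lower = lower, upper = upper),
            class = "dr_family")
}

#' Evaluate a family's mean function
#'
#' @param family a [dr_family()] (or family name, resolved with
#'   `endpoint_kind = "COUNT_PER_CELL"`).
#' @param params numeric parameter vector satisfying the family invariants.
#' @param dose nonnegative dose(s) in Gy.
#' @return expected yield (per-cell rate or cell fraction), vectorized over
#'   `dose`.
#' @export
predict_yield <- function(family, params, dose) {
  if (is.character(family)) family <- dr_family(family)
  stopifnot(inherits(family, "dr_family"))
  if (length(params) != family$n_par)
    stop(sprintf("family %s needs %d parameters (%s)", family$name,
                 family$n_par, paste(family$par_names, collapse = ", ")))
  if (!family$check(params))
    stop(sprintf("parameters violate the %s constraints", family$name))
  if (any(dose < 0)) stop("dose must be >= 0")
  family$mean_fn(as.numeric(params), dose)
}

# deterministic moment-based starting values from (dose, frequency) pairs
.dr_starts <- function(family, dose, freq) {
  c0 <- max(freq[which.min(dose)], 1e-4)
  dmax <- max(dose); fmax_obs <- max(freq)
  sec <- max((fmax_obs - c0) / max(dmax, 1e-6), 1e-4)
  pos <- dose > 0
  low <- if (any(pos)) {
    d1 <- min(dose[pos])
    max((freq[dose == d1][1L] - c0) / d1, 1e-4)
  } else sec
  base <- switch(family$name,
    LINEAR         = c(c0, sec),
    LQ             = c(c0, min(low, sec),
                       max((fmax_obs - c0 - min(low, sec) * dmax) / dmax^2, 1e-4)),
    EXP_SATURATION = c(c0, min(max(2 * fmax_obs, c0 + 0.01),
                               if (family$endpoint_kind == "CELL_FRACTION") 0.99 else Inf),
                       1),
    HRS_LQ         = { s <- .dr_starts(dr_family("LQ", family$endpoint_kind),
                                       dose, freq)[[1L]]
                       c(s[1L], s[2L], 2 * s[2L], 0.2, s[3L]) })
  # a small deterministic grid of perturbed starts guards against local optima
  alts <- lapply(c(0.5, 2), function(m) { p <- base; p[-1L] <- p[-1L] * m; p })
  c(list(base), alts)
}

#' Fit a dose-response model to a per-dose scoring table
#'
#' Maximum-likelihood fit of a [dr_family()] mean function to one endpoint of
#' a [as_scoring_table()] table. Per-cell event counts are modelled as
#' `count_d ~ Poisson(n_d * Y(D_d))`; the aberrant-cell endpoint as
#' `count_d ~ Binomial(n_d, F(D_d))`. A weighted-least-squares mode on the
#' observed frequencies (weights `n_d / Y`, the inverse Poisson variance) is
#' available as `method = "wls"`. Optimization is bounded quasi-Newton
#' (L-BFGS-B) from several deterministic moment-based starts; the parameter
#' covariance is the inverse observed information at the optimum.
#'
#' @param table a `scoring_table`.
#' @param endpoint one of `"breaks"`, `"aberrant_cells"`,
#'   `"stable_exchanges"`, `"unstable_exchanges"`, `"total_aberrations"`.
#' @param family a `dr_family` or family name; the endpoint kind is forced
#'   to match the endpoint.
#' @param method `"ml"` (default) or `"wls"`.
#' @return a `dose_response_fit`: estimates, covariance, log-likelihood,
#'   deviance, the fitted data, convergence status and any warnings.
#' @export
fit_dose_response <- function(table, endpoint, family, method = c("ml", "wls")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "scoring_table"))
  endpoint <- match.arg(endpoint, .endpoints)
  kind <- .endpoint_kind(endpoint)
  if (is.character(family)) family <- dr_family(family, kind)
  if (family$endpoint_kind != kind) family <- dr_family(family$name, kind)

  dose <- table$dose_gy
  y <- table[[endpoint]]
  n <- table$cells_scored
  if (any(y < 0) || any(n < 1)) stop("counts and cells_scored must be positive")
  k <- family$n_par
  if (length(dose) < k)
    stop(sprintf("%s has %d free parameters but only %d dose levels are available",
                 family$name, k, length(dose)))
  warnings <- character(0)
  if (length(dose) == k)
    warnings <- c(warnings, sprintf(
      "%s uses as many parameters as dose levels: no residual degrees of freedom",
      family$name))

  f <- family$mean_fn
  big <- 1e10
  nll <- if (method == "wls") {
    fr <- y / n
    function(p) {
      mu <- f(p, dose)
      if (any(!is.finite(mu)) || any(mu <= 0) ||
          (kind == "CELL_FRACTION" && any(mu >= 1))) return(big)
      sum(n * (fr - mu)^2 / mu)
    }
  } else if (kind == "CELL_FRACTION") {
    function(p) {
      mu <- f(p, dose)
      if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) return(big)
      -sum(stats::dbinom(y, n, mu, log = TRUE))
    }
  } else {
    function(p) {
      mu <- n * f(p, dose)
      if (any(!is.finite(mu)) || any(mu <= 0)) return(big)
      -sum(stats::dpois(y, mu, log = TRUE))
    }
  }

  best <- NULL
  for (start in .dr_starts(family, dose, y / n)) {
    start <- pmax(pmin(start, family$upper - 1e-9), family$lower)
    o <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B",
                   lower = family$lower, upper = family$upper,
                   control = list(factr = 10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(o) || o$value >= big) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop(sprintf("fit of %s to endpoint '%s' did not converge", family$name,
                 endpoint))
  est <- stats::setNames(best$par, family$par_names)

  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  cov <- NULL
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov) || any(!is.finite(cov)) || any(diag(cov) < 0)) {
      cov <- MASS::ginv(H)
      warnings <- c(warnings, "observed information singular; pseudo-inverse covariance")
    }
  }
  if (is.null(cov)) {
    cov <- matrix(0, k, k)
    warnings <- c(warnings, "Hessian unavailable; zero covariance recorded")
  }
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(family$par_names, family$par_names)

  mu <- f(best$par, dose)
  ll <- if (method == "wls") NA_real_ else -best$value
  dev <- if (method == "wls") best$value
  else if (kind == "CELL_FRACTION") {
    term <- function(obs, m) ifelse(obs == 0, 0, obs * log(obs / m))
    2 * sum(term(y, n * mu) + term(n - y, n - n * mu))
  } else {
    m <- n * mu
    2 * sum(ifelse(y == 0, 0, y * log(y / m)) - (y - m))
  }

  structure(list(family = family, estimates = est, covariance = cov,
                 log_likelihood = ll, deviance = dev,
                 n_doses = length(dose), endpoint = endpoint, method = method,
                 data = data.frame(dose_gy = dose, count = y, cells_scored = n,
                                   observed = y / n, fitted = mu),
                 convergence = best$convergence, warnings = warnings),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit: %s, endpoint '%s' (%s)\n", x$family$name,
              x$endpoint, x$method))
  se <- sqrt(pmax(diag(x$covariance), 0))
  print(data.frame(estimate = x$estimates, se = se))
  cat(sprintf("deviance %.4g on %d dose levels\n", x$deviance, x$n_doses))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, dose = NULL, ...) {
  if (is.null(dose)) dose <- object$data$dose_gy
  predict_yield(object$family, object$estimates, dose)
}

# nesting map: reduced -> allowed full families
.dr_nesting <- list(LINEAR = c("LQ", "HRS_LQ"), LQ = "HRS_LQ")

#' Compare nested dose-response fits by F-test
#'
#' Extra-sum-of-squares style F-test on the deviance reduction of a full
#' model over a reduced model nested within it (LINEAR within LQ, LQ within
#' HRS_LQ), with degrees of freedom counted in dose levels:
#' `F = ((dev_r - dev_f) / dp) / (dev_f / (n_doses - p_full))`.
#'
#' @param fit_reduced,fit_full `dose_response_fit`s of nested families on the
#'   same data.
#' @return list with `F`, `p`, and the degrees of freedom `df1`, `df2`.
#' @export
compare_models <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "dose_response_fit"),
            inherits(fit_full, "dose_response_fit"))
  allowed <- .dr_nesting[[fit_reduced$family$name]]
  if (!identical(fit_reduced$family$name, fit_full$family$name) &&
      !(fit_full$family$name %in% allowed))
    stop(sprintf("%s is not nested in %s", fit_reduced$family$name,
                 fit_full$family$name))
  d1 <- fit_reduced$data; d2 <- fit_full$data
  if (!isTRUE(all.equal(d1[c("dose_gy", "count", "cells_scored")],
                        d2[c("dose_gy", "count", "cells_scored")])))
    stop("fits must be to the same data")
  p_full <- fit_full$family$n_par
  n <- fit_full$n_doses
  if (p_full >= n)
    stop("no uncertainty in the regression: the full model has no residual degrees of freedom, p is not calculated")
  df1 <- p_full - fit_reduced$family$n_par
  if (df1 < 1L) {                      # identical families: F = 0, p = 1
    df1 <- 1L
  }
  df2 <- n - p_full
  drop <- max(fit_reduced$deviance - fit_full$deviance, 0)
  Fstat <- (drop / df1) / (fit_full$deviance / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}
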