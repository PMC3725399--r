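test_that("minimal detectable yield matches direct Fisher enumeration", {
  crit <- detect_criterion(c(26, 500), n_cells = 200, alpha = 0.05)
  yd <- minimal_detectable_yield(crit)
  # oracle: smallest k whose one-sided enumeration p rejects
  k_star <- NA
  for (k in 0:200) {
    if (oracle_fisher(k, 200 - k, 26, 474, "greater") < 0.05) { k_star <- k; break }
  }
  expect_equal(yd, k_star / 200)
  expect_gt(yd, 26 / 500)

  # zero-count control: k* from the pure hypergeometric tail
  crit0 <- detect_criterion(c(0, 500), n_cells = 200, alpha = 0.05)
  yd0 <- minimal_detectable_yield(crit0)
  k0 <- NA
  for (k in 0:200) {
    if (oracle_fisher(k, 200 - k, 0, 500, "greater") < 0.05) { k0 <- k; break }
  }
  expect_equal(yd0, k0 / 200)
})

test_that("detectable yield approaches the control frequency as scoring deepens", {
  yds <- vapply(c(100, 200, 1000, 20000), function(m)
    minimal_detectable_yield(detect_criterion(c(26, 500), n_cells = m)),
    numeric(1))
  expect_true(all(diff(yds) <= 1e-12))
  expect_true(all(yds > 26 / 500))
  # the gap above the control frequency shrinks with scoring depth (it does
  # not vanish: the control sample's own uncertainty bounds it below)
  expect_lt(yds[4] - 26 / 500, (yds[1] - 26 / 500) / 2)
})

test_that("raising alpha or scoring depth never raises the threshold dose", {
  tab <- table1_fixture()
  fit <- fit_dose_response(tab, "breaks", "LQ")
  d_of <- function(alpha, m) threshold_dose(fit,
    minimal_detectable_yield(detect_criterion(c(26, 500), m, alpha)))
  expect_true(all(diff(vapply(c(0.01, 0.05, 0.1, 0.2), d_of, numeric(1),
                              m = 200)) <= 1e-9))
  expect_true(all(diff(vapply(c(100, 200, 500, 2000), function(m)
    d_of(0.05, m), numeric(1))) <= 1e-9))
})

test_that("threshold inversion: closed forms, background short-circuit, range errors", {
  tab <- table1_fixture()
  fit <- fit_dose_response(tab, "total_aberrations", "LINEAR")
  cc <- unname(fit$estimates[1]); a <- unname(fit$estimates[2])
  expect_equal(threshold_dose(fit, cc + 0.3 * a), 0.3, tolerance = 1e-9)
  expect_equal(threshold_dose(fit, cc), 0)
  expect_equal(threshold_dose(fit, cc / 2), 0)   # below background
  expect_error(threshold_dose(fit, cc + 10 * a), "not attained")

  # LQ closed form against uniroot
  flq <- fit_dose_response(tab, "breaks", "LQ")
  y <- 0.09
  d_root <- uniroot(function(D) predict(flq, D) - y, c(0, 2), tol = 1e-10)$root
  expect_equal(threshold_dose(flq, y), d_root, tolerance = 1e-6)

  # exp-saturation closed form against uniroot
  fab <- fit_dose_response(tab, "aberrant_cells", "EXP_SATURATION")
  d_root2 <- uniroot(function(D) predict(fab, D) - 0.08, c(0, 2), tol = 1e-10)$root
  expect_equal(threshold_dose(fab, 0.08), d_root2, tolerance = 1e-6)
})

test_that("zero covariance degenerates the upper CL to the point estimate", {
  tab <- table1_fixture()
  fit <- fit_dose_response(tab, "breaks", "LQ")
  fit$covariance[] <- 0
  out <- threshold_upper_cl(fit, 0.09, n_draws = 1000, seed = 1)
  expect_identical(out$upper_cl, out$d_star)
})

test_that("Monte-Carlo upper CL agrees with the delta method on a linear fit", {
  # high-count linear data so the sampling distribution is tight and far
  # from the constraint boundary
  doses <- c(0, 0.25, 0.5, 0.75, 1); n <- rep(5000L, 5)
  set.seed(405)
  y <- rpois(5, n * (0.05 + 0.3 * doses))
  tab <- endpoint_table(y, "breaks", doses, n)
  fit <- fit_dose_response(tab, "breaks", "LINEAR")
  yd <- 0.2
  mc <- threshold_upper_cl(fit, yd, n_draws = 1e5, seed = 9)
  dm <- oracle_linear_ucl(unname(fit$estimates), fit$covariance, yd)
  expect_equal(mc$upper_cl, dm, tolerance = 0.02)
  expect_lte(mc$d_star, mc$upper_cl)
})

test_that("upper CL is reproducible bit-for-bit under a fixed seed", {
  fit <- fit_dose_response(table1_fixture(), "breaks", "LQ")
  a <- threshold_upper_cl(fit, 0.09, n_draws = 2000, seed = 77)
  b <- threshold_upper_cl(fit, 0.09, n_draws = 2000, seed = 77)
  expect_identical(a, b)
  c2 <- threshold_upper_cl(fit, 0.09, n_draws = 2000, seed = 78)
  expect_false(identical(a$upper_cl, c2$upper_cl))
})

test_that("threshold_table runs all endpoints and enforces the sensitivity ordering", {
  tab <- table1_fixture()
  thr <- threshold_table(tab, n_draws = 5000, seed = 123)
  expect_identical(nrow(thr), 5L)
  expect_true(all(!is.na(thr$d_star)))
  expect_true(all(thr$d_star <= thr$upper_cl95))
  get <- function(ep) thr$d_star[thr$endpoint == ep]
  # exchange endpoints are markedly less sensitive than the yield endpoints
  expect_gt(min(get("stable_exchanges"), get("unstable_exchanges")),
            max(get("breaks"), get("aberrant_cells"), get("total_aberrations")))
  # empirical thresholds: first significant dose
  expect_equal(thr$empirical_gy[thr$endpoint == "aberrant_cells"], 0.1)
  expect_equal(thr$empirical_gy[thr$endpoint == "stable_exchanges"], 1)

  # a flat table: no threshold attained, errors recorded per endpoint
  flat <- make_table(c(0, 0.1, 0.25, 0.5, 1), c(500, 200, 200, 200, 200),
                     list(breaks = c(25, 10, 10, 10, 10),
                          aberrant_cells = c(22, 9, 9, 9, 9),
                          stable_exchanges = c(2, 1, 1, 1, 1),
                          unstable_exchanges = c(2, 1, 1, 1, 1),
                          total_aberrations = c(22, 9, 9, 9, 9)))
  thr2 <- threshold_table(flat, n_draws = 2000, seed = 5)
  expect_true(any(!is.na(thr2$error)) || all(is.na(thr2$empirical_gy)))
})

test_that("simulated tables yield thresholds near the analytic plug-in truth", {
  # truth: total-aberration LQ rate of the generator defaults
  true_rate <- c(0.044, 0.21, 0.15)
  crit <- detect_criterion(c(22, 500), 200, 0.05)
  yd <- minimal_detectable_yield(crit)
  d_true <- uniroot(function(D) true_rate[1] + true_rate[2] * D +
                      true_rate[3] * D^2 - yd, c(0, 2))$root
  set.seed(406)
  ds <- replicate(30, {
    tab <- tabulate_records(simulate_scoring(sim_config(seed = sample.int(1e6, 1))))
    fit <- fit_dose_response(tab, "total_aberrations", "LQ")
    threshold_dose(fit, yd)
  })
  expect_lt(abs(mean(ds) - d_true), 3 * sd(ds) / sqrt(length(ds)) + 0.02)
})
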