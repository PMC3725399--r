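test_that("mean functions evaluate correctly and reject invalid parameters", {
  D <- c(0, 0.1, 0.5, 1)
  # every family returns the background at dose 0
  expect_equal(predict_yield("LINEAR", c(0.044, 0.24), 0), 0.044)
  expect_equal(predict_yield("LQ", c(0.05, 0.1, 0.05), 0), 0.05)
  expect_equal(predict_yield("EXP_SATURATION", c(0.04, 0.3, 1.5), 0), 0.04)
  expect_equal(predict_yield("HRS_LQ", c(0.05, 0.2, 0.6, 0.2, 0.1), 0), 0.05)

  expect_equal(predict_yield("LINEAR", c(0.044, 0.24), 1), 0.284)
  expect_equal(predict_yield("LQ", c(0.05, 0.1, 0.05), D),
               0.05 + 0.1 * D + 0.05 * D^2)

  # induced-repair model with alpha_s = alpha_r reduces exactly to LQ
  for (dc in c(0.05, 0.3, 1)) {
    expect_equal(predict_yield("HRS_LQ", c(0.05, 0.1, 0.1, dc, 0.05),
                               c(0.1, 0.5, 1)),
                 predict_yield("LQ", c(0.05, 0.1, 0.05), c(0.1, 0.5, 1)))
  }

  expect_error(predict_yield("LQ", c(-0.1, 0.1, 0.1), 1), "constraints")
  expect_error(predict_yield("HRS_LQ", c(0.05, 0.3, 0.1, 0.2, 0.1), 1),
               "constraints")  # alpha_s < alpha_r
  expect_error(predict_yield("LQ", c(0.1, 0.1), 1), "3 parameters")
})

test_that("zero-residual data recover their generating parameters", {
  # n chosen so every expected count is an exact integer: the data sit
  # exactly on the curve and the fit must be zero-deviance
  doses <- c(0, 0.1, 0.25, 0.5, 1); n <- rep(8000L, 5)
  truth <- c(0.05, 0.1, 0.05)
  y <- as.integer(n * (truth[1] + truth[2] * doses + truth[3] * doses^2))
  stopifnot(all(abs(y - n * (truth[1] + truth[2] * doses + truth[3] * doses^2)) < 1e-9))
  tab <- endpoint_table(y, "breaks", doses, n)
  fit <- fit_dose_response(tab, "breaks", "LQ")
  expect_equal(unname(fit$estimates), truth, tolerance = 2e-3)
  expect_lt(fit$deviance, 1e-4)
  expect_equal(fit$data$fitted, fit$data$observed, tolerance = 1e-4)

  # exp-saturation on the cell-fraction endpoint
  truth2 <- c(0.044, 0.3, 1.5)
  fr <- truth2[2] - (truth2[2] - truth2[1]) * exp(-truth2[3] * doses)
  y2 <- round(n * fr)
  tab2 <- endpoint_table(y2, "aberrant_cells", doses, n)
  fit2 <- fit_dose_response(tab2, "aberrant_cells", "EXP_SATURATION")
  expect_equal(unname(fit2$estimates), truth2, tolerance = 2e-2)
})

test_that("fit output is well-formed: psd covariance, nonneg predictions, warnings", {
  tab <- table1_fixture()
  fit <- fit_dose_response(tab, "breaks", "LQ")
  expect_s3_class(fit, "dose_response_fit")
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  expect_true(all(predict(fit, seq(0, 1, by = 0.05)) >= 0))
  expect_identical(fit$n_doses, 5L)

  # saturated parameterization records a warning
  hrs <- fit_dose_response(tab, "breaks", "HRS_LQ")
  expect_match(hrs$warnings, "no residual degrees of freedom", all = FALSE)

  # too few dose levels is an error
  expect_error(fit_dose_response(tab[1:2, ], "breaks", "LQ"),
               "dose levels")
})

test_that("deviance decreases along nested families; HRS at alpha_s=alpha_r equals LQ", {
  tab <- table1_fixture()
  f_lin <- fit_dose_response(tab, "total_aberrations", "LINEAR")
  f_lq <- fit_dose_response(tab, "total_aberrations", "LQ")
  expect_lte(f_lq$deviance, f_lin$deviance + 1e-6)

  # log-likelihood reduction identity
  lq <- fit_dose_response(tab, "breaks", "LQ")
  p <- unname(lq$estimates)
  ll_hrs <- sum(dpois(tab$breaks, tab$cells_scored *
    predict_yield("HRS_LQ", c(p[1], p[2], p[2], 0.2, p[3]), tab$dose_gy),
    log = TRUE))
  expect_equal(ll_hrs, lq$log_likelihood)
})

test_that("wls mode fits frequencies and is exposed alongside ml", {
  tab <- table1_fixture()
  fit <- fit_dose_response(tab, "breaks", "LQ", method = "wls")
  expect_identical(fit$method, "wls")
  expect_true(is.na(fit$log_likelihood))
  # both criteria agree on clean curve data
  doses <- c(0, 0.1, 0.25, 0.5, 1); n <- rep(2000L, 5)
  y <- round(n * (0.05 + 0.2 * doses))
  tab2 <- endpoint_table(y, "breaks", doses, n)
  expect_equal(unname(fit_dose_response(tab2, "breaks", "LINEAR", "wls")$estimates),
               unname(fit_dose_response(tab2, "breaks", "LINEAR", "ml")$estimates),
               tolerance = 1e-3)
})

test_that("model comparison: nesting rules, identity case, saturated rejection", {
  tab <- table1_fixture()
  f_lin <- fit_dose_response(tab, "total_aberrations", "LINEAR")
  f_lq <- fit_dose_response(tab, "total_aberrations", "LQ")
  cmp <- compare_models(f_lin, f_lq)
  expect_true(cmp$F >= 0)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
  expect_identical(c(cmp$df1, cmp$df2), c(1L, 2L))

  # identical fits: F = 0, p = 1
  cmp0 <- compare_models(f_lq, f_lq)
  expect_equal(cmp0$F, 0)
  expect_equal(cmp0$p, 1)

  # non-nested pair rejected
  f_ab <- fit_dose_response(tab, "aberrant_cells", "EXP_SATURATION")
  expect_error(compare_models(f_lq, f_ab), "not nested")
  # different data rejected
  f_other <- fit_dose_response(tab, "breaks", "LQ")
  expect_error(compare_models(f_lin, f_other), "same data")

  # full model with as many parameters as dose levels: p is not calculated
  f_hrs <- fit_dose_response(tab, "breaks", "HRS_LQ")
  expect_error(compare_models(f_other, f_hrs), "no uncertainty")
})

test_that("F-test does not exceed its nominal level on linear-truth simulations", {
  set.seed(404)
  doses <- c(0, 0.1, 0.25, 0.5, 1); n <- c(500, 200, 200, 200, 200)
  truef <- 0.044 + 0.21 * doses
  rej <- 0; reps <- 300
  for (r in 1:reps) {
    y <- rpois(5, n * truef)
    tab <- endpoint_table(y, "total_aberrations", doses, n)
    cmp <- compare_models(fit_dose_response(tab, "total_aberrations", "LINEAR"),
                          fit_dose_response(tab, "total_aberrations", "LQ"))
    if (cmp$p < 0.05) rej <- rej + 1
  }
  # deviance-based F with 2 residual dose levels is conservative: the
  # rejection rate must stay at or below nominal (plus Monte-Carlo slack)
  expect_lt(rej / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("fit reports serialize to JSON and back", {
  fit <- fit_dose_response(table1_fixture(), "breaks", "LQ")
  js <- fit_report_json(fit)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(parsed$family, "LQ")
  expect_equal(unlist(parsed$estimates), fit$estimates)
  expect_equal(parsed$deviance, fit$deviance)
  expect_equal(nrow(parsed$observed_vs_predicted), 5L)
})
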