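test_that("delta-method budget matches the closed-form example and is additive", {
  m <- calibration_model("constrained", b = 0.2, c = 0.1)
  # exact model, no response noise: no dose uncertainty
  b0 <- dose_uncertainty(m, predict_response(m, 2), 0)
  expect_equal(b0$sigma_dose, 0)

  y1 <- predict_response(m, 1)  # 1/12
  b1 <- dose_uncertainty(m, y1, 0.001)
  expect_equal(b1$dose, 1)
  expect_equal(b1$sigma_dose, 0.1 / y1^2 * 0.001, tolerance = 1e-9)
  expect_equal(b1$sigma_dose, 0.0144, tolerance = 1e-3)
  expect_equal(b1$relative_pct, 1.44, tolerance = 1e-3)

  # total variance is exactly the sum of the two component variances
  mf <- std_xrqa2_model()
  bt <- dose_uncertainty(mf, predict_response(mf, 0.7), 3e-4)
  expect_equal(bt$sigma_dose^2,
               sum(bt$components^2), tolerance = 1e-12)
  # optional extra response-sigma term adds in quadrature
  bx <- dose_uncertainty(mf, predict_response(mf, 0.7), 3e-4,
                         sigma_y_extra = 4e-4)
  expect_gt(bx$sigma_dose, bt$sigma_dose)
})

test_that("delta-method budgets agree with Monte Carlo within 5%", {
  set.seed(99)
  n_mc <- 1e5
  m <- calibration_model("constrained", b = 0.2, c = 0.1)
  y1 <- predict_response(m, 1)
  sy <- 0.001
  mc <- invert_dose(m, y1 + rnorm(n_mc, 0, sy))
  expect_equal(dose_uncertainty(m, y1, sy)$sigma_dose, sd(mc),
               tolerance = 0.05)

  # full covariance case: parameter draws plus response noise
  mf <- std_xrqa2_model()
  y2 <- predict_response(mf, 2)
  pars <- draw_params(mf, n_mc)
  ymc <- y2 + rnorm(n_mc, 0, 3e-4)
  xmc <- (ymc) / (pars[, 2] - pars[, 1] * ymc)  # columns (b, c)
  expect_equal(dose_uncertainty(mf, y2, 3e-4)$sigma_dose, sd(xmc),
               tolerance = 0.05)
})

test_that("saturated responses have no defined uncertainty", {
  m <- calibration_model("constrained", b = 0.2, c = 0.1)
  expect_error(dose_uncertainty(m, 0.5, 1e-4), "saturation")
})

test_that("relative uncertainty decreases with dose for constant response noise", {
  m <- std_xrqa2_model()
  # below the curve's turning point near 1/b the relative uncertainty falls
  # monotonically; approaching saturation it slowly rises again
  cur <- uncertainty_curve(m, seq(0.2, 3, length.out = 60), 3e-4)
  expect_true(all(diff(cur$relative_pct) < 1e-9))
  full <- uncertainty_curve(m, seq(0.2, 10, length.out = 60), 3e-4)
  expect_lt(max(full$relative_pct[full$dose > 1]),
            min(full$relative_pct[full$dose < 0.5]))
  expect_error(uncertainty_curve(m, numeric(0), 3e-4), "empty")
  # threshold statistic: bound must hold from the threshold upward
  thr <- uncertainty_threshold(cur, 2)
  expect_true(all(cur$relative_pct[cur$dose >= thr] <= 2))
  expect_true(is.na(uncertainty_threshold(cur, 1e-6)))
})

test_that("constrained and general forms compare as expected on zero-intercept data", {
  pts <- std_xrqa2_points()
  grid <- exp(seq(log(0.1), log(10), length.out = 200))
  rep <- compare_models(pts, grid, 3e-4)
  # the zero-intercept form is at least as precise everywhere below 1 cGy
  low <- grid < 1
  expect_true(all(rep$curve_constrained$relative_pct[low] <=
                  rep$curve_general$relative_pct[low] + 1e-9))
  # b and c barely move between forms
  expect_true(rep$bc_consistent)
  # threshold pair: 2% above a quarter cGy, 3% well below 3 cGy
  expect_lte(rep$thresholds_cgy[["constrained"]], 0.25)
  expect_lte(rep$thresholds_cgy[["general"]], 3)
})

test_that("a general model whose intercept variance vanishes reduces to the constrained one", {
  mc <- std_xrqa2_model()
  free <- c("a", "b", "c")
  covg <- matrix(0, 3, 3, dimnames = list(free, free))
  covg[2:3, 2:3] <- mc$covariance
  mg <- calibration_model("general", a = 0, b = mc$b, c = mc$c,
                          covariance = covg,
                          valid_dose_range = mc$valid_dose_range)
  grid <- c(0.2, 0.5, 1, 3, 8)
  cc <- uncertainty_curve(mc, grid, 3e-4)
  cg <- uncertainty_curve(mg, grid, 3e-4)
  expect_equal(cg$sigma_dose, cc$sigma_dose, tolerance = 1e-12)

  # nested-model dominance below the calibration midpoint on the same data
  pts <- std_xrqa2_points()
  rep <- compare_models(pts, seq(0.2, 5, by = 0.2), 3e-4)
  expect_true(all(rep$curve_constrained$from_parameters <=
                  rep$curve_general$from_parameters + 1e-12))
})
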