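test_that("noiseless fits recover the generating parameters", {
  truth <- calibration_model("constrained", b = 0.2, c = 0.1)
  pts <- generate_calibration_set(seq(0, 10, length.out = 10), truth, 0)
  m <- fit_calibration(pts, "constrained")
  expect_equal(m$b, 0.2, tolerance = 1e-6)
  expect_equal(m$c, 0.1, tolerance = 1e-6)

  # the general fit on zero-intercept data agrees and returns a ~ 0
  g <- fit_calibration(pts, "general")
  expect_equal(g$a, 0, tolerance = 1e-8)
  expect_equal(g$b, m$b, tolerance = 1e-5)
  expect_equal(g$c, m$c, tolerance = 1e-5)
})

test_that("the general fit's intercept is poorly determined on zero-intercept data", {
  g <- fit_calibration(std_xrqa2_points(), "general")
  rel <- g$fit$rel_unc_pct
  expect_gt(rel[["a"]], rel[["b"]])
  expect_gt(rel[["a"]], rel[["c"]])
  expect_gt(rel[["a"]], 40)  # far worse than the percent-level b and c
  expect_lt(rel[["b"]], 5)
  expect_lt(rel[["c"]], 5)
})

test_that("degenerate designs and non-monotone fits are rejected", {
  flat <- data.frame(dose = rep(2, 6), response = rep(0.1, 6))
  expect_error(fit_calibration(flat, "constrained"), "degenerate")
  expect_error(fit_calibration(data.frame(dose = c(0, 1), response = c(0, 0.1)),
                               "general"), "at least 4")
  bad_sigma <- data.frame(dose = 0:4, response = 0.1 * (0:4),
                          sigma_y = c(0, rep(1e-3, 4)))
  expect_error(fit_calibration(bad_sigma, "constrained"), "sigma_y")
})

test_that("forward evaluation matches the rational form and its limits", {
  m <- calibration_model("constrained", b = 0.2, c = 0.1,
                         valid_dose_range = c(0, 10))
  expect_equal(predict_response(m, 0), 0)
  expect_equal(predict_response(m, 1), 0.1 / 1.2)
  # b -> 0 limit is linear
  lin <- calibration_model("constrained", b = 1e-12, c = 0.1)
  expect_equal(predict_response(lin, 7), 0.7, tolerance = 1e-9)
  expect_warning(predict_response(m, 12), "outside")
})

test_that("closed-form inversion is the exact algebraic inverse", {
  m <- calibration_model("constrained", b = 0.2, c = 0.1)
  g <- calibration_model("general", a = 0.003, b = 0.15, c = 0.09)
  set.seed(5)
  x <- runif(100, 0, 10)
  expect_lt(max(abs(invert_dose(m, predict_response(m, x)) - x)), 1e-10)
  expect_lt(max(abs(invert_dose(g, predict_response(g, x)) - x)), 1e-10)
  expect_equal(invert_dose(m, 0.1 / 1.2), 1)
  expect_error(invert_dose(m, 0.1 / 0.2), "saturation")
})

test_that("rescaling all response sigmas leaves parameters and scales covariance", {
  pts <- std_xrqa2_points()
  m1 <- fit_calibration(pts, "constrained")
  pts2 <- pts; pts2$sigma_y <- 3 * pts$sigma_y
  m2 <- fit_calibration(pts2, "constrained")
  expect_equal(m2$b, m1$b, tolerance = 1e-9)
  expect_equal(m2$c, m1$c, tolerance = 1e-9)
  expect_equal(m2$covariance, 9 * m1$covariance, tolerance = 1e-6)
})

test_that("parameter recovery holds across seeded noisy datasets", {
  truth <- xrqa2_truth_model()
  doses <- default_calibration_doses("XRQA2")[-1]  # drop exact zero
  errs <- vapply(1:50, function(s) {
    sy <- 0.01 * predict_response(truth, doses)
    pts <- generate_calibration_set(doses, truth, sy, seed = 1000 + s)
    m <- fit_calibration(pts, "constrained")
    c(abs(m$b - truth$b) / truth$b, abs(m$c - truth$c) / truth$c)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("calibration JSON round-trips bit-exactly and validates on load", {
  m <- std_xrqa2_model()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_calibration(m, p1)
  back <- load_calibration(p1)
  expect_identical(back$b, m$b)
  expect_identical(back$c, m$c)
  expect_identical(unname(back$covariance), unname(m$covariance))
  save_calibration(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  # schema and invariant violations are refused
  obj <- jsonlite::fromJSON(p1)
  obj$covariance <- NULL
  jsonlite::write_json(obj, p2, auto_unbox = TRUE, digits = NA)
  expect_error(load_calibration(p2), "missing fields")
  obj <- jsonlite::fromJSON(p1)
  obj$a <- 0.01
  jsonlite::write_json(obj, p2, auto_unbox = TRUE, digits = NA)
  expect_error(load_calibration(p2), "a = 0")
  obj <- jsonlite::fromJSON(p1)
  obj$schema <- "something-else"
  jsonlite::write_json(obj, p2, auto_unbox = TRUE, digits = NA)
  expect_error(load_calibration(p2), "schema")
})
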