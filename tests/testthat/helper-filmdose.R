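# shared fixtures: seeded synthetic calibration data and hand-built
# scan / ROI objects used across the unit tests

std_xrqa2_points <- function(seed = 42, sigma_y = 3e-4) {
  generate_calibration_set(default_calibration_doses("XRQA2"),
                           xrqa2_truth_model(), sigma_y, seed = seed)
}

std_xrqa2_model <- function(seed = 42) {
  fit_calibration(std_xrqa2_points(seed), "constrained")
}

std_ebt3_points <- function(seed = 42, sigma_y = 3e-4) {
  generate_calibration_set(default_calibration_doses("EBT3"),
                           ebt3_truth_model(), sigma_y, seed = seed)
}

std_ebt3_model <- function(seed = 42) {
  fit_calibration(std_ebt3_points(seed), "constrained",
                  response_kind = "net_delta_OD",
                  dose_quantity = "dose_to_water")
}

constant_scan <- function(pv, n = 50, film_model = "XRQA2",
                          timepoint = "before", lot = "lotA", res = 0.2) {
  film_scan(array(pv, dim = c(n, n, 3)), res, film_model, timepoint, lot)
}

# ROI sample built directly from summary statistics (oracle-side helper)
roi_stats <- function(mean_pv, sd_pv, n_px, film_model = "XRQA2",
                      timepoint = "before", lot = "lotA", channel = "red") {
  structure(list(center_mm = c(0, 0), side_mm = 1, mean_pv = mean_pv,
                 sd_pv = sd_pv, n_px = n_px, channel = channel,
                 film_model = film_model, timepoint = timepoint,
                 lot_id = lot),
            class = "roi_sample")
}

# sample calibration-parameter draws from a model's covariance (Cholesky)
draw_params <- function(model, n) {
  p <- if (model$form == "constrained") c(model$b, model$c)
       else c(model$a, model$b, model$c)
  L <- chol(model$covariance + diag(1e-30, nrow(model$covariance)))
  z <- matrix(stats::rnorm(n * length(p)), n)
  sweep(z %*% L, 2, p, "+")
}
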