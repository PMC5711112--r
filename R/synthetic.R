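# forward-model generator: synthetic calibration sets, before/after scan
# pairs, and humanoid-phantom dose fixtures.  Ground truth is always stored
# alongside generated data so round-trip tests never compare a pipeline
# against itself.

#' Scanner noise model
#'
#' Per-pixel Gaussian pixel-value noise applied independently to the before
#' and after scans, around an unexposed baseline `pv0`.  The defaults
#' (`pv0 = 52000`, `sigma_pv = 130`) put the 25-pixel ROI-mean netDeltaR
#' noise near 3.7e-4, the level consistent with sub-2% film dosimetry above
#' a quarter of a cGy; they are a model assumption, not a measured scanner
#' property.
#'
#' @param pv0 baseline unexposed pixel value (0--65535).
#' @param sigma_pv per-pixel noise SD in pixel values.
#' @return object of class `scanner_noise_model`.
#' @export
scanner_noise_model <- function(pv0 = 52000, sigma_pv = 130) {
  stopifnot(pv0 >= 0, pv0 <= 65535, sigma_pv >= 0)
  structure(list(pv0 = pv0, sigma_pv = sigma_pv),
            class = "scanner_noise_model")
}

#' Reference synthetic truth calibrations
#'
#' `xrqa2_truth_model()`: constrained rational model for XRQA2-like
#' reflectance response versus air kerma in air, with `b = 0.2`,
#' `c = 0.105` so the response saturates towards `c/b = 0.525`, reaches
#' 0.35 at 10 cGy and is near-linear below 1 cGy.
#' `ebt3_truth_model()`: constrained model for EBT3 net optical density
#' versus dose to water up to 100 cGy (`b = 0.006`, `c = 0.004`; netDeltaOD
#' 0.25 at 100 cGy).
#'
#' @return a [calibration_model] with zero parameter covariance.
#' @export
xrqa2_truth_model <- function() {
  calibration_model("constrained", b = 0.2, c = 0.105,
                    response_kind = "net_delta_R",
                    dose_quantity = "air_kerma_in_air",
                    valid_dose_range = c(0, 10))
}

#' @rdname xrqa2_truth_model
#' @export
ebt3_truth_model <- function() {
  calibration_model("constrained", b = 0.006, c = 0.004,
                    response_kind = "net_delta_OD",
                    dose_quantity = "dose_to_water",
                    valid_dose_range = c(0, 100))
}

#' Default calibration dose ladders
#'
#' Ten dose levels spanning the calibrated range of each film model:
#' 0--10 cGy air kerma for XRQA2, 0--100 cGy dose to water for EBT3, with
#' points concentrated at low dose where imaging doses live.
#'
#' @param film_model `"XRQA2"` or `"EBT3"`.
#' @return numeric dose vector in cGy.
#' @export
default_calibration_doses <- function(film_model = c("XRQA2", "EBT3")) {
  switch(match.arg(film_model),
         XRQA2 = c(0, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 10),
         EBT3 = c(0, 1, 2, 5, 10, 20, 40, 60, 80, 100))
}

#' Generate a synthetic calibration dataset
#'
#' `y_i = truth(x_i) + N(0, sigma_y_i)`, reproducible under `seed`.
#'
#' @param doses nonnegative dose levels in cGy.
#' @param truth a [calibration_model] used as ground truth.
#' @param sigma_y per-point response noise SD, length 1 or `length(doses)`.
#' @param n_films replicate films per dose level.
#' @param seed integer RNG seed (NULL leaves the RNG stream alone).
#' @return data.frame with `dose`, `response`, `sigma_y` and the truth
#'   model in `attr(, "truth")`.
#' @export
generate_calibration_set <- function(doses, truth, sigma_y, n_films = 1,
                                     seed = NULL) {
  stopifnot(all(doses >= 0), inherits(truth, "calibration_model"),
            all(sigma_y >= 0), n_films >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- rep(doses, each = n_films)
  sy <- rep(rep_len(sigma_y, length(doses)), each = n_films)
  y_true <- suppressWarnings(predict_response(truth, x))
  out <- data.frame(dose = x,
                    response = y_true + stats::rnorm(length(x), 0, sy),
                    sigma_y = sy)
  attr(out, "truth") <- truth
  out
}

#' Generate a paired before/after film scan from a dose map
#'
#' Forward model of the measurement chain.  Before scan:
#' `PV = pv0 + noise`.  After scan, clean signal per film model:
#' XRQA2 (reflective): `pv0 - 65536 * truth(dose)`;
#' EBT3 (transmissive): `pv0 * 10^(-truth(dose))`; plus independent pixel
#' noise on each scan.  Pixel values are clipped to `[0, 65535]` and the
#' clipped fraction is recorded on the result.
#'
#' @param dose_map numeric matrix of doses in cGy at scan resolution, in
#'   the truth model's dose quantity (air kerma for XRQA2, dose to water
#'   for EBT3).
#' @param truth ground-truth [calibration_model] matching the film model's
#'   response kind.
#' @param noise a [scanner_noise_model].
#' @param film_model `"XRQA2"` or `"EBT3"`.
#' @param resolution_mm_per_px scan resolution (default 0.2).
#' @param lot_id film lot tag.
#' @param seed integer RNG seed (NULL leaves the RNG stream alone).
#' @return list with `before` and `after` [film_scan]s, `truth_map` (the
#'   dose map), and `clip_fraction`.
#' @export
generate_scan_pair <- function(dose_map, truth, noise, film_model,
                               resolution_mm_per_px = 0.2,
                               lot_id = "synthetic-lot", seed = NULL) {
  film_model <- match.arg(film_model, .film_models)
  stopifnot(inherits(truth, "calibration_model"),
            inherits(noise, "scanner_noise_model"),
            is.matrix(dose_map), all(dose_map >= 0))
  kind <- if (film_model == "XRQA2") "net_delta_R" else "net_delta_OD"
  if (truth$response_kind != kind)
    stop("truth model response kind (", truth$response_kind,
         ") does not match film model ", film_model, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- suppressWarnings(predict_response(truth, dose_map))
  after_clean <- if (film_model == "XRQA2") {
    if (max(y) > noise$pv0 / 65536)
      stop("programmed response exceeds the unexposed baseline; film ",
           "saturated", call. = FALSE)
    noise$pv0 - 65536 * y
  } else {
    noise$pv0 * 10^(-y)
  }
  d <- dim(dose_map)
  make_planes <- function(clean) {
    arr <- array(0, dim = c(d[1], d[2], 3))
    for (k in 1:3) {  # signal lives on red; green/blue kept for diagnostics
      base <- if (k == 1) clean else matrix(noise$pv0, d[1], d[2])
      arr[, , k] <- base + matrix(stats::rnorm(prod(d), 0, noise$sigma_pv),
                                  d[1], d[2])
    }
    arr
  }
  b_arr <- make_planes(matrix(noise$pv0, d[1], d[2]))
  a_arr <- make_planes(after_clean)
  n_clip <- sum(b_arr < 0 | b_arr > 65535) + sum(a_arr < 0 | a_arr > 65535)
  clip <- function(a) pmin(pmax(a, 0), 65535)
  list(before = film_scan(clip(b_arr), resolution_mm_per_px, film_model,
                          "before", lot_id),
       after = film_scan(clip(a_arr), resolution_mm_per_px, film_model,
                         "after", lot_id),
       truth_map = dose_map,
       clip_fraction = n_clip / (2 * prod(d) * 3))
}

# ---- phantom dose fixtures ------------------------------------------------

# per-acquisition surface doses to water (cGy) at the four aspects, and the
# per-acquisition site maximum, for each machine/site combination of the
# reference measurement campaign.
.fixture_surface <- list(
  OBI_21eX = list(
    head = c(Ant = 0.05, Post = 0.50, Left = 0.38, Right = 0.44),
    thorax = c(Ant = 0.75, Post = 0.64, Left = 0.58, Right = 0.65),
    pelvis = c(Ant = 3.72, Post = 3.48, Left = 2.74, Right = 2.58)),
  OBI_TrueBeam = list(
    head = c(Ant = 0.09, Post = 0.27, Left = 0.32, Right = 0.31),
    thorax = c(Ant = 0.65, Post = 0.48, Left = 0.47, Right = 0.51),
    pelvis = c(Ant = 3.10, Post = 2.02, Left = 1.89, Right = 2.02)),
  CyberKnife = list(
    head = c(Ant = 4.33, Post = 0.50, Left = 2.27, Right = 2.09),
    thorax = c(Ant = 3.86, Post = 0.45, Left = 1.75, Right = 1.74),
    pelvis = c(Ant = 6.50, Post = 0.30, Left = 3.30, Right = 3.25)),
  TomoTherapy = list(
    head = c(Ant = 2.07, Post = 2.92, Left = 2.22, Right = 2.31),
    thorax = c(Ant = 1.05, Post = 1.70, Left = 0.97, Right = 0.89),
    pelvis = c(Ant = 0.98, Post = 1.49, Left = 0.79, Right = 0.71)))

# standard errors of the triplicate surface means (cGy), same layout
.fixture_surface_se <- list(
  OBI_21eX = list(
    head = c(Ant = 0.01, Post = 0.01, Left = 0.01, Right = 0.01),
    thorax = c(Ant = 0.01, Post = 0.01, Left = 0.01, Right = 0.01),
    pelvis = c(Ant = 0.06, Post = 0.05, Left = 0.04, Right = 0.04)),
  OBI_TrueBeam = list(
    head = c(Ant = 0.01, Post = 0.01, Left = 0.01, Right = 0.01),
    thorax = c(Ant = 0.01, Post = 0.01, Left = 0.01, Right = 0.01),
    pelvis = c(Ant = 0.05, Post = 0.03, Left = 0.03, Right = 0.03)),
  CyberKnife = list(
    head = c(Ant = 0.07, Post = 0.01, Left = 0.04, Right = 0.04),
    thorax = c(Ant = 0.06, Post = 0.01, Left = 0.03, Right = 0.03),
    pelvis = c(Ant = 0.10, Post = 0.01, Left = 0.05, Right = 0.05)),
  TomoTherapy = list(
    head = c(Ant = 0.03, Post = 0.05, Left = 0.04, Right = 0.04),
    thorax = c(Ant = 0.02, Post = 0.03, Left = 0.02, Right = 0.02),
    pelvis = c(Ant = 0.02, Post = 0.03, Left = 0.02, Right = 0.02)))

.fixture_max <- list(
  OBI_21eX = c(head = 0.50, thorax = 1.01, pelvis = 4.91),
  OBI_TrueBeam = c(head = 0.38, thorax = 0.84, pelvis = 3.15),
  CyberKnife = c(head = 4.33, thorax = 3.86, pelvis = 6.50),
  TomoTherapy = c(head = 3.84, thorax = 1.90, pelvis = 2.09))

# strip spans (mm): anterior-posterior (vertical) and left-right (lateral)
.fixture_span <- list(head = c(vertical = 200, lateral = 160),
                      thorax = c(vertical = 220, lateral = 300),
                      pelvis = c(vertical = 240, lateral = 340))

#' Phantom dose-distribution fixture
#'
#' Programs a machine/site dose fixture whose surface endpoints equal the
#' reference surface-dose means and whose profile peak equals the site
#' maximum for that machine, with the qualitative shape rules of the
#' acquisition geometries: vertical profiles are anterior-loaded for the
#' CyberKnife (ceiling-mounted sources), posterior-loaded for OBI head
#' scans (tube rotating behind the head), and peak between the surfaces
#' otherwise; lateral profiles carry a programmable isocenter offset for
#' the rotational systems (treatment positioning shifts the patient
#' midplane off isocenter) and are symmetric for the CyberKnife.  Interior
#' profile values between the programmed endpoints are fixture-defined
#' (piecewise-parabolic), not measured data.
#'
#' @param machine one of `"OBI_21eX"`, `"OBI_TrueBeam"`, `"CyberKnife"`,
#'   `"TomoTherapy"`.
#' @param site `"head"`, `"thorax"` or `"pelvis"`.
#' @param lateral_offset_mm isocenter offset of the lateral peak for
#'   rotational systems (default 8 mm).
#' @return object of class `dose_map_fixture` with `surface_values` and
#'   `surface_se` (cGy per acquisition), `film_model`, per-axis profile
#'   shape parameters, and the programmed `peak_cgy` ground truth.
#' @export
make_phantom_fixture <- function(machine, site, lateral_offset_mm = 8) {
  if (!machine %in% names(.fixture_surface))
    stop("unknown machine: ", machine, call. = FALSE)
  if (!site %in% names(.fixture_surface[[machine]]))
    stop("unknown site: ", site, call. = FALSE)
  sv <- .fixture_surface[[machine]][[site]]
  peak <- unname(.fixture_max[[machine]][site])
  span <- .fixture_span[[site]]
  Lv <- span[["vertical"]]; Ll <- span[["lateral"]]
  # vertical peak position (positive = anterior)
  p0v <- if (machine == "CyberKnife") Lv / 2
         else if (machine %in% c("OBI_21eX", "OBI_TrueBeam") && site == "head")
           -Lv * 0.25
         else 0
  if (machine == "OBI_21eX" && site == "head") p0v <- -Lv / 2
  p0l <- if (machine == "CyberKnife") 0 else lateral_offset_mm
  lat_peak <- if (machine == "CyberKnife")
    1.15 * max(sv[c("Left", "Right")]) else peak
  structure(list(
    machine = machine, site = site,
    film_model = if (machine == "TomoTherapy") "EBT3" else "XRQA2",
    surface_values = sv,
    surface_se = .fixture_surface_se[[machine]][[site]],
    peak_cgy = peak,
    profiles = list(
      vertical = list(span_mm = Lv, peak_cgy = peak, peak_pos_mm = p0v,
                      end_lo = unname(sv["Post"]), end_hi = unname(sv["Ant"])),
      lateral = list(span_mm = Ll, peak_cgy = lat_peak, peak_pos_mm = p0l,
                     end_lo = unname(sv["Right"]), end_hi = unname(sv["Left"])))),
    class = "dose_map_fixture")
}

#' @export
print.dose_map_fixture <- function(x, ...) {
  cat(sprintf("dose_map_fixture: %s / %s (%s film)\n", x$machine, x$site,
              x$film_model))
  cat("  surface (cGy/acq): ",
      paste(names(x$surface_values), sprintf("%.2f", x$surface_values),
            collapse = "  "), "\n")
  cat(sprintf("  programmed peak: %.2f cGy/acq\n", x$peak_cgy))
  invisible(x)
}

#' Ground-truth fixture dose along a profile axis
#'
#' Piecewise-parabolic shape: the dose equals the programmed surface value
#' at each strip end and the programmed peak at the peak position, varying
#' monotonically on each side of the peak.
#'
#' @param fixture a [make_phantom_fixture()] result.
#' @param axis `"vertical"` (negative = posterior) or `"lateral"`
#'   (negative = right).
#' @param position_mm positions along the axis, isocenter origin.
#' @return per-acquisition dose to water in cGy at each position.
#' @export
fixture_profile_dose <- function(fixture, axis = c("vertical", "lateral"),
                                 position_mm) {
  axis <- match.arg(axis)
  pr <- fixture$profiles[[axis]]
  L2 <- pr$span_mm / 2
  stopifnot(all(position_mm >= -L2 - 1e-9), all(position_mm <= L2 + 1e-9))
  p0 <- pr$peak_pos_mm
  lo_side <- position_mm < p0
  d <- numeric(length(position_mm))
  if (p0 > -L2) {
    t <- (position_mm[lo_side] - p0) / (-L2 - p0)
    d[lo_side] <- pr$peak_cgy - (pr$peak_cgy - pr$end_lo) * t^2
  }
  if (p0 < L2) {
    t <- (position_mm[!lo_side] - p0) / (L2 - p0)
    d[!lo_side] <- pr$peak_cgy - (pr$peak_cgy - pr$end_hi) * t^2
  } else {
    d[!lo_side] <- pr$peak_cgy
  }
  d
}
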