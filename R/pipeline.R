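# measurement pipeline: scan pair -> ROI -> response -> dose with budget,
# plus fixture drivers that run the full chain on synthetic scans.

#' Measure dose from one before/after scan pair at one ROI
#'
#' Runs the measurement chain: ROI statistics on both scans, film response
#' (netDeltaR or netDeltaOD), closed-form dose inversion with a one-sigma
#' budget, air-kerma to dose-to-water conversion for kV beams, and scaling
#' to the per-acquisition dose.
#'
#' @param before,after [film_scan]s of the same piece.
#' @param calibration fitted [calibration_model] for the film model.
#' @param center_mm ROI centre, mm.
#' @param side_mm ROI side, mm (default 1).
#' @param quality a [beam_quality]; required for kV (XRQA2) measurements,
#'   ignored for MV.
#' @param n_acquisitions acquisitions accumulated on the film (default 1).
#' @param label,aspect,site,machine metadata for the dose point.
#' @return one-row dose-point data.frame with `dose_cgy` (per acquisition,
#'   dose to water), `sigma_cgy` from the delta-method budget, and
#'   `response`/`response_sigma` diagnostics.
#' @export
measure_dose <- function(before, after, calibration, center_mm, side_mm = 1,
                         quality = NULL, n_acquisitions = 1, label = "",
                         aspect = NA_character_, site = NA_character_,
                         machine = NA_character_) {
  stopifnot(inherits(calibration, "calibration_model"))
  rb <- sample_roi(before, "red", center_mm, side_mm)
  ra <- sample_roi(after, "red", center_mm, side_mm)
  resp <- film_response(rb, ra, before$film_model, label)
  if (resp$response_kind != calibration$response_kind)
    stop("calibration response kind does not match the film model",
         call. = FALSE)
  budget <- dose_uncertainty(calibration, resp$value, resp$sigma_y)
  dose <- budget$dose
  sigma <- budget$sigma_dose
  if (calibration$dose_quantity == "air_kerma_in_air") {
    if (is.null(quality))
      stop("kV measurement needs a beam_quality for the kerma-to-dose ",
           "conversion", call. = FALSE)
    # linear conversion; applied directly so zero-dose pieces whose noisy
    # kerma estimate is slightly negative keep their sign
    r <- kerma_ratio(quality$hvl_mm_al)
    dose <- dose * r
    sigma <- sigma * r
  }
  pt <- dose_point(dose / n_acquisitions, sigma / n_acquisitions,
                   aspect = aspect, site = site, machine = machine,
                   label = label)
  pt$response <- resp$value
  pt$response_sigma <- resp$sigma_y
  pt
}

# truth model matching a fixture's film model
.fixture_truth <- function(fixture) {
  if (fixture$film_model == "EBT3") ebt3_truth_model() else xrqa2_truth_model()
}

# convert a dose-to-water map into the generator's dose quantity
.to_generator_quantity <- function(dose_w, fixture, quality) {
  if (fixture$film_model == "EBT3") dose_w
  else dose_w / kerma_ratio(quality$hvl_mm_al)
}

#' Simulate and measure a fixture surface dose
#'
#' Full round trip for one surface film piece: the fixture's programmed
#' surface dose (optionally jittered for repeat-to-repeat variation) is
#' accumulated over the protocol's acquisitions, forward-modelled into a
#' synthetic before/after scan pair, and measured back through the complete
#' pipeline with the supplied calibration.
#'
#' @param fixture a [make_phantom_fixture()] result.
#' @param aspect `"Ant"`, `"Post"`, `"Left"` or `"Right"`.
#' @param calibration fitted [calibration_model] used for inversion (the
#'   measurement side; the generation side always uses the fixture's truth
#'   model).
#' @param noise a [scanner_noise_model].
#' @param seed RNG seed.
#' @param repeat_cv coefficient of variation of repeat-to-repeat dose
#'   jitter (0 = none; the reference campaign's triplicate scatter
#'   corresponds to about 0.035).
#' @param piece_mm edge length of the simulated film piece (default 8 mm).
#' @param resolution_mm_per_px scan resolution (default 0.2).
#' @return one-row dose-point data.frame (per-acquisition dose to water)
#'   with the programmed truth in `truth_cgy`.
#' @export
measure_fixture_surface <- function(fixture, aspect,
                                    calibration,
                                    noise = scanner_noise_model(),
                                    seed = NULL, repeat_cv = 0,
                                    piece_mm = 8,
                                    resolution_mm_per_px = 0.2) {
  stopifnot(inherits(fixture, "dose_map_fixture"))
  aspect <- match.arg(aspect, .aspects)
  protocol <- get_protocol(fixture$machine, fixture$site)
  quality <- protocol_beam_quality(protocol)
  if (!is.null(seed)) set.seed(seed)
  truth_dose <- unname(fixture$surface_values[aspect])
  if (repeat_cv > 0)
    truth_dose <- truth_dose * (1 + stats::rnorm(1, 0, repeat_cv))
  n <- protocol$n_acquisitions_measured
  accumulated <- truth_dose * n
  npx <- max(round(piece_mm / resolution_mm_per_px), 7)
  map <- matrix(.to_generator_quantity(accumulated, fixture, quality),
                npx, npx)
  pair <- generate_scan_pair(map, .fixture_truth(fixture), noise,
                             fixture$film_model, resolution_mm_per_px)
  centre <- rep((npx - 1) * resolution_mm_per_px / 2, 2)
  pt <- measure_dose(pair$before, pair$after, calibration, centre,
                     quality = quality, n_acquisitions = n,
                     label = paste(fixture$machine, fixture$site, aspect,
                                   sep = "/"),
                     aspect = aspect, site = fixture$site,
                     machine = fixture$machine)
  pt$truth_cgy <- unname(fixture$surface_values[aspect])
  pt
}

#' Simulate and measure a fixture dose profile
#'
#' Generates a synthetic film strip exposed to the fixture's programmed
#' profile (accumulated over the protocol's acquisitions), then measures it
#' back: ROI sampling at regular positions along the strip, response,
#' inversion, conversion, and per-acquisition scaling.
#'
#' @inheritParams measure_fixture_surface
#' @param axis `"vertical"` or `"lateral"`.
#' @param spacing_mm ROI spacing along the strip (default 2 mm).
#' @param width_mm strip width (default 10 mm).
#' @return a [build_profile()] result; the programmed truth per position is
#'   in column `truth_cgy` of `$points`.
#' @export
measure_fixture_profile <- function(fixture, axis = c("vertical", "lateral"),
                                    calibration,
                                    noise = scanner_noise_model(),
                                    seed = NULL, spacing_mm = 2,
                                    width_mm = 10,
                                    resolution_mm_per_px = 0.2) {
  stopifnot(inherits(fixture, "dose_map_fixture"))
  axis <- match.arg(axis)
  protocol <- get_protocol(fixture$machine, fixture$site)
  quality <- protocol_beam_quality(protocol)
  n <- protocol$n_acquisitions_measured
  pr <- fixture$profiles[[axis]]
  L2 <- pr$span_mm / 2
  if (!is.null(seed)) set.seed(seed)

  ncol_px <- round(pr$span_mm / resolution_mm_per_px) + 1
  nrow_px <- round(width_mm / resolution_mm_per_px)
  x_mm <- (seq_len(ncol_px) - 1) * resolution_mm_per_px
  pos_of_px <- x_mm - L2
  dose_w <- fixture_profile_dose(fixture, axis, pos_of_px) * n
  map <- matrix(rep(.to_generator_quantity(dose_w, fixture, quality),
                    each = nrow_px), nrow_px, ncol_px)
  pair <- generate_scan_pair(map, .fixture_truth(fixture), noise,
                             fixture$film_model, resolution_mm_per_px)

  margin <- 2  # keep ROIs fully inside the strip and the grid on the
               # peak-offset lattice
  positions <- seq(-L2 + margin, L2 - margin, by = spacing_mm)
  y_centre <- (nrow_px - 1) * resolution_mm_per_px / 2
  pts <- do.call(rbind, lapply(positions, function(p) {
    pt <- measure_dose(pair$before, pair$after, calibration,
                       c(p + L2, y_centre), quality = quality,
                       n_acquisitions = n,
                       label = paste(fixture$machine, fixture$site, axis,
                                     sep = "/"),
                       site = fixture$site, machine = fixture$machine)
    pt$position_mm <- p
    pt$truth_cgy <- fixture_profile_dose(fixture, axis, p)
    pt
  }))
  build_profile(pts, if (axis == "lateral") "lateral" else "vertical",
                site = fixture$site)
}

#' Simulate, measure and aggregate triplicate surface repeats
#'
#' Runs [measure_fixture_surface()] once per seed with repeat-to-repeat
#' dose jitter and aggregates the repeats to mean and standard error.
#'
#' @inheritParams measure_fixture_surface
#' @param seeds one RNG seed per repeat (default `1:3`).
#' @param repeat_cv repeat-to-repeat coefficient of variation
#'   (default 0.035, reproducing the reference campaign's standard errors
#'   of about 2% of the mean).
#' @return aggregated dose-point row (see [aggregate_repeats()]).
#' @export
measure_fixture_repeats <- function(fixture, aspect, calibration,
                                    noise = scanner_noise_model(),
                                    seeds = 1:3, repeat_cv = 0.035, ...) {
  reps <- do.call(rbind, lapply(seeds, function(s)
    measure_fixture_surface(fixture, aspect, calibration, noise = noise,
                            seed = s, repeat_cv = repeat_cv, ...)))
  aggregate_repeats(reps)
}
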