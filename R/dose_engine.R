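# beam qualities, protocol registry, air-kerma to dose-to-water conversion,
# per-scan scaling and triplicate aggregation.

#' Construct a beam quality
#'
#' kV qualities are specified by tube potential and first HVL in mm Al and
#' use the in-air mass-energy-absorption conversion; MV qualities (MVCT)
#' skip that path because EBT3 is calibrated directly in dose to water.
#'
#' @param modality `"kV"` or `"MV"`.
#' @param kvp tube potential in kV (kV only, 40--150).
#' @param hvl_mm_al first HVL in mm Al (kV only, > 0).
#' @param label free-text label (machine + site).
#' @return object of class `beam_quality`.
#' @export
beam_quality <- function(modality = c("kV", "MV"), kvp = NA_real_,
                         hvl_mm_al = NA_real_, label = "") {
  modality <- match.arg(modality)
  if (modality == "kV") {
    if (!is.finite(kvp) || kvp < 40 || kvp > 150)
      stop("kV quality requires kvp in [40, 150]", call. = FALSE)
    if (!is.finite(hvl_mm_al) || hvl_mm_al <= 0)
      stop("kV quality requires hvl_mm_al > 0", call. = FALSE)
  }
  structure(list(modality = modality, kvp = kvp, hvl_mm_al = hvl_mm_al,
                 label = label), class = "beam_quality")
}

#' Convert air kerma in air to dose to water
#'
#' Multiplies the film-measured air kerma by the water-to-air
#' mass-energy-absorption-coefficient ratio at the beam's effective energy
#' (in-air method): `D_w = K_air * (mu_en/rho)_w/air`.  Only the kV path is
#' supported; MVCT doses are measured with EBT3 film calibrated directly in
#' dose to water, so no conversion applies there.
#'
#' @param kerma_cgy air kerma in air, cGy (vectorised, nonnegative).
#' @param quality a [beam_quality] with `modality = "kV"`.
#' @return dose to water in cGy.
#' @export
air_kerma_to_dose_water <- function(kerma_cgy, quality) {
  stopifnot(inherits(quality, "beam_quality"))
  if (quality$modality != "kV")
    stop("air-kerma conversion applies to kV qualities only; EBT3/MV doses ",
         "are already dose to water", call. = FALSE)
  if (any(kerma_cgy < 0)) stop("kerma must be nonnegative", call. = FALSE)
  kerma_cgy * kerma_ratio(quality$hvl_mm_al)
}

#' Packaged IGRT imaging protocol registry
#'
#' The clinical acquisition settings for the four imaging systems and three
#' anatomical sites: machine, site, technique, beam quality (kVp and HVL in
#' mm Al for kV systems, 3.5 MV flag for MVCT), tube loading, the number of
#' acquisitions accumulated per measurement, and the per-acquisition
#' reporting unit.
#'
#' @return data.frame with 12 rows.
#' @export
imaging_protocols <- function() {
  data.frame(
    machine = rep(c("OBI_21eX", "OBI_TrueBeam", "CyberKnife", "TomoTherapy"),
                  each = 3),
    site = rep(c("head", "thorax", "pelvis"), 4),
    technique = c(
      "Standard dose, FF (200 deg)", "Low Dose Thorax, HF (360 deg)",
      "Pelvis, HF (360 deg)",
      "Standard dose, FF (200 deg)", "Thorax Slow, HF (360 deg)",
      "Pelvis, HF (360 deg)",
      "6D Skull / 100 image pairs", "C-spine / 100 image pairs",
      "L-Spine / 100 image pairs",
      "Pitch 2 (TG 148)", "Pitch 2 (TG 148)", "Pitch 2 (TG 148)"),
    modality = rep(c("kV", "kV", "kV", "MV"), each = 3),
    kvp = c(100, 110, 125, 100, 125, 125, 100, 110, 125, NA, NA, NA),
    beam_energy = c("100 kV", "110 kV", "125 kV", "100 kV", "125 kV",
                    "125 kV", "100 kV", "110 kV", "125 kV",
                    "3.5 MeV", "3.5 MeV", "3.5 MeV"),
    total_quality = c("4.9 mm Al", "5.2 mm Al", "5.8 mm Al", "6.9 mm Al",
                      "7.7 mm Al", "7.7 mm Al", "5.4 mm Al", "5.7 mm Al",
                      "6.4 mm Al", "3.5 MV", "3.5 MV", "3.5 MV"),
    hvl_mm_al = c(4.9, 5.2, 5.8, 6.9, 7.7, 7.7, 5.4, 5.7, 6.4, NA, NA, NA),
    mAs_or_MU = c(145, 262, 1049, 146, 252, 1056, 1250, 1500, 4000,
                  6.4, 6.4, 6.4),
    n_acquisitions_measured = c(5, 5, 5, 5, 5, 5, 1, 1, 1, 5, 5, 5),
    reporting_unit = c(rep("per CBCT scan", 6), rep("per 100 image pairs", 3),
                       rep("per MVCT scan", 3)),
    stringsAsFactors = FALSE)
}

#' Look up one imaging protocol
#'
#' @param machine one of `"OBI_21eX"`, `"OBI_TrueBeam"`, `"CyberKnife"`,
#'   `"TomoTherapy"`.
#' @param site `"head"`, `"thorax"` or `"pelvis"`.
#' @return single-row data.frame from [imaging_protocols()].
#' @export
get_protocol <- function(machine, site) {
  reg <- imaging_protocols()
  row <- reg[reg$machine == machine & reg$site == site, ]
  if (nrow(row) != 1)
    stop("unknown protocol: ", machine, "/", site, call. = FALSE)
  row
}

#' Beam quality of a protocol row
#'
#' @param protocol a row of [imaging_protocols()].
#' @return a [beam_quality].
#' @export
protocol_beam_quality <- function(protocol) {
  if (protocol$modality == "kV")
    beam_quality("kV", protocol$kvp, protocol$hvl_mm_al,
                 paste(protocol$machine, protocol$site))
  else
    beam_quality("MV", label = paste(protocol$machine, protocol$site))
}

#' Construct a dose point
#'
#' @param dose_cgy dose to water, cGy (>= 0 within noise).
#' @param sigma_cgy one-sigma uncertainty, cGy.
#' @param position_mm position along a profile axis (profile points), or NA.
#' @param aspect surface aspect, one of `"Ant"`, `"Post"`, `"Left"`,
#'   `"Right"` (surface points), or NA.
#' @param site anatomical site.
#' @param machine machine identifier.
#' @param label measurement label (repeats to be aggregated share it).
#' @return one-row data.frame.
#' @export
dose_point <- function(dose_cgy, sigma_cgy = 0, position_mm = NA_real_,
                       aspect = NA_character_, site = NA_character_,
                       machine = NA_character_, label = "") {
  if (sigma_cgy < 0) stop("sigma_cgy must be >= 0", call. = FALSE)
  if (!is.na(aspect))
    aspect <- match.arg(aspect, c("Ant", "Post", "Left", "Right"))
  data.frame(label = label, machine = machine, site = site, aspect = aspect,
             position_mm = position_mm, dose_cgy = dose_cgy,
             sigma_cgy = sigma_cgy, stringsAsFactors = FALSE)
}

#' Scale an accumulated measurement to the per-acquisition dose
#'
#' Measurements accumulate several identical acquisitions on one film (five
#' CBCT or MVCT scans); dose and sigma are divided by
#' `n_acquisitions_measured`.  CyberKnife measurements are already taken
#' over 100 image pairs and reported per 100 image pairs (divisor 1).
#'
#' @param point a dose-point row ([dose_point()]).
#' @param protocol a row of [imaging_protocols()].
#' @return the scaled dose-point row with a `unit` column.
#' @export
per_scan_dose <- function(point, protocol) {
  n <- protocol$n_acquisitions_measured
  stopifnot(n >= 1)
  point$dose_cgy <- point$dose_cgy / n
  point$sigma_cgy <- point$sigma_cgy / n
  point$unit <- protocol$reporting_unit
  point
}

#' Aggregate repeated measurements to mean and standard error
#'
#' All measurements are repeated (three times in the reference protocol)
#' and reported as the mean with its standard error (one sigma):
#' `SE = sd / sqrt(n)` with the sample (n - 1) standard deviation.
#'
#' @param points data.frame of dose-point rows sharing one label.
#' @return single aggregated dose-point row.
#' @export
aggregate_repeats <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) >= 2)
  if (length(unique(points$label)) != 1)
    stop("cannot aggregate repeats with mixed labels: ",
         paste(unique(points$label), collapse = ", "), call. = FALSE)
  out <- points[1, , drop = FALSE]
  out$dose_cgy <- mean(points$dose_cgy)
  out$sigma_cgy <- stats::sd(points$dose_cgy) / sqrt(nrow(points))
  out$n_repeats <- nrow(points)
  out
}
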