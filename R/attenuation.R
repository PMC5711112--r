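# Mass attenuation / mass energy-absorption data (NIST Hubbell & Seltzer
# compilations), cm^2/g, photon energies in keV.  Grid covers the kV imaging
# range; values outside [12, 150] keV are refused rather than extrapolated.
.atten_energies_kev <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150)
.al_mu_over_rho     <- c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681,
                         0.2778, 0.2018, 0.1704, 0.1378)
.water_muen_over_rho <- c(4.944, 1.374, 0.5503, 0.1557, 0.06947, 0.04223,
                          0.03190, 0.02597, 0.02546, 0.02764)
.air_muen_over_rho   <- c(4.742, 1.334, 0.5389, 0.1537, 0.06833, 0.04098,
                          0.03041, 0.02407, 0.02325, 0.02496)
.rho_al_g_cm3 <- 2.699

# log-log monotone spline interpolators (attenuation data are smooth and
# monotone over this range; monoH.FC preserves that)
.loglog_fun <- function(e, v) {
  sf <- stats::splinefun(log(e), log(v), method = "monoH.FC")
  function(energy_kev) exp(sf(log(energy_kev)))
}
.mu_al   <- .loglog_fun(.atten_energies_kev, .al_mu_over_rho)
.muen_w  <- .loglog_fun(.atten_energies_kev, .water_muen_over_rho)
.muen_a  <- .loglog_fun(.atten_energies_kev, .air_muen_over_rho)

.energy_range_kev <- c(12, 150)

#' First half-value layer in aluminum of a monoenergetic photon beam
#'
#' @param energy_kev photon energy in keV (12--150).
#' @return HVL in mm of aluminum.
#' @keywords internal
mono_hvl_mm_al <- function(energy_kev) {
  stopifnot(all(energy_kev >= .energy_range_kev[1]),
            all(energy_kev <= .energy_range_kev[2]))
  10 * log(2) / (.mu_al(energy_kev) * .rho_al_g_cm3)
}

#' Effective energy of a kV beam from its first HVL in aluminum
#'
#' The effective energy is that of the monoenergetic beam with the same
#' first half-value layer in aluminum, the standard in-air beam-quality
#' mapping for kV dosimetry.
#'
#' @param hvl_mm_al first half-value layer, mm Al.
#' @return effective energy in keV.
#' @export
#' @examples
#' hvl_effective_energy(4.9)
hvl_effective_energy <- function(hvl_mm_al) {
  lo <- mono_hvl_mm_al(.energy_range_kev[1])
  hi <- mono_hvl_mm_al(.energy_range_kev[2])
  vapply(hvl_mm_al, function(h) {
    if (!is.finite(h) || h < lo || h > hi)
      stop("HVL ", h, " mm Al outside supported range [",
           signif(lo, 3), ", ", signif(hi, 3), "] mm Al", call. = FALSE)
    stats::uniroot(function(e) mono_hvl_mm_al(e) - h,
                   .energy_range_kev, tol = 1e-10)$root
  }, numeric(1))
}

#' Water-to-air mass-energy-absorption-coefficient ratio for a kV beam
#'
#' Ratio (mu_en/rho)_water / (mu_en/rho)_air evaluated at the effective
#' energy matching the beam's first HVL in aluminum.  This is the in-air
#' conversion factor from air kerma in air to dose to water at the surface.
#'
#' @param hvl_mm_al first half-value layer, mm Al.
#' @return dimensionless ratio, about 1.02--1.04 for CBCT beam qualities.
#' @export
#' @examples
#' kerma_ratio(4.9)
kerma_ratio <- function(hvl_mm_al) {
  e <- hvl_effective_energy(hvl_mm_al)
  .muen_w(e) / .muen_a(e)
}

#' Packaged conversion-ratio table at 1 keV steps
#'
#' @return data.frame with energy (keV), HVL in mm Al, and the
#'   water-to-air mass-energy-absorption-coefficient ratio.
#' @export
kerma_ratio_table <- function() {
  e <- seq(.energy_range_kev[1], .energy_range_kev[2], by = 1)
  data.frame(energy_kev = e,
             hvl_mm_al = mono_hvl_mm_al(e),
             ratio_w_air = .muen_w(e) / .muen_a(e))
}

#' Spread of the conversion ratio across a beam-quality range
#'
#' Quantifies the error committed by converting all measurements with one
#' representative ratio (taken at the mid-range quality) instead of the
#' quality-specific ratio: the maximum relative deviation, in percent, of
#' the ratio over [hvl_lo, hvl_hi] from the mid-range value.
#'
#' @param hvl_lo,hvl_hi HVL bounds in mm Al.
#' @param n number of evaluation points across the range.
#' @return maximum relative deviation from the mid-range ratio, percent.
#' @export
#' @examples
#' kerma_ratio_spread(4.9, 7.7) # < 1 for the CBCT quality range
kerma_ratio_spread <- function(hvl_lo, hvl_hi, n = 50) {
  stopifnot(hvl_lo > 0, hvl_hi > hvl_lo)
  h <- seq(hvl_lo, hvl_hi, length.out = n)
  r <- kerma_ratio(h)
  r0 <- kerma_ratio((hvl_lo + hvl_hi) / 2)
  100 * max(abs(r - r0)) / r0
}
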