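---
title: "Radiochromic film dosimetry of image-guidance procedures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiochromic film dosimetry of image-guidance procedures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filmdose)
```

## The measurement problem

Image-guided radiotherapy (IGRT) delivers a concomitant imaging dose at
every session: kV cone-beam CT on linac-mounted on-board imagers (OBI),
stereoscopic kV radiographs on robotic radiosurgery systems, and MV
fan-beam CT (MVCT) on helical tomotherapy units. These doses are small —
tenths of a cGy to a few cGy per acquisition at the patient surface — but
they accumulate over 20–40 fractions and they land largely outside the
planned target volume. Comparing imaging systems fairly requires one
dosimeter and one analysis chain across all of them.

`filmdose` implements such a reference dosimetry chain for GAFCHROMIC
radiochromic films read on a flatbed scanner:

* **XRQA2** (reflective) film for kV beams, calibrated in *air kerma in
  air* up to 10 cGy and converted to dose to water at the surface;
* **EBT3** (transmissive) film for MV beams, calibrated directly in *dose
  to water* up to 100 cGy.

Film pieces are scanned before exposure and again 24 h after, at
0.2 mm/pixel in 48-bit RGB (16 bits per channel). All dosimetry uses the
red channel, sampled over a 1 × 1 mm region of interest (ROI) — 25 pixels
at the reference resolution. The green and blue planes are carried along
for diagnostics only.

## Film response

For a ROI with before/after mean pixel values $PV_b$ and $PV_a$:

* XRQA2 (reflective): net reflectance change
  $\mathrm{net}\Delta R = (PV_b - PV_a)/2^{16}$,
* EBT3 (transmissive): net optical density change
  $\mathrm{net}\Delta OD = \log_{10}(PV_b / PV_a)$.

The normalisation constant is $2^{16} = 65536$ rather than $65535$; the
two differ by under 0.002 % and nothing downstream depends on the choice.
ROI statistics use the population SD; the standard error of a ROI mean is
$sd/\sqrt{n}$ under an independent-pixel assumption (no spatial noise
correlation model is applied). The response noise $\sigma_y$ combines the
two ROI-mean standard errors in quadrature (first order through the log
ratio for $\Delta OD$); these first-order sigmas agree with Monte-Carlo
resampling to well under 5 % whenever the pixel noise is below a few
percent of the mean, which is always the case for real scans. An optional
additive response-sigma term is available in the uncertainty budget for
inter-film (lot) variation; its default is zero.

## Calibration: the general and zero-intercept rational forms

Dose–response data are fitted with the rational function

$$y = \frac{a + c\,x}{1 + b\,x},$$

where $x$ is dose (air kerma in air for XRQA2, dose to water for EBT3)
and $y$ the film response. Two forms are supported:

* **general** — all three parameters free;
* **constrained** — $a \equiv 0$, the physically motivated form: an
  unexposed film must show zero net response.

On zero-intercept data the general fit returns $\hat a$ close to zero but
with a very large relative uncertainty (two orders of magnitude above
those of $b$ and $c$ in the packaged synthetic conditions), and that
poorly determined intercept dominates the propagated dose uncertainty at
low dose, exactly where imaging doses live. Forcing $a = 0$ leaves $b$
and $c$ essentially unchanged (they agree within one combined sigma)
while removing that term: in the packaged study conditions the total
one-sigma dose uncertainty improves from 3 % above about 1 cGy to better
than 2 % for all doses above 0.25 cGy. `compare_models()` reproduces this
comparison on any calibration set.

Fitting details (`fit_calibration()`):

* weighted least squares with weights $1/\sigma_y^2$; an unweighted fit
  is used when no point sigmas are supplied;
* starting values from the exact linearisation
  $y = a + c x - b (x y)$ solved by ordinary least squares, refined by
  Levenberg–Marquardt (`minpack.lm`);
* parameter covariance $(J^\top W J)^{-1}$ from the analytic Jacobian at
  the optimum. For weighted fits the supplied sigmas set the absolute
  scale and no rescaling is applied; unweighted fits are scaled by the
  reduced chi-square. The distinction matters: quoted parameter
  uncertainties are otherwise software-dependent;
* fitted models must be strictly increasing over the calibrated range
  ($c - ab > 0$, no pole); violations reject the model;
* the valid dose range is the span of the fitted doses. Evaluating or
  inverting outside it warns rather than errors, because measured
  imaging doses routinely sit near the bottom of the calibrated range
  (and accumulated multi-scan exposures can sit above it).

Inversion is in closed form, $x = (y - a)/(c - b y)$, exact to machine
precision; responses at or beyond the saturation asymptote $c/b$ are
refused.

## Uncertainty budgets

`dose_uncertainty()` propagates by the delta method on the closed-form
inverse:

$$\sigma_x^2 = \left(\frac{\partial x}{\partial y}\right)^2 \sigma_y^2
  + g^\top C\, g,$$

with $g$ the gradient of the inverse with respect to the free parameters
and $C$ the full fit covariance. Off-diagonal covariance terms are
included: $b$ and $c$ are strongly correlated in rational fits and
dropping the cross terms biases $\sigma_x$ low. Response noise and
parameter uncertainty are treated as independent, since calibration films
and measurement films are distinct pieces. The two variance components
are reported separately and sum exactly to the total.

Delta-method budgets agree with $10^5$-draw Monte-Carlo sampling of both
noise and parameters to within 5 % whenever all relative input
uncertainties are below ~10 %; the test suite checks this.

One feature worth knowing: for constant response noise the *relative*
dose uncertainty of the constrained model is not monotone in dose. The
response-noise term scales as $(1+bx)^2/x$, so the curve falls steeply at
low dose, reaches its minimum near $x = 1/b$, and rises slowly again
towards saturation. The high-dose rise stays far below the low-dose
values over the calibrated range. Threshold statistics
(`uncertainty_threshold()`) are therefore defined conservatively: the
smallest grid dose above which the bound holds *for every larger grid
dose*, evaluated on a 200-point log-spaced grid.

## Air kerma to dose to water

XRQA2 measures air kerma in air; the clinical quantity is dose to water
at the surface. For kV CBCT beam qualities the in-air conversion is a
single multiplication by the water-to-air mass-energy-absorption-
coefficient ratio,

$$D_w = K_{air} \left[\left(\bar\mu_{en}/\rho\right)^{w}_{air}\right],$$

evaluated at the beam's *effective energy* — the energy of the
monoenergetic beam with the same first HVL in aluminum, the standard
in-air practice. The packaged table is built at 1 keV steps from the
standard mass-attenuation compilations (log-log monotone spline between
tabulated energies, aluminum HVL from $\ln 2 / \mu$).

Across the packaged quality range (first HVL 4.9–7.7 mm Al, 100–125 kVp)
the ratio runs from about 1.018 to 1.036. The quantity that matters in
practice is the error committed by converting *all* measurements with one
representative ratio: the maximum deviation from the mid-range value,
`kerma_ratio_spread(4.9, 7.7)`, is 0.95 % — under 1 %. The end-to-end
difference between the two extreme qualities is larger (about 1.7 %);
users measuring across the full quality span should use the
quality-specific ratio, which `measure_dose()` does automatically from
the protocol registry. MV measurements skip this path entirely: EBT3 is
calibrated in a solid-water phantom directly in dose to water, and the
energy difference between a 4 MV calibration beam and the detuned 3.5 MV
imaging beam is treated as negligible given the flat MV-range energy
response of the EBT film family.

## Measurement design

The protocol registry (`imaging_protocols()`) packages the twelve
machine/site acquisition settings (technique, kVp, first HVL, tube
loading, reporting unit). Because single-acquisition doses are small,
each film accumulates several identical acquisitions: five CBCT scans
(OBI), five MVCT scans (TomoTherapy), or 100 stereoscopic image pairs
(CyberKnife, reported per 100 pairs as delivered clinically).
`per_scan_dose()` divides dose and sigma by the accumulation count.
Every measurement is repeated three times; `aggregate_repeats()` reports
the mean with its standard error $sd/\sqrt{n}$ using the sample ($n-1$)
SD — with three repeats the unbiased variance is the sensible choice.

Surface pieces are taped at four aspects (Ant, Post, Left, Right) of the
slice at the centre of the imaging volume; 1-inch film strips between
phantom slabs give vertical and lateral dose profiles. Profile positions
are mm from the machine isocenter projected onto the strip (positive =
anterior or phantom-left); the phantom midplane is deliberately offset
from isocenter on the rotational systems, as it is when patients are set
up to treatment positions, which produces slightly asymmetric lateral
profiles. `asymmetry_summary()` quantifies this as the signed relative
difference of the mean dose on the two sides of the origin.

## The synthetic generator

`generate_scan_pair()` inverts the measurement chain: dose map →
response via a truth calibration → clean pixel values
($pv_0 - 2^{16} y$ reflective; $pv_0\,10^{-y}$ transmissive) →
independent Gaussian pixel noise on each scan → clipping to the 16-bit
range (the clipped fraction is reported and is below $10^{-6}$ at the
default noise). Ground truth is always returned alongside the generated
data, so round-trip tests compare the pipeline against an independent
record, never against itself.

Defaults, chosen once as the study conditions:

* truth calibration `xrqa2_truth_model()`: $b = 0.2$, $c = 0.105$, a
  saturating curve with response 0.35 at 10 cGy and near-linear below
  1 cGy; `ebt3_truth_model()`: $b = 0.006$, $c = 0.004$ (netΔOD 0.25 at
  100 cGy);
* scanner noise `pv0 = 52000`, `sigma_pv = 130`, putting the 25-pixel
  ROI netΔR noise near $3.7\times10^{-4}$ — the level at which sub-2 %
  dosimetry above 0.25 cGy is attainable. This is a model assumption, not
  a measured scanner property;
* calibration sets use ten dose levels per film model with per-point
  response noise $\sigma_y = 3\times10^{-4}$;
* triplicate surface repeats add a repeat-to-repeat dose jitter with CV
  0.035, reproducing standard errors near 2 % of the mean.

Phantom fixtures (`make_phantom_fixture()`) program each machine/site
combination with the reference per-acquisition surface doses at the four
aspects and the site maximum as the profile peak, shaped by the
acquisition geometry: anterior-loaded vertical profiles for the
CyberKnife (ceiling-mounted sources), posterior-loaded for OBI head scans
(the tube rotates behind the head), interior peaks otherwise, and a
programmable isocenter offset (default 8 mm) on the lateral axis of the
rotational systems. Interior profile values between the programmed
endpoints follow piecewise parabolas; they are fixture-defined shapes,
not measured data, and tests assert only the programmed endpoints, peaks
and ordering/asymmetry relations.

What the generator deliberately does **not** emulate: scanner lateral
response and orientation effects, film-to-scanner registration by image
content, film inhomogeneity within a lot, post-irradiation darkening
kinetics (the 24 h protocol point is taken as given), energy-dependent
response within the kV range, and multichannel dosimetry. Passing
round-trip tests therefore demonstrates the correctness of the analysis
chain under the stated noise model — not the physical accuracy of any
particular scanner or film batch.

## Numerical choices

* A pixel belongs to a ROI iff its centre lies in the closed square;
  deterministic and resolution-independent. ROIs that would leave the
  scanned area are errors, never silently clipped.
* Coordinates: origin at the top-left pixel centre, x rightward,
  y downward, in mm.
* Report cells round half away from zero at two decimals
  (`"0.50±0.01"`); formatted tables parse back to their stored values
  within rounding.
* Profile extrema break ties at the smallest position.
* Calibration JSON serialises doubles at 17 significant digits, which
  round-trips IEEE doubles exactly; save → load → save is byte-identical.
* Thresholds are evaluated on log-spaced grids; the bound must hold at
  every grid point above the threshold, so a reported threshold is
  conservative with respect to grid refinement.

## Problem sizes

The packaged study conditions keep everything desk-scale: 10-point
calibration sets, 200-point uncertainty grids, $10^5$-draw Monte-Carlo
cross-checks, 200 replicate fits for parameter-recovery statistics, and
synthetic strips of roughly $1200 \times 50$ pixels. The full test suite
runs in a few seconds.

## Known limitations

* The kV conversion uses the monoenergetic effective-energy mapping; a
  spectrum-weighted conversion would differ at the few-tenths-of-percent
  level for heavily filtered beams.
* The uncertainty budget omits positioning and scan-to-scan registration
  errors; the manifest is trusted for co-registration.
* `sigma_y` from a single ROI pair underestimates the film-to-film
  spread; the optional extra sigma term exists for that but defaults to
  zero.
* Saturation handling is a hard error at $y \ge c/b$; there is no
  graceful high-dose extrapolation beyond the rational form itself.
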