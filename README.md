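# filmdose

Radiochromic film dosimetry for image-guidance dose measurement.

Image-guided radiotherapy (IGRT) adds a small imaging dose — tenths of a
cGy to a few cGy at the surface — at every treatment session, from kV
cone-beam CT (Varian OBI on 21eX / TrueBeam), stereoscopic kV imagers
(CyberKnife), or MV fan-beam CT (TomoTherapy MVCT). `filmdose` implements
a complete reference film dosimetry chain that lets a medical physicist
measure and compare these doses with one dosimeter and one analysis:

* **scan I/O** — 48-bit RGB flatbed TIFF scans (16 bits/channel,
  0.2 mm/px), red-channel statistics over 1 × 1 mm ROIs;
* **film response** — net reflectance change
  `netΔR = (PV_before − PV_after)/2^16` for GAFCHROMIC XRQA2 (kV, air
  kerma in air), net optical density change
  `netΔOD = log10(PV_before/PV_after)` for EBT3 (MV, dose to water), each
  with a one-sigma response noise;
* **calibration** — weighted fits of the rational response model

  `y = (a + c·x) / (1 + b·x)`

  in the general three-parameter form and the improved zero-intercept
  form (`a ≡ 0`: an unexposed film must read zero), closed-form dose
  inversion `x = (y − a)/(c − b·y)`, lossless JSON serialisation;
* **uncertainty** — delta-method one-sigma dose budgets combining the
  response noise with the full calibration-parameter covariance,
  uncertainty-versus-dose curves and threshold statistics, and a
  comparison report for the two calibration forms. The zero-intercept
  form keeps the total dose uncertainty within 2 % for all doses above
  0.25 cGy under the packaged study conditions, versus 3 % above ~1 cGy
  for the general form;
* **dose engine** — air kerma to dose to water via water-to-air
  mass-energy-absorption-coefficient ratios at the HVL-matched effective
  energy (TG-61-style in-air method), the 12-protocol clinical registry,
  per-acquisition scaling of accumulated multi-scan exposures, and
  triplicate aggregation to mean ± standard error;
* **profiles and reports** — 1D dose profiles from film strips, extrema,
  a signed asymmetry statistic, and surface-dose tables formatted as
  `mean±SE` cells;
* **synthetic generator** — seeded forward models for calibration sets,
  before/after scan pairs and humanoid-phantom fixtures, with ground
  truth always stored alongside, so the entire chain is testable without
  physical films.

## Worked example

Fit both calibration forms to a seeded synthetic XRQA2 calibration set,
then measure a CyberKnife pelvis anterior surface piece through the full
pipeline:

```r
library(filmdose)

points <- generate_calibration_set(default_calibration_doses("XRQA2"),
                                   xrqa2_truth_model(),
                                   sigma_y = 3e-4, seed = 42)
report <- compare_models(points,
                         exp(seq(log(0.1), log(10), length.out = 200)),
                         sigma_y_model = 3e-4)
report
#> calibration form comparison
#>   constrained: b = 0.20022, c = 0.10514; rel unc % (b, c) = 0.352, 0.198
#>   general:     a = 0.000147, b = 0.19982, c = 0.10499; rel unc % (a, b, c) = 143, 0.454, 0.28
#>   threshold: <= 2% above 0.1552 cGy (constrained); <= 3% above 0.1176 cGy (general)
#>   b, c agree between forms within one sigma: TRUE

cal <- report$constrained
fx <- make_phantom_fixture("CyberKnife", "pelvis")
pt <- measure_fixture_surface(fx, "Ant", cal, seed = 7)
pt[, c("label", "dose_cgy", "sigma_cgy", "truth_cgy")]
#>                  label dose_cgy  sigma_cgy truth_cgy
#>  CyberKnife/pelvis/Ant 6.490987 0.02402021       6.5
format_dose_cell(pt$dose_cgy, pt$sigma_cgy)
#> [1] "6.49±0.02"
```

Reading the numbers: the general fit's intercept `a` is consistent with
zero but carries a ~143 % relative uncertainty, which is why the
zero-intercept form holds its 2 % dose-uncertainty bound down to
0.16 cGy on this dataset while the general form only manages its 3 %
bound at low dose by a smaller margin. The pipeline recovers the
programmed 6.50 cGy surface dose (per 100 image pairs) to 0.14 %, with a
0.024 cGy one-sigma budget.

## Layout

```
R/                 implementation (scan_io, response, calibration,
                   uncertainty, dose_engine, profiles, synthetic,
                   pipeline, cli)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R
vignettes/         film-dosimetry.Rmd — models, assumptions, design notes
inst/scripts/      filmdose command-line wrapper
```
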