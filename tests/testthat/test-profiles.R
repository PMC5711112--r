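mk_points <- function(pos, dose, sigma = 0.01) {
  do.call(rbind, mapply(function(p, d) dose_point(d, sigma, position_mm = p,
                                                  label = "prof"),
                        pos, dose, SIMPLIFY = FALSE))
}

test_that("profiles sort by position and reject malformed input", {
  pts <- mk_points(c(5, -5, 0), c(1, 2, 3))
  prof <- build_profile(pts, "lateral")
  expect_equal(prof$points$position_mm, c(-5, 0, 5))
  expect_equal(prof$points$dose_cgy, c(2, 3, 1))
  expect_error(build_profile(mk_points(c(0, 0, 5), c(1, 2, 3)), "lateral"),
               "duplicate")
  expect_error(build_profile(mk_points(0, 1), "lateral"), "nrow")
  expect_error(build_profile(mk_points(c(-1, 1), c(-0.5, 1)), "lateral"),
               "nonnegative")
})

test_that("extrema pick the extreme doses with ties at the smallest position", {
  flat <- build_profile(mk_points(c(-4, -2, 0, 2), rep(1.5, 4)), "vertical")
  ex <- profile_extrema(flat)
  expect_equal(ex$min$dose_cgy, ex$max$dose_cgy)
  expect_equal(ex$max$position_mm, -4)  # tie broken by smallest position
  peaked <- build_profile(mk_points(-3:3, c(1, 2, 5, 9, 5, 2, 1)), "vertical")
  expect_equal(profile_extrema(peaked)$max$position_mm, 0)
  expect_equal(profile_extrema(peaked)$min$position_mm, -3)
})

test_that("the asymmetry statistic is signed and antisymmetric", {
  sym <- build_profile(mk_points(c(-4, -2, 2, 4), c(1, 2, 2, 1)), "vertical")
  expect_equal(asymmetry_summary(sym), 0)
  ant <- build_profile(mk_points(c(-4, -2, 2, 4), c(1, 1, 2, 3)), "vertical")
  expect_gt(asymmetry_summary(ant), 0)
  mirrored <- build_profile(mk_points(-c(-4, -2, 2, 4), c(1, 1, 2, 3)),
                            "vertical")
  expect_equal(asymmetry_summary(mirrored), -asymmetry_summary(ant))
  one_sided <- build_profile(mk_points(c(1, 2), c(1, 2)), "vertical")
  expect_error(asymmetry_summary(one_sided), "both sides")
})

test_that("fixture profile shapes carry the acquisition-geometry asymmetries", {
  pos <- function(f, ax) seq(-f$profiles[[ax]]$span_mm / 2,
                             f$profiles[[ax]]$span_mm / 2, by = 2)
  truth_profile <- function(machine, site, ax) {
    f <- make_phantom_fixture(machine, site)
    p <- pos(f, ax)
    build_profile(mk_points(p, fixture_profile_dose(f, ax, p)), ax)
  }
  # ceiling-mounted sources load the anterior side
  expect_gt(asymmetry_summary(truth_profile("CyberKnife", "head", "vertical")), 0)
  expect_gt(asymmetry_summary(truth_profile("CyberKnife", "pelvis", "vertical")), 0)
  # the OBI head technique rotates behind the head: posterior excess
  expect_lt(asymmetry_summary(truth_profile("OBI_21eX", "head", "vertical")), 0)
  # CyberKnife lateral profiles are symmetric; rotational systems carry the
  # programmed isocenter offset
  expect_equal(asymmetry_summary(truth_profile("CyberKnife", "pelvis", "lateral")),
               0, tolerance = 0.02)
  expect_false(isTRUE(all.equal(
    asymmetry_summary(truth_profile("OBI_21eX", "pelvis", "lateral")), 0)))
})

test_that("surface cells format as mean±SE with half-up rounding and parse back", {
  expect_identical(format_dose_cell(0.50, 0.01), "0.50±0.01")
  expect_identical(format_dose_cell(0.505, 0.015), "0.51±0.02")
  expect_identical(format_dose_cell(6.499, 0.104), "6.50±0.10")
  expect_equal(unname(parse_dose_cell("3.72±0.06")), c(3.72, 0.06))
  expect_error(parse_dose_cell("3.72"), "malformed")
})

test_that("the surface-dose table reproduces the reference layout cell by cell", {
  pts <- do.call(rbind, lapply(c("OBI_21eX", "OBI_TrueBeam", "CyberKnife",
                                 "TomoTherapy"), function(m)
    do.call(rbind, lapply(c("head", "thorax", "pelvis"), function(s) {
      f <- make_phantom_fixture(m, s)
      do.call(rbind, lapply(names(f$surface_values), function(a)
        dose_point(unname(f$surface_values[a]), unname(f$surface_se[a]),
                   aspect = a, site = s, machine = m, label = "t")))
    }))))
  tab <- surface_dose_table(pts)
  expect_identical(dim(tab), c(12L, 6L))
  cell <- function(site, aspect, machine)
    tab[tab$site == site & tab$aspect == aspect, machine]
  expect_identical(cell("head", "Post", "OBI_21eX"), "0.50±0.01")
  expect_identical(cell("pelvis", "Ant", "CyberKnife"), "6.50±0.10")
  expect_identical(cell("head", "Post", "TomoTherapy"), "2.92±0.05")
  expect_identical(cell("thorax", "Ant", "OBI_TrueBeam"), "0.65±0.01")
  # every formatted cell parses back to its stored values within rounding
  for (i in seq_len(nrow(pts))) {
    v <- parse_dose_cell(cell(pts$site[i], pts$aspect[i], pts$machine[i]))
    expect_lt(abs(v[1] - pts$dose_cgy[i]), 0.005 + 1e-9)
    expect_lt(abs(v[2] - pts$sigma_cgy[i]), 0.005 + 1e-9)
  }
  # missing combinations render as explicit blanks with a warning
  expect_warning(t2 <- surface_dose_table(pts[-1, ]), "no surface dose")
  expect_identical(t2[t2$site == pts$site[1] & t2$aspect == pts$aspect[1],
                      pts$machine[1]], "")
  # rendered table round-trips through the plain-text layout
  lines <- capture.output(render_surface_dose_table(tab))
  expect_true(any(grepl("0.50±0.01", lines, fixed = TRUE)))
})

test_that("surface ordering relations survive the full measurement round trip", {
  cal_x <- std_xrqa2_model()
  cal_e <- std_ebt3_model()
  measure <- function(machine, site, aspect, seed) {
    f <- make_phantom_fixture(machine, site)
    cal <- if (f$film_model == "EBT3") cal_e else cal_x
    suppressWarnings(
      measure_fixture_surface(f, aspect, cal, seed = seed))$dose_cgy
  }
  # CyberKnife: sources above the patient, anterior always hottest
  for (s in c("head", "thorax", "pelvis"))
    expect_gt(measure("CyberKnife", s, "Ant", 21), measure("CyberKnife", s, "Post", 22))
  # OBI head: tube rotates behind the head
  expect_gt(measure("OBI_21eX", "head", "Post", 23),
            measure("OBI_21eX", "head", "Ant", 24))
  # MVCT: charged particles from the couch land on the posterior surface
  for (s in c("head", "thorax", "pelvis"))
    expect_gt(measure("TomoTherapy", s, "Post", 25), measure("TomoTherapy", s, "Ant", 26))
})
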