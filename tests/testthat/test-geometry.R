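# Asymmetry geometry: angles, areas, ratios, and their invariances.

test_that("signed tilt follows the clockwise-positive convention", {
  expect_equal(signed_tilt_deg(c(0, 5), c(10, 5)), 0)
  expect_equal(signed_tilt_deg(c(0, 0), c(10, 10)), 45) # right end lower
  expect_equal(signed_tilt_deg(c(0, 10), c(10, 0)), -45)
  expect_equal(signed_tilt_deg(c(0, 0), c(8, 2)), 14.0362434679, tolerance = 1e-9)
  expect_error(signed_tilt_deg(c(10, 0), c(0, 0)), "side-order",
               class = "trunkmetrics_geometry_error")
})

test_that("height angles are the per-pair tilts", {
  t <- make_template()
  expect_equal(unname(height_angles(t)), c(0, 0, 0))
  rot <- apply_deformity(t, list(sha_deg = 5))
  ha <- height_angles(rot)
  expect_equal(ha[["sha_deg"]], 5, tolerance = 1e-12)
  expect_equal(ha[["aha_deg"]], 0)
  expect_equal(ha[["wha_deg"]], 0)
  f1 <- height_angles(f1_landmarks())
  expect_equal(f1[["sha_deg"]], f1_expected$sha_deg, tolerance = 1e-9)
  expect_equal(f1[["aha_deg"]], f1_expected$aha_deg, tolerance = 1e-9)
  expect_equal(f1[["wha_deg"]], f1_expected$wha_deg, tolerance = 1e-9)
})

test_that("waistline angle is the interior angle at the waist vertex", {
  expect_equal(waistline_angle(c(0, -5), c(0, 0), c(0, 5)), 180)
  expect_equal(waistline_angle(c(0, -5), c(0, 0), c(5, 0)), 90)
  expect_equal(waistline_angle(c(1, -3), c(0, 0), c(0, 3)), 161.5650511771,
               tolerance = 1e-9)
  expect_error(waistline_angle(c(0, 0), c(0, 0), c(1, 1)), "degenerate",
               class = "trunkmetrics_geometry_error")
  expect_equal(waistline_angle_difference(144.8, 147.9), -3.1)
  expect_equal(waistline_angle_difference(150, 130), 20)
})

test_that("shoelace area matches hand values and rejects degenerate input", {
  expect_equal(polygon_area_px2(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygon_area_px2(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  expect_equal(polygon_area_px2(rbind(c(0, 1), c(-4, 1), c(-3, 3), c(0, 3))), 7)
  # orientation independence
  expect_equal(polygon_area_px2(rbind(c(0, 1), c(0, 3), c(-3, 3), c(-4, 1))), 7)
  expect_error(polygon_area_px2(rbind(c(0, 0), c(1, 1))), "3")
})

test_that("shoelace area agrees with a Monte-Carlo rasterization oracle", {
  set.seed(404)
  for (i in 1:5) {
    poly <- random_convex_polygon(sample(4:10, 1))
    mc <- mc_polygon_area(poly)
    expect_lt(abs(polygon_area_px2(poly) - mc$estimate), 3 * mc$se)
  }
})

test_that("hemitrunk areas match the F1 hand shoelace computation", {
  a <- hemitrunk_areas(f1_landmarks())
  expect_equal(a$plumbline_x, 500)
  for (nm in names(f1_expected$areas)) {
    expect_equal(a[[nm]], unname(f1_expected$areas[nm]), info = nm)
  }
})

test_that("hemitrunk areas are mirror-equal for the template and scale as length squared", {
  t <- make_template()
  a <- hemitrunk_areas(t)
  for (region in c("shoulder", "waist", "pelvic")) {
    expect_equal(a[[paste0(region, "_left_px2")]],
                 a[[paste0(region, "_right_px2")]])
  }
  a2 <- hemitrunk_areas(scale_landmarks(t, 2))
  for (nm in grep("_px2$", names(a), value = TRUE)) {
    expect_equal(a2[[nm]], 4 * a[[nm]])
  }
})

test_that("plumbline outside the trunk is a degenerate-geometry error", {
  t <- make_template()
  pts <- t$landmarks
  pts$c7[["x"]] <- pts$waist_right[["x"]] + 1
  bad <- back_landmarks("bad", pts)
  expect_error(hemitrunk_areas(bad), "plumbline",
               class = "trunkmetrics_geometry_error")
})

test_that("area ratios follow hand arithmetic and reject zero denominators", {
  mk <- function(left, right) {
    structure(list(plumbline_x = 0,
                   shoulder_left_px2 = left[1], waist_left_px2 = left[2],
                   pelvic_left_px2 = left[3],
                   shoulder_right_px2 = right[1], waist_right_px2 = right[2],
                   pelvic_right_px2 = right[3]),
              class = "hemitrunk_areas")
  }
  expect_equal(unname(area_ratios(mk(c(3, 3, 3), c(3, 3, 3)))), rep(1, 4))
  expect_equal(unname(area_ratios(mk(c(2, 2, 2), c(4, 4, 4)))), rep(0.5, 4))
  expect_equal(unname(area_ratios(mk(c(7, 3, 5), c(5, 6, 4)))),
               c(1.4, 0.5, 1.25, 1))
  expect_error(area_ratios(mk(c(1, 1, 1), c(0, 1, 1))), "shoulder",
               class = "trunkmetrics_geometry_error")
})

test_that("the full F1 profile matches the hand oracle and its invariants", {
  p <- measure_profile(f1_landmarks())
  for (nm in c("sha_deg", "aha_deg", "wha_deg", "lwa_deg", "rwa_deg",
               "wad_deg", "sa_ratio", "wa_ratio", "pa_ratio", "ta_ratio")) {
    expect_equal(p[[nm]], f1_expected[[nm]], tolerance = 1e-9, info = nm)
  }
})

test_that("a symmetric template has the identity profile", {
  for (h in c(1500, 600)) {
    p <- measure_profile(make_template(h, h * 2 / 3))
    expect_equal(unname(profile_values(p)[c("SHA", "AHA", "WHA", "WAD")]),
                 rep(0, 4))
    expect_equal(p$lwa_deg, p$rwa_deg)
    expect_equal(unname(profile_values(p)[c("SA", "WA", "PA", "TA")]),
                 rep(1, 4))
  }
})

test_that("profiles are translation- and scale-invariant", {
  set.seed(11)
  t <- make_template()
  for (i in 1:10) {
    lms <- random_deformed(t)
    v <- profile_values(measure_profile(lms))
    expect_equal(profile_values(measure_profile(
      translate_landmarks(lms, 37, -12))), v, tolerance = 1e-10)
    expect_equal(profile_values(measure_profile(
      scale_landmarks(lms, 2.5, center = c(13, -7)))), v, tolerance = 1e-10)
  }
})

test_that("mirroring about the plumbline negates angles, swaps waistline angles and inverts ratios", {
  set.seed(12)
  t <- make_template()
  for (i in 1:10) {
    lms <- random_deformed(t)
    v <- profile_values(measure_profile(lms))
    m <- profile_values(measure_profile(mirror_landmarks(lms)))
    expect_equal(unname(m[c("SHA", "AHA", "WHA", "WAD")]),
                 unname(-v[c("SHA", "AHA", "WHA", "WAD")]), tolerance = 1e-10)
    expect_equal(unname(m[c("LWA", "RWA")]), unname(v[c("RWA", "LWA")]),
                 tolerance = 1e-10)
    expect_equal(unname(m[c("SA", "WA", "PA", "TA")]),
                 unname(1 / v[c("SA", "WA", "PA", "TA")]), tolerance = 1e-10)
  }
})

test_that("WAD identity and the mediant bound hold on random profiles", {
  set.seed(13)
  t <- make_template()
  for (i in 1:20) {
    p <- measure_profile(random_deformed(t))
    expect_identical(p$wad_deg, p$lwa_deg - p$rwa_deg)
    ratios <- c(p$sa_ratio, p$wa_ratio, p$pa_ratio)
    expect_gte(p$ta_ratio, min(ratios))
    expect_lte(p$ta_ratio, max(ratios))
    expect_true(all(ratios > 0))
  }
})

test_that("moving the plumbline toward the patient's right increases the total area ratio", {
  t <- make_template()
  shifts <- c(-60, -20, 0, 20, 60)
  tas <- vapply(shifts, function(s) {
    measure_profile(apply_deformity(t, list(trunk_shift_px = s)))$ta_ratio
  }, numeric(1))
  expect_true(all(diff(tas) > 0))
  expect_gt(tas[5], 1)
  expect_lt(tas[1], 1)
})

test_that("profile tables round-trip through the CSV report", {
  profs <- list(measure_profile(f1_landmarks()),
                measure_profile(make_template(photo_id = "T")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profs, path)
  back <- read_profiles(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$SHA[1], f1_expected$sha_deg, tolerance = 1e-9)
  expect_equal(back$TA[2], 1)
  expect_named(back, c("photo_id", MEASURE_NAMES,
                       "shoulder_left_px2", "shoulder_right_px2",
                       "waist_left_px2", "waist_right_px2",
                       "pelvic_left_px2", "pelvic_right_px2", "plumbline_x"))
})
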