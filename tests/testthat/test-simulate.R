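test_that("index-matched media record the undistorted rotated geometry", {
  ph <- make_phantom("young_adult", media = optical_media(1, 1, 1, 1))
  prot <- fx_protocol_small()
  mer <- forward_simulate(ph, prot, "nasal_30")
  gz <- attr(mer, "gaze")
  cal <- oct_calibration(lateral_scale = prot$lateral_range / prot$n_ascans)
  p3 <- map_meridians_to_3d(pixels_to_mm(
    mer[!mer$missing & mer$surface != "IRIS", ], cal,
    n_ascans = prot$n_ascans))
  # map recorded points back into the phantom frame and compare to conicoids
  m <- cbind(p3$x, p3$y, p3$z)
  m <- sweep((m - matrix(gz$centre, nrow(m), 3, byrow = TRUE)) %*%
               gz$rotation, 2, gz$centre, "+")
  r <- sqrt(m[, 1]^2 + m[, 2]^2)
  sag <- lensrecon:::conicoid_sag
  zt <- rep(NA_real_, nrow(m))
  for (s in c("CA", "CP", "LA", "LP")) {
    conic <- switch(s, CA = ph$cornea_ant, CP = ph$cornea_post,
                    LA = ph$lens_ant, LP = ph$lens_post)
    sel <- p3$surface == s
    zt[sel] <- conic$apex_z + sag(conic, r[sel])
  }
  expect_lt(max(abs(m[, 3] - zt), na.rm = TRUE), 1e-6)
})

test_that("axial pixel reading is cumulative OPL over the axial scale", {
  # central A-scan, on axis: CA at its sag, CP deeper by n_cornea * thickness
  mer <- fx_sim_onaxis()
  prot <- fx_protocol()
  ph <- fx_phantom()
  centre <- mer[mer$ascan_index %in% c(127, 128) & mer$meridian_index == 0, ]
  ca <- centre$z_px[centre$surface == "CA"]
  cp <- centre$z_px[centre$surface == "CP"]
  # OPL between the corneal surfaces at the apex ~ n_cornea * 0.55 mm
  expect_equal(mean(cp - ca) * prot$axial_scale / 1000,
               ph$media$n_cornea * 0.55, tolerance = 2e-3)
  # a 1 mm geometric step in a 1.345 medium reads 1345 / 9.2 pixels
  expect_equal(1 * 1.345 * 1000 / 9.2, 146.2, tolerance = 0.01)
})

test_that("on-axis lens samples beyond the pupil radius are missing", {
  mer <- fx_sim_onaxis()
  prot <- fx_protocol()
  pitch <- prot$lateral_range / prot$n_ascans
  lens <- mer[mer$surface %in% c("LA", "LP"), ]
  lat <- abs((lens$ascan_index - (prot$n_ascans - 1) / 2) * pitch)
  # corneal refraction converges rays, so the iris-plane radius is slightly
  # smaller than the A-scan lateral position; 0.6 mm covers the convergence
  expect_true(all(lens$missing[lat > fx_phantom()$pupil_radius + 0.6]))
  expect_true(any(!lens$missing[lat < fx_phantom()$pupil_radius - 0.5]))
})

test_that("occluded lens fraction decreases as the pupil dilates", {
  prot <- fx_protocol_small()
  frac <- vapply(c(2.0, 2.8, 3.6, 4.4), function(pr) {
    ph <- make_phantom("young_adult", pupil_radius = pr)
    mer <- forward_simulate(ph, prot, "on_axis")
    lens <- mer[mer$surface %in% c("LA", "LP"), ]
    mean(lens$missing)
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
})

test_that("identical seeds give byte-identical acquisition files", {
  ph <- fx_phantom()
  prot <- fx_protocol_small(noise_sd_px = 1.5, rng_seed = 42L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_acquisition(forward_simulate(ph, prot, "on_axis"), d1, prot)
  write_acquisition(forward_simulate(ph, prot, "on_axis"), d2, prot)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the noise
  prot2 <- fx_protocol_small(noise_sd_px = 1.5, rng_seed = 43L)
  m3 <- forward_simulate(ph, prot2, "on_axis")
  m1 <- forward_simulate(ph, prot, "on_axis")
  expect_false(isTRUE(all.equal(m1$z_px, m3$z_px)))
})

test_that("unknown orientations and degenerate protocols are rejected", {
  expect_error(forward_simulate(fx_phantom(), fx_protocol(), "sideways"),
               "not in the protocol")
  expect_error(acquisition_protocol(n_meridians = 10, meridian_step = 0.048),
               "span")
  expect_error(acquisition_protocol(noise_sd_px = -1), "noise")
})

test_that("simulated meridians span [0, pi) at the 0.048 rad spacing", {
  mer <- fx_sim_onaxis()
  angles <- sort(unique(mer$meridian_angle))
  expect_equal(length(angles), 65)
  expect_equal(diff(angles), rep(0.048, 64))
  expect_equal(max(angles), 64 * 0.048, tolerance = 1e-12)
  expect_lt(max(angles), pi)
})
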