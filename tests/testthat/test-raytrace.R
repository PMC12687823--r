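test_that("vector Snell matches scalar Snell across random geometries", {
  # normal incidence and matched indices are identities
  d <- c(0, 0, 1)
  expect_equal(as.numeric(snell_refract_3d(d, c(0, 0, -1), 1, 1.5)), d)
  d30 <- c(sin(pi / 6), 0, cos(pi / 6))
  expect_equal(as.numeric(snell_refract_3d(d30, c(0.3, -0.2, -0.9), 1.33, 1.33)),
               d30, tolerance = 1e-12)
  # 30 deg across air -> 1.5: refraction angle asin(sin(30)/1.5)
  out <- snell_refract_3d(d30, c(0, 0, -1), 1, 1.5)
  ang <- acos(abs(out[1, 3]))
  expect_equal(ang, asin(sin(pi / 6) / 1.5), tolerance = 1e-9)
  expect_equal(ang * 180 / pi, 19.471, tolerance = 1e-4)

  # 1000 random incidence geometries: angle to the normal obeys scalar Snell,
  # the tangential component of n * direction is conserved, and the refracted
  # ray stays in the plane of incidence
  withr::with_seed(101, {
    d <- lensrecon:::normalize_rows(matrix(rnorm(3000), 1000, 3))
    nn <- lensrecon:::normalize_rows(matrix(rnorm(3000), 1000, 3))
    n1 <- runif(1000, 1, 1.8)
    n2 <- runif(1000, 1, 1.8)
  })
  out <- snell_refract_3d(d, nn, 1, 1.5)  # fixed pair first
  ci <- abs(rowSums(d * nn))
  si <- sqrt(1 - ci^2)
  st <- sqrt(1 - abs(rowSums(out * nn))^2)
  expect_lt(max(abs(st - si / 1.5)), 1e-9)
  # conservation of the tangential wave-vector component, per ray
  tang_in <- 1 * (d - rowSums(d * nn) * nn)
  tang_out <- 1.5 * (out - rowSums(out * nn) * nn)
  expect_lt(max(abs(tang_in - tang_out)), 1e-10)
  # plane of incidence: out is a linear combination of d and n
  cr <- cbind(d[, 2] * nn[, 3] - d[, 3] * nn[, 2],
              d[, 3] * nn[, 1] - d[, 1] * nn[, 3],
              d[, 1] * nn[, 2] - d[, 2] * nn[, 1])
  expect_lt(max(abs(rowSums(cr * out))), 1e-10)
})

test_that("total internal reflection is signalled, never silently reflected", {
  d <- c(sin(70 * pi / 180), 0, cos(70 * pi / 180))
  out <- snell_refract_3d(d, c(0, 0, -1), 1.7, 1.0)
  expect_true(all(is.na(out)))
  # just below the critical angle refracts fine
  dc <- c(sin(30 * pi / 180), 0, cos(30 * pi / 180))
  expect_false(any(is.na(snell_refract_3d(dc, c(0, 0, -1), 1.7, 1.0))))
})

test_that("ray-surface intersection matches plane and sphere oracles", {
  # plane z = 2
  pl <- tibble::tibble(x = runif(80, -3, 3), y = runif(80, -3, 3), z = 2)
  fpl <- fit_zernike(pl, n_terms = 6)
  hit <- intersect_ray_surface(matrix(c(0.5, -0.2, -1), 1),
                               matrix(c(0, 0, 1), 1), fpl)
  expect_equal(as.numeric(hit$point), c(0.5, -0.2, 2), tolerance = 1e-9)
  expect_equal(abs(as.numeric(hit$normal)), c(0, 0, 1), tolerance = 1e-9)

  # sphere cap, apex at origin, radius 7
  sp <- disc_points(800, radius = 3.5, seed = 21)
  R <- 7
  sp$z <- R - sqrt(R^2 - sp$x^2 - sp$y^2)
  fsp <- fit_zernike(sp, n_terms = 15)
  # axial ray through the apex (agreement limited by the 15-term fit bias)
  hit0 <- intersect_ray_surface(matrix(c(0, 0, -2), 1), matrix(c(0, 0, 1), 1),
                                fsp)
  expect_lt(max(abs(as.numeric(hit0$point) - c(0, 0, 0))), 5e-4)
  # the solver itself lands on the fitted surface to 1e-9
  on_surf <- evaluate_zernike(fsp, hit0$point[1], hit0$point[2])$z
  expect_lt(abs(hit0$point[3] - on_surf), 1e-8)
  # oblique ray versus the closed-form line-sphere intersection
  o <- c(1.2, -0.8, -3)
  dvec <- c(0.15, 0.1, 1); dvec <- dvec / sqrt(sum(dvec^2))
  ctr <- c(0, 0, R)
  b <- 2 * sum(dvec * (o - ctr))
  cc <- sum((o - ctr)^2) - R^2
  t_true <- (-b - sqrt(b^2 - 4 * cc)) / 2
  hit1 <- intersect_ray_surface(matrix(o, 1), matrix(dvec, 1), fsp)
  p_true <- o + t_true * dvec
  expect_lt(max(abs(as.numeric(hit1$point) - p_true)), 5e-4)
  on_surf1 <- evaluate_zernike(fsp, hit1$point[1], hit1$point[2])$z
  expect_lt(abs(hit1$point[3] - on_surf1), 1e-8)
})

test_that("correction with matched indices is the identity on geometry", {
  ph <- make_phantom("young_adult", media = optical_media(1, 1, 1, 1))
  mer <- forward_simulate(ph, fx_protocol_small(), "on_axis")
  raw <- eye_model_from_meridians(mer)
  cor <- correct_model(raw, media = ph$media)
  raw_pts <- raw$points[raw$points$surface %in% c("CP", "LA", "LP"), ]
  cor_pts <- cor$points[cor$points$surface %in% c("CP", "LA", "LP"), ]
  # corrected equals uncorrected (up to dropped out-of-domain rays)
  expect_lte(nrow(cor_pts), nrow(raw_pts))
  j <- dplyr::inner_join(cor_pts, raw_pts,
                         by = c("surface", "meridian_index", "ascan_index"))
  expect_gt(nrow(j), 0.8 * nrow(cor_pts))
  expect_lt(max(abs(j$z.x - j$z.y)), 1e-9)
  expect_lt(max(abs(j$x.x - j$x.y)), 1e-9)
})

test_that("single-layer OPL arithmetic recovers corneal thickness", {
  # flat CA at z = 1; flat CP measured at OPL 0.743 mm below it
  grid <- expand.grid(x = seq(-3, 3, 0.25), y = seq(-3, 3, 0.25))
  ca <- tibble::tibble(x = grid$x, y = grid$y, z = 1)
  fca <- fit_zernike(ca, n_terms = 6)
  ascans <- tibble::tibble(x = ca$x, y = ca$y, z_CA = 1, z_CP = 1 + 0.743,
                           z_LA = NA_real_, z_LP = NA_real_,
                           z_IRIS = NA_real_)
  model <- assemble_model(list(CA = fca), iris = tibble::tibble(),
                          incidence = "on_axis", ascans = ascans)
  cor <- correct_model(model, media = optical_media(), n_terms = 6,
                       correct_iris = FALSE)
  cp <- cor$points[cor$points$surface == "CP", ]
  expect_equal(mean(cp$z - 1), 0.743 / 1.385, tolerance = 1e-9)
  expect_equal(0.743 / 1.385, 0.536, tolerance = 1e-3)
})

test_that("forward distortion is inverted to a few microns on the phantom", {
  ph <- fx_phantom()
  cor <- fx_corrected_onaxis()
  sag <- lensrecon:::conicoid_sag
  for (s in c("CP", "LA", "LP")) {
    p <- cor$points[cor$points$surface == s, ]
    conic <- switch(s, CP = ph$cornea_post, LA = ph$lens_ant,
                    LP = ph$lens_post)
    zt <- conic$apex_z + sag(conic, sqrt(p$x^2 + p$y^2))
    err <- (p$z - zt)
    expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 5e-3)
  }
})

test_that("surface correction honours physical ordering", {
  cor <- fx_corrected_onaxis()
  expect_error(correct_model(cor), "already corrected")
  expect_error(correct_surface(cor, "LP"), "ordering|raw")
})

test_that("3-D correction leaves the meridian plane at oblique incidence", {
  # at 45 deg gaze, rays of a meridian not aligned with the rotation plane
  # are refracted out of that plane; per-meridian 2-D correction cannot
  # represent this
  mer <- simulate_protocol(fx_phantom(), fx_protocol())
  m45 <- mer[mer$incidence == "nasal_45", ]
  cor <- correct_model(eye_model_from_meridians(m45), media = optical_media())
  ang <- 16 * 0.048  # meridian well away from the x-z rotation plane
  lp <- cor$points[cor$points$surface == "LP" & cor$points$meridian_index == 16, ]
  expect_gt(nrow(lp), 50)
  # distance of 3-D-corrected points from the B-scan's own plane
  nrm2 <- c(-sin(ang), cos(ang))
  off_plane <- abs(lp$x * nrm2[1] + lp$y * nrm2[2])
  expect_gt(max(off_plane), 10e-3)
})
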