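test_that("sphere limits hold simultaneously for DIA, VOL and LSA", {
  for (R in c(1, 3, 4.6)) {
    g <- sphere_grid(R)
    expect_equal(as.numeric(compute_diameter(g)), 2 * R, tolerance = 5e-3)
    expect_equal(compute_volume(g), 4 / 3 * pi * R^3, tolerance = 5e-3)
    expect_equal(compute_surface_area(g), 4 * pi * R^2, tolerance = 5e-3)
  }
  # the default grid is well inside 0.5 %
  g <- sphere_grid(1)
  expect_lt(abs(compute_volume(g) - 4 / 3 * pi) / (4 / 3 * pi), 0.005)
  expect_lt(abs(compute_surface_area(g) - 4 * pi) / (4 * pi), 0.005)
})

test_that("an ellipsoid's diameter is its major axis", {
  a <- 5; b <- 4; cc <- 2
  P <- 100; Q <- 100
  g <- lensrecon:::new_lens_polar_grid(matrix(0, P, Q), P, Q)
  I <- outer(g$theta, g$phi, function(t, p)
    1 / sqrt(sin(t)^2 * cos(p)^2 / a^2 + sin(t)^2 * sin(p)^2 / b^2 +
               cos(t)^2 / cc^2))
  g$I <- I
  d <- compute_diameter(g)
  expect_equal(as.numeric(d), 2 * a, tolerance = 2e-3)
  expect_equal(attr(d, "azimuth_rad") %% pi, 0, tolerance = 0.05)
  # ellipsoid volume 4/3 pi a b c
  expect_equal(compute_volume(g), 4 / 3 * pi * a * b * cc, tolerance = 5e-3)
})

test_that("metrics are invariant to rotation about the polar axis", {
  g <- phantom_lens_grid(fx_phantom())
  # make it azimuthally structured (elliptical scaling), then rotate by
  # whole grid steps: an exact column permutation
  I <- g$I * (1 + 0.03 * cos(2 * matrix(g$phi, g$P, g$Q, byrow = TRUE)))
  g$I <- I
  m0 <- c(compute_diameter(g), compute_volume(g), compute_surface_area(g))
  g2 <- g
  g2$I <- I[, c(26:100, 1:25)]
  m2 <- c(compute_diameter(g2), compute_volume(g2), compute_surface_area(g2))
  expect_equal(m2, m0, tolerance = 1e-9)
  # a general small 3-D rotation, via resampling: agreement to interpolation
  # accuracy
  cloud <- lensrecon:::polar_grid_points(g)
  Rt <- lensrecon:::rotation_about_axis(c(1, 0.5, 0.2), 0.2)
  rot <- as.matrix(cloud[, c("x", "y", "z")]) %*% t(Rt)
  g3 <- to_polar_grid(tibble::tibble(x = rot[, 1], y = rot[, 2],
                                     z = rot[, 3]), max_points = 200000,
                      max_angle = 0.1)
  expect_false(anyNA(g3$I))
  m3 <- c(compute_diameter(g3), compute_volume(g3), compute_surface_area(g3))
  expect_equal(m3, m0, tolerance = 2e-3)
})

test_that("volume and area converge under grid refinement at order >= 2", {
  ph <- fx_phantom()
  vol_true <- phantom_truth(ph)$vol_mm3
  lsa_true <- phantom_truth(ph)$lsa_mm2
  sizes <- c(50, 100, 200)
  errs <- vapply(sizes, function(P) {
    g <- phantom_lens_grid(ph, P = P, Q = P)
    c(abs(compute_volume(g) - vol_true), abs(compute_surface_area(g) - lsa_true))
  }, numeric(2))
  # halving the step divides the error by at least ~3.5 (order ~2)
  expect_gt(errs[1, 1] / errs[1, 2], 3.5)
  expect_gt(errs[2, 1] / errs[2, 2], 3.5)
  expect_gt(errs[1, 2] / errs[1, 3], 3.5)
  expect_gt(errs[2, 2] / errs[2, 3], 3.5)
})

test_that("two-cap phantom volume matches the spherical cap-sum formula", {
  ph <- make_phantom(NULL, lens_radius_ant = 10, lens_radius_post = 6,
                     lens_conic_ant = 0, lens_conic_post = 0,
                     lens_thickness = 4, lens_dia = NULL, pupil_radius = 1.5)
  g <- phantom_lens_grid(ph, P = 200, Q = 100)
  f <- function(r) sqrt(100 - r^2) + sqrt(36 - r^2) - 12
  re <- uniroot(f, c(1, 5.9), tol = 1e-12)$root
  h1 <- 10 - sqrt(100 - re^2)
  h2 <- 6 - sqrt(36 - re^2)
  cap_sum <- pi * h1^2 * (30 - h1) / 3 + pi * h2^2 * (18 - h2) / 3
  expect_equal(compute_volume(g), cap_sum, tolerance = 5e-3)
})

test_that("phantom diameter parameter is recovered through the grid", {
  ph <- make_phantom("young_adult", lens_dia = 9.0)
  g <- phantom_lens_grid(ph)
  expect_equal(as.numeric(compute_diameter(g)), 9.0, tolerance = 0.01 / 9)
})

test_that("refined-grid area converges from below for convex shapes", {
  areas <- vapply(c(40, 80, 160), function(P)
    compute_surface_area(sphere_grid(2, P = P, Q = P)), numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas < 4 * pi * 4))
})

test_that("incomplete shapes are refused with advice to reconstruct", {
  g <- sphere_grid(2)
  g$I[5, 5] <- NA
  expect_error(compute_volume(g), "missing nodes")
  expect_error(lens_metrics(g), "missing nodes")
})

test_that("the regular-grid triangulation matches a Delaunay oracle", {
  skip_if_not_installed("deldir")
  # small grid: compare against deldir's Delaunay triangulation of the
  # parameter plane, evaluating total 3-D area on an asymmetric shape
  P <- 24; Q <- 24
  g <- lensrecon:::new_lens_polar_grid(matrix(0, P, Q), P, Q)
  g$I <- outer(g$theta, g$phi, function(t, p)
    3 + 0.2 * sin(2 * t) * cos(p) + 0.1 * cos(3 * p))
  a_grid <- compute_surface_area(g)
  pts <- lensrecon:::polar_grid_points(g)
  # parameter-plane Delaunay (jitter the regular grid to break co-circularity)
  withr::with_seed(8, {
    jit_t <- pts$theta + runif(nrow(pts), -1e-7, 1e-7)
    jit_p <- pts$phi + runif(nrow(pts), -1e-7, 1e-7)
  })
  dd <- deldir::deldir(jit_p, jit_t)
  tl <- deldir::triang.list(dd)
  area3 <- sum(vapply(tl, function(tr) {
    v <- as.matrix(pts[tr$ptNum, c("x", "y", "z")])
    0.5 * sqrt(sum(lensrecon:::pracma_cross(v[2, ] - v[1, ],
                                            v[3, ] - v[1, ])^2))
  }, numeric(1)))
  # the azimuth seam (phi wrap) is absent from the oracle triangulation;
  # agreement on the bulk is a few percent at this coarse grid
  expect_equal(area3, a_grid, tolerance = 0.06)
})
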