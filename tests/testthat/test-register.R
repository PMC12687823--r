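circle_points <- function(n, centre = c(0, 0, 0), radius = 5.5,
                          tilt = diag(3), noise = 0, seed = 1) {
  withr::with_seed(seed, {
    a <- seq(0, 2 * pi, length.out = n + 1)[-1]
    p <- cbind(radius * cos(a), radius * sin(a), 0)
    if (noise > 0) p <- p + matrix(rnorm(3 * n, sd = noise), n, 3)
    sweep(p %*% t(tilt), 2, centre, "+")
  })
}

test_that("an exact coplanar circle is fitted exactly", {
  pts <- circle_points(120, centre = c(1, 2, 0))
  fit <- fit_iris(pts)
  expect_equal(abs(fit$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fit$centre, c(1, 2, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 5.5, tolerance = 1e-9)
  # circle centre lies on the fitted plane
  expect_lt(abs(sum(fit$normal * fit$centre) - fit$offset), 1e-9)
})

test_that("a rotated iris plane recovers its tilt to 1e-9", {
  Rt <- lensrecon:::rotation_about_axis(c(1, 0, 0), 20 * pi / 180)
  pts <- circle_points(150, centre = c(0.5, -0.3, 1), tilt = Rt)
  fit <- fit_iris(pts)
  ang <- acos(min(1, abs(fit$normal[3])))
  expect_equal(ang, 20 * pi / 180, tolerance = 1e-9)
  expect_error(fit_iris(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear|degenerate")
})

test_that("noisy iris fits recover the radius within 10 um on average", {
  errs <- vapply(1:100, function(s) {
    pts <- circle_points(400, radius = 5.5, noise = 0.01, seed = s)
    fit_iris(pts)$radius - 5.5
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.01)
})

test_that("initial alignment is the identity for an aligned model and centres the iris", {
  pts <- circle_points(100, centre = c(0, 0, 0))
  al <- initial_align(tibble::as_tibble(as.data.frame(pts)) |>
                        rlang::set_names(c("x", "y", "z")))
  expect_equal(al$transform$R, diag(3), tolerance = 1e-9)
  expect_equal(al$transform$t, c(0, 0, 0), tolerance = 1e-9)
  # a translated, tilted iris lands its centre at the origin
  Rt <- lensrecon:::rotation_about_axis(c(0, 1, 0), 0.4)
  pts2 <- circle_points(100, centre = c(1, -2, 3), tilt = Rt)
  al2 <- initial_align(tibble::tibble(x = pts2[, 1], y = pts2[, 2],
                                      z = pts2[, 3]))
  moved <- apply_transform(al2$transform, matrix(al2$iris_fit$centre, 1))
  expect_lt(max(abs(moved)), 1e-9)
})

test_that("a known 30 degree gaze rotation is recovered within 0.1 degree", {
  models <- fx_models_all()
  labs <- vapply(models, function(m) m$incidence, character(1))
  m30 <- models[[which(labs == "nasal_30")]]
  al <- initial_align(m30)
  expect_equal(tidy(al$transform)$angle_deg, 30, tolerance = 0.1 / 30)
  m45 <- models[[which(labs == "temporal_45")]]
  expect_equal(tidy(initial_align(m45)$transform)$angle_deg, 45,
               tolerance = 0.1 / 45)
})

test_that("ICP recovers a constructed rigid motion and decreases trimmed MSE", {
  cl <- withr::with_seed(5, matrix(rnorm(3000), 1000, 3))
  expect_identical_cloud <- icp_refine(cl, cl, gate_mm = 5)
  expect_lt(attr(expect_identical_cloud, "rms"), 1e-12)
  expect_equal(expect_identical_cloud$R, diag(3), tolerance = 1e-9)

  tf0 <- rigid_transform(lensrecon:::rotation_about_axis(c(0, 0.3, 1),
                                                         5 * pi / 180),
                         c(0.2, -0.1, 0.05))
  src <- apply_transform(invert_transform(tf0), cl)
  tf <- icp_refine(src, cl, gate_mm = 5)
  expect_lt(lensrecon:::rotation_angle(tf$R %*% t(tf0$R)), 1e-6)
  expect_lt(max(abs(tf$t - tf0$t)), 1e-6)
  h <- attr(tf, "history")$mse
  expect_true(all(diff(h) <= 1e-12))
  # no overlap within the gate errors out
  expect_error(icp_refine(cl, cl + 100, gate_mm = 0.5), "overlap")
})

test_that("all returned rotations are orthonormal with det +1", {
  reg <- fx_registration()
  for (tf in reg$transforms) {
    expect_lt(max(abs(crossprod(tf$R) - diag(3))), 1e-10)
    expect_equal(det(tf$R), 1, tolerance = 1e-10)
  }
})

test_that("eight registered incidences land on the phantom to within 10 um RMS", {
  reg <- fx_registration()
  err <- merged_lens_axial_error_mm(reg$merged, fx_phantom())
  expect_lt(sqrt(mean(err^2)) * 1000, 10)
  # redundancy audit: overlapping incidences agree pairwise
  expect_gt(nrow(reg$overlap), 20)
  expect_true(all(reg$overlap$rms_mm < 0.3))
})

test_that("a single on-axis model registers to its initial alignment", {
  models <- fx_models_all()
  labs <- vapply(models, function(m) m$incidence, character(1))
  m0 <- models[[which(labs == "on_axis")]]
  reg1 <- register_all(list(m0))
  al <- initial_align(m0)
  expect_equal(reg1$transforms[["on_axis"]]$R, al$transform$R,
               tolerance = 1e-12)
  expect_equal(nrow(reg1$merged), nrow(m0$points))
})

test_that("registration is equivariant under a common rigid motion", {
  models <- fx_models_all()
  labs <- vapply(models, function(m) m$incidence, character(1))
  pick <- models[labs %in% c("on_axis", "nasal_30", "temporal_30")]
  reg_a <- register_all(pick)
  tf <- rigid_transform(lensrecon:::rotation_about_axis(c(1, 1, 0), 0.15),
                        c(0.4, -0.2, 0.6))
  moved <- lapply(pick, function(m) {
    m$points <- apply_transform(tf, m$points)
    m$iris <- apply_transform(tf, m$iris)
    m
  })
  reg_b <- register_all(moved)
  # the merged shapes agree: iris alignment undoes the common motion
  a <- as.matrix(reg_a$merged[reg_a$merged$surface == "LP", c("x", "y", "z")])
  b <- as.matrix(reg_b$merged[reg_b$merged$surface == "LP", c("x", "y", "z")])
  nn <- lensrecon:::nearest_neighbour(lensrecon:::subsample_rows(a, 500), b)
  expect_lt(sqrt(mean(nn$dist^2)), 0.02)
})
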