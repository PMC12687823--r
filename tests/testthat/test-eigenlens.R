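test_that("lens alignment finds the shape origin of symmetric clouds", {
  # sphere: origin at the sphere centre
  g <- sphere_grid(4.6)
  cloud <- lensrecon:::polar_grid_points(g)
  cloud$surface <- ifelse(cloud$z <= 0, "LA", "LP")
  al <- align_lens(cloud)
  expect_lt(max(abs(al$origin)), 1e-3)
  # a pre-centred lens shifts by (almost) nothing
  ph <- fx_phantom()
  g2 <- phantom_lens_grid(ph)
  cl2 <- lensrecon:::polar_grid_points(g2)
  cl2$surface <- ifelse(cl2$z <= 0, "LA", "LP")
  al2 <- align_lens(cl2)
  expect_lt(max(abs(al2$origin[1:2])), 1e-3)
  expect_lt(abs(al2$origin[3]), 2e-3)
  # a constructed +0.3 mm lateral decentration is recovered
  cl3 <- dplyr::mutate(cl2, x = x + 0.3)
  al3 <- align_lens(cl3)
  expect_equal(al3$origin[1], 0.3, tolerance = 0.02)
})

test_that("polar resampling reproduces spheres and ellipsoids", {
  # dense analytic ellipsoid cloud (a, a, b)
  a <- 4.6; b <- 2.1
  th <- seq(0.001, pi - 0.001, length.out = 260)
  phh <- seq(0, 2 * pi, length.out = 420)[-1]
  gr <- expand.grid(theta = th, phi = phh)
  den <- sqrt((sin(gr$theta)^2) / a^2 + (cos(gr$theta)^2) / b^2)
  rho <- 1 / den
  cloud <- tibble::tibble(x = rho * sin(gr$theta) * cos(gr$phi),
                          y = rho * sin(gr$theta) * sin(gr$phi),
                          z = -rho * cos(gr$theta))
  g <- to_polar_grid(cloud, max_points = 200000)
  I_true <- outer(g$theta, g$phi,
                  function(t, p) 1 / sqrt(sin(t)^2 / a^2 + cos(t)^2 / b^2))
  obs <- !is.na(g$I)
  expect_gt(mean(obs), 0.97)
  expect_lt(max(abs(g$I - I_true)[obs]), 1e-4)

  # sphere: all radii equal
  cs <- cloud
  rs <- sqrt(cs$x^2 + cs$y^2 + cs$z^2)
  cs <- dplyr::mutate(cs, x = x / rs * 3, y = y / rs * 3, z = z / rs * 3)
  gs <- to_polar_grid(cs, max_points = 200000)
  expect_lt(max(abs(gs$I - 3), na.rm = TRUE), 1e-6)
})

test_that("an equatorial acquisition gap maps to a confined missing band", {
  g <- phantom_lens_grid(fx_phantom())
  cloud <- lensrecon:::polar_grid_points(g)
  keep <- !(cloud$theta > 1.35 & cloud$theta < 1.75)
  gg <- to_polar_grid(cloud[keep, ], max_points = 200000)
  miss <- which(is.na(gg$I), arr.ind = TRUE)
  expect_gt(nrow(miss), 0)
  th_miss <- gg$theta[miss[, 1]]
  expect_true(all(th_miss > 1.2 & th_miss < 1.9))
})

test_that("a degenerate training population gives the mean lens and zero eigenvalues", {
  g <- phantom_lens_grid(fx_phantom(), P = 40, Q = 40)
  training <- rep(list(g), 10)
  b <- build_basis(training, K = 3)
  expect_equal(b$mean, as.vector(g$I), tolerance = 1e-12)
  expect_lt(max(b$eigenvalues), 1e-20)
  expect_error(build_basis(training[1:3], K = 3), "training lenses")
})

test_that("a two-parameter family concentrates variance in two components", {
  lenses <- withr::with_seed(77, lapply(1:24, function(i)
    phantom_lens_grid(make_phantom("young_adult",
                                   lens_dia = runif(1, 8.5, 10),
                                   lens_thickness = runif(1, 3.4, 4.6)),
                      P = 50, Q = 50)))
  b <- build_basis(lenses, K = 6)
  expect_gt(sum(b$all_eigenvalues[1:2]) / sum(b$all_eigenvalues), 0.99)
})

test_that("held-out reconstruction error decreases with K", {
  training <- training_lens_family(n = 40, P = 50, Q = 50, seed = 314)
  held <- phantom_lens_grid(make_phantom("young_adult", lens_dia = 9.4,
                                         lens_thickness = 4.0), P = 50, Q = 50)
  errs <- vapply(1:6, function(k) {
    b <- build_basis(training, K = k)
    rec <- reconstruct_lens(project_lens(held, b), b)
    sqrt(mean((rec$I - held$I)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-12))
})

test_that("projection algebra: mean lens, basis vectors, idempotence, Pythagoras", {
  b <- fx_basis()
  M <- b$P * b$Q
  # I = mean -> a = 0 -> reconstruct returns the mean
  g_mean <- lensrecon:::new_lens_polar_grid(matrix(b$mean, b$P, b$Q), b$P, b$Q)
  a0 <- project_lens(g_mean, b)
  expect_lt(max(abs(a0$a)), 1e-10)
  expect_equal(as.vector(reconstruct_lens(a0, b)$I), b$mean, tolerance = 1e-12)
  # I = mean + 0.5 e3 -> a = (0, 0, 0.5, 0, 0, 0)
  g3 <- lensrecon:::new_lens_polar_grid(
    matrix(b$mean + 0.5 * b$basis[, 3], b$P, b$Q), b$P, b$Q)
  a3 <- project_lens(g3, b)
  expect_equal(a3$a, c(0, 0, 0.5, 0, 0, 0), tolerance = 1e-10)
  # arbitrary lens: coefficients equal per-component inner products
  g_arb <- phantom_lens_grid(make_phantom("young_adult", lens_dia = 9.0,
                                          lens_thickness = 3.6))
  a_arb <- project_lens(g_arb, b)
  r <- as.vector(g_arb$I) - b$mean
  brute <- vapply(1:6, function(k) sum(b$basis[, k] * r), numeric(1))
  expect_equal(a_arb$a, brute, tolerance = 1e-10)
  # project(reconstruct(a)) == a and double application equals single
  rec <- reconstruct_lens(a_arb, b)
  a_again <- project_lens(rec, b)
  expect_equal(a_again$a, a_arb$a, tolerance = 1e-10)
  # Pythagoras: |r|^2 = |r - Ma|^2 + |Ma|^2 for the orthogonal projector
  fitted <- as.numeric(b$basis %*% a_arb$a)
  expect_equal(sum(r^2), sum((r - fitted)^2) + sum(fitted^2),
               tolerance = 1e-8)
  # span membership: a lens reconstructed from the basis reprojects exactly
  expect_lt(sqrt(mean((reconstruct_lens(a_again, b)$I - rec$I)^2)), 1e-12)
  expect_error(reconstruct_lens(c(1, 2), b), "length")
})

test_that("basis columns are orthonormal and eigenvalues ordered", {
  b <- fx_basis()
  expect_lt(max(abs(crossprod(b$basis) - diag(6))), 1e-10)
  expect_true(all(diff(b$eigenvalues) <= 0))
  expect_equal(glance(b)$M, 10000)
})

test_that("projection smooths iid node noise by roughly sqrt(K / M)", {
  b <- fx_basis()
  g <- reconstruct_lens(c(1, -0.5, 0.3, 0.2, -0.1, 0.05), b)  # span member
  sigma <- 0.02
  errs <- vapply(1:100, function(s) {
    noisy <- g
    noisy$I <- g$I + withr::with_seed(1000 + s,
                                      matrix(rnorm(10000, 0, sigma), 100, 100))
    rec <- reconstruct_lens(project_lens(noisy, b), b)
    sqrt(mean((rec$I - g$I)^2))
  }, numeric(1))
  expect_lt(mean(errs), 3 * sigma * sqrt(6 / 10000))
})

test_that("missing-node projection completes the shape from partial data", {
  b <- fx_basis()
  g <- phantom_lens_grid(fx_phantom())
  full <- lens_metrics(reconstruct_lens(project_lens(g, b), b))
  gm <- g
  gm$I[36:65, ] <- NA  # 30 % equatorial gap
  co <- project_lens(gm, b)
  expect_equal(co$n_observed, 7000)
  rec <- reconstruct_lens(co, b)
  expect_false(anyNA(rec$I))
  gap <- lens_metrics(rec)
  expect_lt(abs(gap$dia_mm - full$dia_mm) / full$dia_mm, 0.02)
})

test_that("the basis serializes with a checksum and round-trips", {
  b <- build_basis(training_lens_family(n = 12, P = 30, Q = 30, seed = 2), K = 4)
  td <- withr::local_tempdir()
  f <- file.path(td, "basis.json")
  write_basis(b, f)
  b2 <- read_basis(f)
  expect_equal(b2$basis, b$basis, tolerance = 1e-12)
  expect_equal(b2$mean, b$mean, tolerance = 1e-12)
  # corrupting the payload breaks the checksum
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  j$mean[1] <- j$mean[1] + 1
  jsonlite::write_json(j, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_basis(f), "checksum")
})
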