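# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fx_phantom <- function() memo("phantom", make_phantom("young_adult"))

fx_protocol <- function(noise_sd_px = 0, rng_seed = 1L) {
  acquisition_protocol(noise_sd_px = noise_sd_px, rng_seed = rng_seed)
}

# coarser protocol for structural tests (keeps the [0, pi) span)
fx_protocol_small <- function(noise_sd_px = 0, rng_seed = 1L) {
  acquisition_protocol(n_meridians = 33, meridian_step = 0.096,
                       n_ascans = 128, noise_sd_px = noise_sd_px,
                       rng_seed = rng_seed)
}

fx_sim_onaxis <- function() memo("sim_onaxis", {
  forward_simulate(fx_phantom(), fx_protocol(), "on_axis")
})

fx_corrected_onaxis <- function() memo("corrected_onaxis", {
  cfg <- default_config()
  correct_model(eye_model_from_meridians(fx_sim_onaxis(), config = cfg),
                media = cfg$media)
})

fx_sim_all <- function() memo("sim_all", {
  simulate_protocol(fx_phantom(), fx_protocol())
})

fx_models_all <- function() memo("models_all", {
  cfg <- default_config()
  mer <- fx_sim_all()
  lapply(unique(mer$incidence), function(lb)
    correct_model(eye_model_from_meridians(
      mer[mer$incidence == lb, ], config = cfg),
      media = cfg$media))
})

fx_registration <- function() memo("registration", {
  register_all(fx_models_all(), icp = default_config()$icp)
})

fx_basis <- function() memo("basis", {
  build_basis(training_lens_family(n = 80), K = 6)
})

# distance of registered lens points to the analytic phantom surfaces, in the
# registered frame (iris centre at the origin); axial gap only, inner region
merged_lens_axial_error_mm <- function(merged, ph, r_max = 4.3) {
  p <- merged[merged$surface %in% c("LA", "LP"), ]
  r <- sqrt(p$x^2 + p$y^2)
  zsh <- ph$iris_z
  sag <- lensrecon:::conicoid_sag
  za <- ph$lens_ant$apex_z - zsh + sag(ph$lens_ant, r)
  zp <- ph$lens_post$apex_z - zsh + sag(ph$lens_post, r)
  err <- ifelse(p$surface == "LA", p$z - za, p$z - zp)
  err[r < r_max & !is.na(err)]
}

# analytic radial grid of a sphere
sphere_grid <- function(R, P = 100, Q = 100) {
  lensrecon:::new_lens_polar_grid(matrix(R, P, Q), P, Q)
}

# uniform random points on a disc
disc_points <- function(n = 600, radius = 4, seed = 11) {
  withr::with_seed(seed, {
    r <- radius * sqrt(runif(n))
    a <- runif(n, 0, 2 * pi)
    tibble::tibble(x = r * cos(a), y = r * sin(a))
  })
}

# agreement of a computed CV with its printed two-decimal value: the print
# may round or truncate, so accept either reading of the last digit
expect_cv_printed <- function(values, printed) {
  cv <- coefficient_of_variation(values)
  ok <- isTRUE(all.equal(round(cv, 2), printed)) ||
    isTRUE(all.equal(trunc(cv * 100) / 100, printed))
  expect_true(ok, label = sprintf("CV %.4f matches printed %.2f", cv, printed))
}
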