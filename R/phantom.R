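#' Build a synthetic eye phantom
#'
#' Constructs an analytic anterior-segment phantom: conicoid anterior and
#' posterior corneal surfaces, a crystalline lens made of two conicoid caps
#' meeting at a closed equatorial contour, and a flat iris annulus. The
#' phantom is the ground truth against which the whole reconstruction
#' pipeline is exercised: its equatorial diameter, volume and surface area
#' are available in closed form or by fine quadrature.
#'
#' By default the lens is built from `lens_dia`, `lens_thickness` and
#' `lens_split` (the anterior share of the thickness) as two vertical-tangent
#' conicoid caps, giving a closed shape that is C1-smooth at the equator as
#' in vivo lenses are; apex radii and conic constants are then derived.
#' Alternatively explicit cap geometry may be given: `lens_radius_ant` /
#' `lens_radius_post` with conic constants (thickness or diameter is then
#' derived from the cap intersection), or radii with `lens_dia` plus
#' `lens_thickness`, in which case a shared conic-constant offset is solved
#' so the caps intersect exactly at the requested diameter.
#'
#' @param preset `"young_adult"` (default geometry of a dilated young adult
#'   eye) or `"spherical"` (lens is a full sphere, radius `lens_dia / 2`), or
#'   `NULL` to use the explicit parameters only.
#' @param ... named overrides of any geometry field (see Details).
#' @returns An object of class `phantom_eye`.
#' @examples
#' ph <- make_phantom("young_adult")
#' phantom_truth(ph)
#' @export
make_phantom <- function(preset = "young_adult", ...) {
  base <- list(
    cornea_radius_ant = 7.8, cornea_conic_ant = -0.24, cornea_apex_z = 0,
    cornea_radius_post = 6.5, cornea_conic_post = -0.1, cornea_thickness = 0.55,
    cornea_r_max = 6.0,
    lens_radius_ant = NULL, lens_radius_post = NULL,
    lens_conic_ant = NULL, lens_conic_post = NULL,
    lens_dia = 9.2, lens_thickness = 3.8, lens_split = 0.45,
    lens_apex_z = 3.6,
    iris_z = 3.5, pupil_radius = 3.6, iris_outer_radius = 5.9,
    media = optical_media()
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("young_adult", "spherical"))
    if (preset == "spherical") {
      base$lens_thickness <- 9.2
      base$lens_split <- 0.5
    }
  }
  user <- list(...)
  unknown <- setdiff(names(user), names(base))
  assert_that(length(unknown) == 0,
              paste("unknown phantom parameters:", paste(unknown, collapse = ", ")))
  p <- utils::modifyList(base, user, keep.null = TRUE)
  if (!is.null(preset) && preset == "spherical" && is.null(user$lens_thickness) &&
      !is.null(user$lens_dia)) {
    p$lens_thickness <- p$lens_dia
  }
  build_phantom(p)
}

build_phantom <- function(p) {
  for (f in c("cornea_radius_ant", "cornea_radius_post", "lens_radius_ant",
              "lens_radius_post", "pupil_radius", "iris_outer_radius")) {
    if (!is.null(p[[f]])) {
      assert_that(p[[f]] > 0, paste("phantom field", f, "must be positive"))
    }
  }
  have_conics <- !is.null(p$lens_conic_ant) && !is.null(p$lens_conic_post)
  have_radii <- !is.null(p$lens_radius_ant) && !is.null(p$lens_radius_post)
  if (!have_radii) {
    # default construction: vertical-tangent (ellipsoidal) conicoid caps,
    # C1-smooth at the equator like the in vivo lens; the split fraction
    # apportions the thickness between anterior and posterior semi-axes
    assert_that(!is.null(p$lens_dia) && !is.null(p$lens_thickness) &&
                  !is.null(p$lens_split),
                "give lens_dia, lens_thickness and lens_split, or explicit cap radii")
    assert_that(p$lens_split > 0 && p$lens_split < 1,
                "lens_split must lie in (0, 1)")
    re <- p$lens_dia / 2
    A <- p$lens_split * p$lens_thickness
    B <- (1 - p$lens_split) * p$lens_thickness
    p$lens_radius_ant <- re^2 / A
    p$lens_conic_ant <- re^2 / A^2 - 1
    p$lens_radius_post <- re^2 / B
    p$lens_conic_post <- re^2 / B^2 - 1
  } else if (have_conics) {
    if (is.null(p$lens_thickness)) {
      assert_that(!is.null(p$lens_dia), "give lens_dia or lens_thickness")
      re <- p$lens_dia / 2
      sa <- conicoid_sag(conicoid(p$lens_radius_ant, p$lens_conic_ant, 0, re), re)
      sp <- conicoid_sag(conicoid(-p$lens_radius_post, p$lens_conic_post, 0, re), re)
      assert_that(is.finite(sa) && is.finite(sp),
                  "invalid lens geometry: caps do not reach the requested equator")
      p$lens_thickness <- sa - sp
    } else if (is.null(p$lens_dia)) {
      # equator where the sag gap closes
      f <- function(r) {
        sa <- conicoid_sag(conicoid(p$lens_radius_ant, p$lens_conic_ant, 0, r + 1), r)
        sp <- conicoid_sag(conicoid(-p$lens_radius_post, p$lens_conic_post, 0, r + 1), r)
        if (is.na(sa) || is.na(sp)) return(NA_real_)
        sa - sp - p$lens_thickness
      }
      r_hi <- min(
        p$lens_radius_ant / sqrt(max(1 + p$lens_conic_ant, 1e-12)),
        p$lens_radius_post / sqrt(max(1 + p$lens_conic_post, 1e-12)),
        p$lens_radius_ant + p$lens_radius_post)
      grid <- seq(1e-3, r_hi, length.out = 400)
      vals <- vapply(grid, f, numeric(1))
      ok <- which(!is.na(vals) & vals >= -1e-9)
      assert_that(length(ok) > 0,
                  "invalid lens geometry: cap surfaces do not intersect")
      i <- ok[1]
      re <- if (i == 1 || abs(vals[i]) <= 1e-9) grid[i] else
        uniroot(f, c(grid[i - 1], grid[i]), tol = 1e-12)$root
      p$lens_dia <- 2 * re
    }
  } else {
    assert_that(!is.null(p$lens_dia) && !is.null(p$lens_thickness),
                "give lens_dia and lens_thickness, or explicit lens conics")
    ks <- solve_cap_conics(p$lens_dia / 2, p$lens_thickness,
                           p$lens_radius_ant, p$lens_radius_post)
    p$lens_conic_ant <- unname(ks["k_ant"])
    p$lens_conic_post <- unname(ks["k_post"])
  }
  re <- p$lens_dia / 2
  assert_that(p$lens_dia > 2 * p$pupil_radius,
              "lens equatorial diameter must exceed the pupil diameter")
  ph <- structure(list(
    cornea_ant = conicoid(p$cornea_radius_ant, p$cornea_conic_ant,
                          p$cornea_apex_z, p$cornea_r_max),
    cornea_post = conicoid(p$cornea_radius_post, p$cornea_conic_post,
                           p$cornea_apex_z + p$cornea_thickness,
                           p$cornea_r_max * 0.97),
    lens_ant = conicoid(p$lens_radius_ant, p$lens_conic_ant, p$lens_apex_z, re),
    lens_post = conicoid(-p$lens_radius_post, p$lens_conic_post,
                         p$lens_apex_z + p$lens_thickness, re),
    lens_thickness = p$lens_thickness,
    lens_dia = p$lens_dia,
    lens_apex_z = p$lens_apex_z,
    iris_z = p$iris_z, pupil_radius = p$pupil_radius,
    iris_outer_radius = p$iris_outer_radius,
    media = p$media,
    params = p
  ), class = "phantom_eye")
  check_phantom(ph)
  ph
}

# Lens profile about the volumetric centre must be star-convex: the polar
# angle along the meridional profile must be strictly monotone.
check_phantom <- function(ph) {
  prof <- lens_profile(ph, n = 400)
  ctr <- lens_centre(ph)
  ang <- atan2(prof$r, -(prof$z - ctr[3]))
  assert_that(all(diff(ang) > 0),
              "invalid lens geometry: profile is not star-convex about its centre")
  assert_that(ph$lens_dia / 2 > 0, "lens equatorial radius must be positive")
  invisible(ph)
}

# Meridional profile of the lens, anterior pole -> equator -> posterior pole.
# Returns tibble(r, z) in the phantom frame (n points per cap).
lens_profile <- function(ph, n = 200) {
  re <- ph$lens_dia / 2
  # parameterize by angle for even coverage near the equator
  u <- seq(0, pi / 2, length.out = n)
  r_a <- re * sin(u)
  z_a <- ph$lens_apex_z + conicoid_sag(ph$lens_ant, r_a)
  r_p <- re * sin(rev(u[-n]))
  z_p <- ph$lens_apex_z + ph$lens_thickness + conicoid_sag(ph$lens_post, r_p)
  tibble::tibble(r = c(r_a, r_p), z = c(z_a, z_p))
}

# Axial centre of the lens volume (on the axis of symmetry).
lens_centre <- function(ph) {
  c(0, 0, ph$lens_apex_z + ph$lens_thickness / 2)
}

#' Ground-truth lens morphometry of a phantom
#'
#' Computes the equatorial diameter, volume and surface area of the phantom's
#' analytic lens by fine one-dimensional quadrature on the surface-of-
#' revolution profile (the lens caps are conicoids of revolution, so both
#' integrals reduce to 1-D).
#'
#' @param ph a [make_phantom()] object.
#' @param n quadrature panels per cap.
#' @returns A tibble with `dia_mm`, `vol_mm3`, `lsa_mm2`.
#' @export
phantom_truth <- function(ph, n = 20000) {
  re <- ph$lens_dia / 2
  u <- seq(0, pi / 2, length.out = n)
  r <- re * sin(u)
  vol <- 0
  lsa <- 0
  z0 <- ph$lens_apex_z
  zT <- ph$lens_apex_z + ph$lens_thickness
  za <- z0 + conicoid_sag(ph$lens_ant, r)
  zp <- zT + conicoid_sag(ph$lens_post, r)
  # volume between the caps
  vol <- trapz(r, 2 * pi * r * (zp - za))
  # area as a surface of revolution, parameterized by the rim angle u so the
  # vertical tangent at a spherical rim is integrable
  for (zz in list(za, zp)) {
    ds <- sqrt(diff(r)^2 + diff(zz)^2)
    r_mid <- (r[-1] + r[-n]) / 2
    lsa <- lsa + sum(2 * pi * r_mid * ds)
  }
  tibble::tibble(dia_mm = ph$lens_dia, vol_mm3 = vol, lsa_mm2 = lsa)
}

# Voxel-grid volume oracle used by tests: counts centres of a fine grid that
# fall between the caps.
phantom_volume_voxel <- function(ph, n_cells = 100) {
  re <- ph$lens_dia / 2
  z0 <- ph$lens_apex_z
  zT <- z0 + ph$lens_thickness
  xs <- seq(-re, re, length.out = n_cells)
  zs <- seq(min(z0, zT) - 0.2, max(z0, zT) + 0.2, length.out = n_cells)
  dx <- xs[2] - xs[1]
  dz <- zs[2] - zs[1]
  g <- expand.grid(x = xs, y = xs)
  r <- sqrt(g$x^2 + g$y^2)
  inside_disc <- r <= re
  za <- z0 + conicoid_sag(ph$lens_ant, r)
  zp <- zT + conicoid_sag(ph$lens_post, r)
  count <- 0
  for (z in zs) {
    count <- count + sum(inside_disc & !is.na(za) & !is.na(zp) & z >= za & z <= zp)
  }
  count * dx * dx * dz
}

#' @export
print.phantom_eye <- function(x, ...) {
  cat("<phantom_eye>\n")
  cat(sprintf("  lens: DIA %.3f mm, thickness %.3f mm, caps R %.2f / %.2f mm (K %.3f / %.3f)\n",
              x$lens_dia, x$lens_thickness, x$lens_ant$radius,
              -x$lens_post$radius, x$lens_ant$conic, x$lens_post$conic))
  cat(sprintf("  cornea: R %.2f / %.2f mm, thickness %.2f mm\n",
              x$cornea_ant$radius, x$cornea_post$radius,
              x$cornea_post$apex_z - x$cornea_ant$apex_z))
  cat(sprintf("  iris: plane z %.2f mm, pupil radius %.2f mm\n",
              x$iris_z, x$pupil_radius))
  invisible(x)
}

#' Refractive media of the eye model
#'
#' Group refractive indices used both by the forward simulator and by the
#' distortion correction: 1.385 for the cornea, 1.345 for the aqueous and
#' 1.417 for the crystalline lens, with air at 1.
#'
#' @param n_air,n_cornea,n_aqueous,n_lens group indices (dimensionless).
#' @returns A named list of class `optical_media`.
#' @export
optical_media <- function(n_air = 1.0, n_cornea = 1.385, n_aqueous = 1.345,
                          n_lens = 1.417) {
  vals <- c(n_air, n_cornea, n_aqueous, n_lens)
  assert_that(all(vals >= 1), "refractive indices must be >= 1")
  structure(list(n_air = n_air, n_cornea = n_cornea, n_aqueous = n_aqueous,
                 n_lens = n_lens), class = "optical_media")
}

#' Export a phantom as JSON geometry plus an ASCII PLY mesh
#'
#' @param ph phantom.
#' @param path_json,path_ply output paths (either may be `NULL` to skip).
#' @param n_theta,n_phi mesh sampling of the lens surface.
#' @returns Invisibly, the written file paths.
#' @export
write_phantom <- function(ph, path_json = NULL, path_ply = NULL,
                          n_theta = 60, n_phi = 60) {
  if (!is.null(path_json)) {
    keep <- ph$params[!vapply(ph$params, is.null, logical(1))]
    keep$media <- unclass(keep$media)
    jsonlite::write_json(keep, path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_ply)) {
    grid <- phantom_lens_grid(ph, P = n_theta, Q = n_phi)
    mesh <- polar_grid_mesh(grid)
    write_ply(mesh$vertices, mesh$faces, path_ply)
  }
  invisible(c(path_json, path_ply))
}

#' Analytic polar-grid sampling of a phantom lens
#'
#' Samples the phantom's lens surface about its volumetric centre on the
#' eigenlens polar grid (elevation measured from the anterior pole), without
#' any simulation or reconstruction: the exact radial elevations of the
#' analytic shape. Used as ground truth for the grid-based morphometry and
#' to build training populations.
#'
#' @param ph a [make_phantom()] object.
#' @param P,Q grid dimensions.
#' @returns A complete `lens_polar_grid`.
#' @export
phantom_lens_grid <- function(ph, P = 100, Q = 100) {
  prof_radius <- phantom_radial_profile(ph, P)
  I <- matrix(rep(prof_radius, Q), nrow = P)
  new_lens_polar_grid(I, P = P, Q = Q, origin = lens_centre(ph))
}

# Radial distance from the lens centre along each elevation angle theta in
# [0, pi] (theta = 0 towards the instrument / anterior pole).
phantom_radial_profile <- function(ph, P = 100) {
  ctr <- lens_centre(ph)
  theta <- seq(0, pi, length.out = P)
  z0 <- ph$lens_apex_z
  zT <- z0 + ph$lens_thickness
  re <- ph$lens_dia / 2
  vapply(theta, function(th) {
    d <- c(sin(th), -cos(th))  # (r, z) direction from centre
    # positive inside the lens, negative outside; continuous across the
    # boundary, so the first crossing is the radial elevation
    f <- function(rho) {
      r <- rho * d[1]
      z <- ctr[3] + rho * d[2]
      if (r > re) return(-1)
      za <- z0 + conicoid_sag(ph$lens_ant, r)
      zp <- zT + conicoid_sag(ph$lens_post, r)
      if (is.na(za) || is.na(zp)) return(-1)
      min(z - za, zp - z)
    }
    uniroot(f, c(1e-9, ph$lens_dia), tol = 1e-12)$root
  }, numeric(1))
}
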