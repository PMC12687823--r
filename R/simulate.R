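#' Multi-incidence OCT acquisition protocol
#'
#' Describes the radial scan pattern and the set of gaze orientations under
#' which the eye is imaged: on-axis plus nasal 30/45 deg, temporal 30/45 deg,
#' superior 20/30 deg and inferior 45 deg, i.e. eight incidences in total.
#' Each volumetric acquisition consists of 65 meridional B-scans at 0.048 rad
#' angular spacing with 256 A-scans over a 14 mm lateral range; axial pixels
#' are 9.2 um.
#'
#' @param orientations tibble with columns `label`, `axis` (`"x"` or `"y"`),
#'   `angle_deg`; defaults to the eight-orientation protocol.
#' @param n_meridians,meridian_step,n_ascans,lateral_range,axial_scale scan
#'   geometry (counts, rad, count, mm, um/pixel).
#' @param noise_sd_px axial Gaussian noise SD, in pixels.
#' @param rng_seed integer seed controlling the simulated noise.
#' @returns A list of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(orientations = default_orientations(),
                                 n_meridians = 65, meridian_step = 0.048,
                                 n_ascans = 256, lateral_range = 14,
                                 axial_scale = 9.2, noise_sd_px = 0,
                                 rng_seed = 1L) {
  assert_that(noise_sd_px >= 0, "noise_sd_px must be >= 0")
  span <- n_meridians * meridian_step
  assert_that(span > pi * 0.9 && span < pi * 1.1,
              "n_meridians x meridian_step must span approximately [0, pi)")
  structure(list(orientations = orientations, n_meridians = n_meridians,
                 meridian_step = meridian_step, n_ascans = n_ascans,
                 lateral_range = lateral_range, axial_scale = axial_scale,
                 noise_sd_px = noise_sd_px, rng_seed = as.integer(rng_seed)),
            class = "acquisition_protocol")
}

#' @rdname acquisition_protocol
#' @export
default_orientations <- function() {
  tibble::tibble(
    label = c("on_axis", "nasal_30", "nasal_45", "temporal_30", "temporal_45",
              "superior_20", "superior_30", "inferior_45"),
    axis = c("y", "y", "y", "y", "y", "x", "x", "x"),
    angle_deg = c(0, 30, 45, -30, -45, 20, 30, -45))
}

# Gaze rotation of the whole eye about the iris-circle centre (rigid, no
# cyclotorsion). Returns the 3x3 rotation in the instrument frame.
gaze_rotation <- function(axis, angle_deg) {
  u <- if (axis == "x") c(1, 0, 0) else c(0, 1, 0)
  rotation_about_axis(u, angle_deg * pi / 180)
}

#' Forward-simulate one distorted OCT acquisition of a phantom
#'
#' Rotates the phantom rigidly about its iris-circle centre by the gaze angle
#' of `orientation`, then traces one telecentric ray per A-scan per meridian.
#' At every interface the ray is refracted by the vector form of Snell's law
#' and the optical path length (geometric segment times the group index of the
#' medium) is accumulated; each surface crossing is recorded at the A-scan's
#' lateral pixel and at an axial pixel equal to the cumulative OPL divided by
#' the axial scale. Lens samples blocked by the iris annulus are flagged
#' missing, as are rays that miss a surface. Gaussian axial pixel noise is
#' added to non-missing samples.
#'
#' @param phantom a [make_phantom()] object.
#' @param protocol an [acquisition_protocol()].
#' @param orientation a gaze label present in `protocol$orientations`.
#' @returns A tibble with columns `incidence`, `meridian_index`,
#'   `meridian_angle`, `direction`, `ascan_index`, `surface`, `x_px`, `z_px`,
#'   `missing` (one row per meridian x A-scan x surface). The attribute
#'   `"tir_dropped"` counts samples lost to total internal reflection.
#' @export
forward_simulate <- function(phantom, protocol, orientation) {
  ori <- protocol$orientations[protocol$orientations$label == orientation, ]
  assert_that(nrow(ori) == 1,
              paste0("orientation '", orientation, "' is not in the protocol"))
  Rg <- gaze_rotation(ori$axis, ori$angle_deg)
  ctr <- c(0, 0, phantom$iris_z)

  nM <- protocol$n_meridians
  nA <- protocol$n_ascans
  pitch <- protocol$lateral_range / nA
  centre_idx <- (nA - 1) / 2
  mer <- rep(seq_len(nM) - 1L, each = nA)
  asc <- rep(seq_len(nA) - 1L, times = nM)
  ang <- mer * protocol$meridian_step
  lat <- (asc - centre_idx) * pitch
  n <- length(mer)

  # rays in the instrument frame: origin on the z = z0 reference, axial dir
  z0 <- -5
  o_w <- cbind(lat * cos(ang), lat * sin(ang), z0)
  d_w <- cbind(rep(0, n), 0, 1)
  # transform into the (un-rotated) phantom frame
  o_p <- sweep((o_w - matrix(ctr, n, 3, byrow = TRUE)) %*% Rg, 2, ctr, "+")
  d_p <- d_w %*% Rg

  med <- phantom$media
  z_app <- matrix(NA_real_, n, 5,
                  dimnames = list(NULL, SURFACE_LABELS))
  tir_dropped <- 0L

  # --- anterior cornea (air) ---
  hit <- conicoid_intersect(phantom$cornea_ant, o_p, d_p)
  ok <- !is.na(hit$t)
  z_app[ok, "CA"] <- z0 + med$n_air * hit$t[ok]
  nrm <- conicoid_normal(phantom$cornea_ant, hit$point)
  d2 <- snell_refract_3d(d_p, nrm, med$n_air, med$n_cornea)
  tir <- ok & is.na(d2[, 1])
  tir_dropped <- tir_dropped + sum(tir)
  alive <- ok & !is.na(d2[, 1])

  # --- posterior cornea ---
  p1 <- hit$point
  hit2 <- conicoid_intersect(phantom$cornea_post, p1, d2)
  ok2 <- alive & !is.na(hit2$t)
  z_app[ok2, "CP"] <- z_app[ok2, "CA"] + med$n_cornea * hit2$t[ok2]
  nrm2 <- conicoid_normal(phantom$cornea_post, hit2$point)
  d3 <- snell_refract_3d(d2, nrm2, med$n_cornea, med$n_aqueous)
  tir <- ok2 & is.na(d3[, 1])
  tir_dropped <- tir_dropped + sum(tir)
  alive2 <- ok2 & !is.na(d3[, 1])

  # --- iris plane crossing (in aqueous) ---
  p2 <- hit2$point
  t_ir <- (phantom$iris_z - p2[, 3]) / d3[, 3]
  x_ir <- p2[, 1] + t_ir * d3[, 1]
  y_ir <- p2[, 2] + t_ir * d3[, 2]
  r_ir <- sqrt(x_ir^2 + y_ir^2)
  on_iris <- alive2 & t_ir > 0 & r_ir >= phantom$pupil_radius &
    r_ir <= phantom$iris_outer_radius
  through <- alive2 & t_ir > 0 & r_ir < phantom$pupil_radius
  z_app[on_iris, "IRIS"] <- z_app[on_iris, "CP"] + med$n_aqueous * t_ir[on_iris]

  # --- anterior lens (only through the pupil) ---
  hit3 <- conicoid_intersect(phantom$lens_ant, p2, d3)
  ok3 <- through & !is.na(hit3$t)
  z_app[ok3, "LA"] <- z_app[ok3, "CP"] + med$n_aqueous * hit3$t[ok3]
  nrm3 <- conicoid_normal(phantom$lens_ant, hit3$point)
  d4 <- snell_refract_3d(d3, nrm3, med$n_aqueous, med$n_lens)
  tir <- ok3 & is.na(d4[, 1])
  tir_dropped <- tir_dropped + sum(tir)
  alive3 <- ok3 & !is.na(d4[, 1])

  # --- posterior lens ---
  p3 <- hit3$point
  hit4 <- conicoid_intersect(phantom$lens_post, p3, d4)
  ok4 <- alive3 & !is.na(hit4$t)
  z_app[ok4, "LP"] <- z_app[ok4, "LA"] + med$n_lens * hit4$t[ok4]

  out <- tidyr::expand_grid(
    row = seq_len(n),
    surface = factor(SURFACE_LABELS, levels = SURFACE_LABELS))
  out <- tibble::tibble(
    incidence = orientation,
    meridian_index = mer[out$row],
    meridian_angle = ang[out$row],
    direction = 1L,
    ascan_index = asc[out$row],
    surface = as.character(out$surface),
    x_px = as.numeric(asc[out$row]),
    z_px = z_app[cbind(out$row, as.integer(out$surface))] * 1000 /
      protocol$axial_scale,
    missing = is.na(z_app[cbind(out$row, as.integer(out$surface))]))
  if (protocol$noise_sd_px > 0) {
    seed <- protocol$rng_seed + match(orientation,
                                      protocol$orientations$label) * 1000L
    out$z_px <- with_seed(seed, {
      nz <- !out$missing
      out$z_px[nz] <- out$z_px[nz] + rnorm(sum(nz), sd = protocol$noise_sd_px)
      out$z_px
    })
  }
  attr(out, "tir_dropped") <- tir_dropped
  attr(out, "gaze") <- list(axis = ori$axis, angle_deg = ori$angle_deg,
                            rotation = Rg, centre = ctr)
  out
}

#' Simulate the full eight-orientation acquisition
#'
#' Runs [forward_simulate()] for every orientation in the protocol and binds
#' the results.
#'
#' @inheritParams forward_simulate
#' @returns A tibble as in [forward_simulate()], with all incidences; per-
#'   incidence gaze metadata is kept in the `"gaze"` attribute (named list).
#' @export
simulate_protocol <- function(phantom, protocol) {
  sets <- lapply(protocol$orientations$label, function(lb)
    forward_simulate(phantom, protocol, lb))
  gaze <- lapply(sets, attr, "gaze")
  names(gaze) <- protocol$orientations$label
  out <- dplyr::bind_rows(sets)
  attr(out, "gaze") <- gaze
  out
}
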