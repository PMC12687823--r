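#' Vector-form Snell refraction in 3-D
#'
#' Refracts unit direction vectors at an interface with unit normals, going
#' from index `n1` into `n2`. The refracted ray stays in the plane of
#' incidence and the tangential wave-vector component is scaled by `n1/n2`.
#' Total internal reflection is signalled by an `NA` row, never by a silent
#' reflection.
#'
#' @param direction n x 3 matrix (or length-3 vector) of unit directions.
#' @param normal n x 3 matrix (or length-3 vector) of unit surface normals;
#'   orientation relative to the ray is resolved internally.
#' @param n1,n2 refractive indices (scalars).
#' @returns An n x 3 matrix of unit refracted directions (`NA` rows on TIR).
#' @export
snell_refract_3d <- function(direction, normal, n1, n2) {
  d <- if (is.matrix(direction)) direction else matrix(direction, 1)
  nn <- if (is.matrix(normal)) normal else matrix(normal, 1)
  if (nrow(nn) == 1 && nrow(d) > 1) nn <- nn[rep(1, nrow(d)), , drop = FALSE]
  assert_that(n1 >= 1 && n2 >= 1, "refractive indices must be >= 1")
  # orient normals against the incoming direction
  ci <- -rowSums(d * nn)
  flip <- !is.na(ci) & ci < 0
  nn[flip, ] <- -nn[flip, , drop = FALSE]
  ci <- abs(ci)
  eta <- n1 / n2
  k <- 1 - eta^2 * (1 - ci^2)
  out <- eta * d + (eta * ci - sqrt(pmax(k, 0))) * nn
  out[!is.na(k) & k < 0, ] <- NA_real_
  bad <- is.na(d[, 1]) | is.na(d[, 2]) | is.na(d[, 3])
  out[bad, ] <- NA_real_
  out
}

#' Intersect rays with a fitted Zernike surface
#'
#' Finds the nearest forward intersection of each ray with the surface by a
#' safeguarded 1-D root solve of `z_ray(t) - z_surface(x(t), y(t))` along the
#' ray (bisection on a bracket found by marching, polished by bisection to
#' `tol`). The surface normal at the hit comes from the analytic Zernike
#' gradient. Rays that do not cross the surface inside its domain are
#' flagged with `NA`.
#'
#' @param origin,direction n x 3 matrices (direction unit).
#' @param surface a [fit_zernike()] object.
#' @param t_max maximum ray parameter searched (mm).
#' @param tol solve tolerance (mm).
#' @returns list with `point` (n x 3), `normal` (n x 3), `t` (n).
#' @export
intersect_ray_surface <- function(origin, direction, surface,
                                  t_max = 30, tol = 1e-10) {
  o <- if (is.matrix(origin)) origin else matrix(origin, 1)
  d <- if (is.matrix(direction)) direction else matrix(direction, 1)
  Rfit <- surface$rotation
  if (!is.null(Rfit)) {
    o <- o %*% t(Rfit)
    d <- d %*% t(Rfit)
  }
  n <- nrow(o)
  f_of <- function(t) {
    # signed gap z_ray - z_surface, NA outside the disc
    x <- o[, 1] + t * d[, 1]
    y <- o[, 2] + t * d[, 2]
    z <- o[, 3] + t * d[, 3]
    zs <- evaluate_zernike(surface, x, y, enforce_domain = FALSE)$z
    z - zs
  }
  # march to bracket the first sign change
  n_steps <- 64
  ts <- seq(0, t_max, length.out = n_steps + 1)
  lo <- rep(NA_real_, n)
  hi <- rep(NA_real_, n)
  f_prev <- f_of(rep(ts[1], n))
  for (i in 2:(n_steps + 1)) {
    f_cur <- f_of(rep(ts[i], n))
    take <- is.na(lo) & !is.na(f_prev) & !is.na(f_cur) &
      sign(f_prev) != sign(f_cur)
    lo[take] <- ts[i - 1]
    hi[take] <- ts[i]
    f_prev <- f_cur
  }
  ok <- !is.na(lo)
  # vectorized bisection
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f_of(mid)
    flo <- f_of(lo)
    move_lo <- ok & !is.na(fm) & sign(fm) == sign(flo)
    lo[move_lo] <- mid[move_lo]
    hi[ok & !move_lo] <- mid[ok & !move_lo]
    if (all(is.na(lo) | (hi - lo) < tol)) break
  }
  t_hit <- ifelse(ok, (lo + hi) / 2, NA_real_)
  px <- o[, 1] + t_hit * d[, 1]
  py <- o[, 2] + t_hit * d[, 2]
  pz <- o[, 3] + t_hit * d[, 3]
  nrm <- matrix(NA_real_, n, 3)
  if (any(ok)) {
    nrm[ok, ] <- zernike_normal(surface, px[ok], py[ok])
  }
  pt <- cbind(x = px, y = py, z = pz)
  if (!is.null(Rfit)) {
    pt <- pt %*% Rfit
    colnames(pt) <- c("x", "y", "z")
    nrm <- nrm %*% Rfit
  }
  list(point = pt, normal = nrm, t = t_hit)
}

#' Assemble a per-incidence 3-D eye model
#'
#' Bundles the fitted surfaces, the per-A-scan apparent (OPL) depth table and
#' the iris points into a raw `eye_model` ready for distortion correction.
#' An error is raised immediately when the anterior cornea is absent but
#' correction will be requested.
#'
#' @param surfaces named list of [fit_zernike()] objects (subset of CA, CP,
#'   LA, LP).
#' @param iris tibble of iris 3-D points (apparent, mm).
#' @param incidence incidence label.
#' @param ascans per-A-scan apparent depth table (columns `x`, `y`, `z_CA`,
#'   `z_CP`, `z_LA`, `z_LP`, `z_IRIS`).
#' @param points tibble of raw surface sample points (`surface`, `x`, `y`,
#'   `z`).
#' @param require_ca error when the anterior cornea fit is missing.
#' @returns An object of class `eye_model` with `distortion_state = "raw"`.
#' @export
assemble_model <- function(surfaces, iris, incidence, ascans = NULL,
                           points = NULL, require_ca = TRUE) {
  if (require_ca) {
    assert_that("CA" %in% names(surfaces),
                "anterior cornea (CA) fit is required for distortion correction")
  }
  order_keep <- intersect(c("CA", "CP", "LA", "LP"), names(surfaces))
  structure(list(
    incidence = incidence,
    surfaces = surfaces[order_keep],
    iris = iris,
    ascans = ascans,
    points = points,
    state = "raw"
  ), class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("<eye_model> incidence %s, state %s, surfaces: %s\n",
              x$incidence, x$state, paste(names(x$surfaces), collapse = ", ")))
  invisible(x)
}

# Correct one surface of a raw model given the already-corrected ray state.
# Internal engine shared by correct_model(); `rays` carries the per-A-scan
# current position, direction and apparent depth of the previous crossing.
propagate_to <- function(rays, z_app_target, n_group) {
  opl <- z_app_target - rays$z_app
  ok <- rays$alive & !is.na(opl) & opl > 0
  s <- opl / n_group
  pt <- rays$point + ifelse(ok, s, NA_real_) * rays$dir
  list(point = pt, ok = ok)
}

#' Optical distortion correction of an eye model
#'
#' Implements surface-by-surface 3-D ray-traced correction: for every A-scan
#' ray, refract at the anterior cornea (air to cornea), advance by the
#' measured optical path length to the posterior cornea divided by the
#' corneal group index, refract again (cornea to aqueous), advance to the
#' anterior lens, refract (aqueous to lens) and advance to the posterior
#' lens. After each surface is corrected its Zernike expansion is refitted so
#' the next refraction uses corrected geometry. Iris points are corrected
#' through the cornea only (CA and CP). Rays whose anterior-cornea crossing
#' falls outside the corneal data domain lose their deeper samples: an
#' uncovered corneal region makes the lens below it unrecoverable.
#'
#' @param model a raw `eye_model` from [assemble_model()] with an `ascans`
#'   table.
#' @param media an [optical_media()].
#' @param n_terms Zernike terms used for the refits.
#' @param correct_iris correct iris points through the cornea (default) or
#'   keep them raw.
#' @returns The corrected `eye_model` (`state = "corrected"`), with corrected
#'   per-surface points in `$points` and refitted surfaces in `$surfaces`.
#' @export
correct_model <- function(model, media = optical_media(), n_terms = 15,
                          correct_iris = TRUE) {
  assert_that(inherits(model, "eye_model"), "model must be an eye_model")
  assert_that(model$state == "raw", "model is already corrected")
  assert_that(!is.null(model$ascans), "model has no per-A-scan OPL table")
  a <- model$ascans
  ca_fit <- model$surfaces$CA
  assert_that(!is.null(ca_fit), "anterior cornea fit missing")
  tilt <- model$tilt  # de-tilt rotation shared by this incidence's fits

  n <- nrow(a)
  p_ca <- cbind(a$x, a$y, a$z_CA)
  have_ca <- !is.na(a$z_CA)
  # domain rule: rays without anterior coverage lose their deeper samples
  inside <- rep(FALSE, n)
  inside[have_ca] <- in_domain_at(ca_fit, p_ca[have_ca, , drop = FALSE])
  alive <- have_ca & inside

  d0 <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  d1 <- matrix(NA_real_, n, 3)
  if (any(alive)) {
    nrm_ca <- surface_normal_at(ca_fit, p_ca[alive, , drop = FALSE])
    d1[alive, ] <- snell_refract_3d(d0[alive, , drop = FALSE], nrm_ca,
                                    media$n_air, media$n_cornea)
  }
  alive <- alive & !is.na(d1[, 1])

  rays <- list(point = p_ca, dir = d1, z_app = a$z_CA, alive = alive)
  ids <- if (all(c("meridian_index", "ascan_index") %in% names(a))) {
    tibble::tibble(meridian_index = a$meridian_index,
                   ascan_index = a$ascan_index)
  } else {
    tibble::tibble(meridian_index = rep(NA_integer_, n),
                   ascan_index = seq_len(n) - 1L)
  }
  out_points <- list(CA = tibble::tibble(
    surface = "CA", x = a$x[have_ca], y = a$y[have_ca], z = a$z_CA[have_ca],
    cos_inc = NA_real_, ids[have_ca, ]))
  fits <- list(CA = ca_fit)
  status <- tibble::tibble(ray = seq_len(n), ca = have_ca, ca_domain = inside)

  # advance rays to a surface, refit it, and refract into the next medium
  advance <- function(rays, z_target, n_prop, n_next, refit_label) {
    pr <- propagate_to(rays, z_target, n_prop)
    pts <- pr$point
    keep <- pr$ok
    fit <- NULL
    d_next <- matrix(NA_real_, n, 3)
    cos_inc <- rep(NA_real_, n)
    if (sum(keep) >= n_terms) {
      fit <- fit_zernike(pts[keep, , drop = FALSE], n_terms = n_terms,
                         label = refit_label, rotation = tilt)
      nrm <- surface_normal_at(fit, pts[keep, , drop = FALSE])
      cos_inc[keep] <- abs(rowSums(rays$dir[keep, , drop = FALSE] * nrm))
      if (!is.null(n_next)) {
        d_next[keep, ] <- snell_refract_3d(rays$dir[keep, , drop = FALSE],
                                           nrm, n_prop, n_next)
      }
    }
    list(points = pts, keep = keep, fit = fit, d_next = d_next,
         cos_inc = cos_inc,
         rays = list(point = pts, dir = d_next, z_app = z_target,
                     alive = keep & !is.na(d_next[, 1])))
  }
  as_tb <- function(label, st) {
    k <- st$keep
    tibble::tibble(surface = label, x = st$points[k, 1], y = st$points[k, 2],
                   z = st$points[k, 3], cos_inc = st$cos_inc[k], ids[k, ])
  }

  # posterior cornea, then anterior and posterior lens
  s_cp <- advance(rays, a$z_CP, media$n_cornea, media$n_aqueous, "CP")
  if (!is.null(s_cp$fit)) fits$CP <- s_cp$fit
  out_points$CP <- as_tb("CP", s_cp)

  # iris through the cornea (CA + CP only)
  iris_pts <- model$iris
  if (correct_iris && "z_IRIS" %in% names(a)) {
    pr <- propagate_to(s_cp$rays, a$z_IRIS, media$n_aqueous)
    keep <- pr$ok
    iris_pts <- tibble::tibble(x = pr$point[keep, 1], y = pr$point[keep, 2],
                               z = pr$point[keep, 3])
  }

  s_la <- advance(s_cp$rays, a$z_LA, media$n_aqueous, media$n_lens, "LA")
  if (!is.null(s_la$fit)) fits$LA <- s_la$fit
  out_points$LA <- as_tb("LA", s_la)

  s_lp <- advance(s_la$rays, a$z_LP, media$n_lens, NULL, "LP")
  if (!is.null(s_lp$fit)) fits$LP <- s_lp$fit
  out_points$LP <- as_tb("LP", s_lp)

  out <- model
  out$surfaces <- fits[intersect(c("CA", "CP", "LA", "LP"), names(fits))]
  out$points <- dplyr::bind_rows(out_points)
  out$iris <- iris_pts
  out$state <- "corrected"
  out$ray_status <- status
  out
}

#' Correct a single surface of a raw model
#'
#' Convenience wrapper around the full chain of [correct_model()] that
#' returns the corrected point set of one target surface. Surfaces must be
#' corrected in their physical order (CP, then LA, then LP); requesting a
#' deeper surface implies correcting (and refitting) all shallower ones
#' first, and requesting them out of order on a partially corrected model is
#' an error.
#'
#' @inheritParams correct_model
#' @param target one of `"CP"`, `"LA"`, `"LP"`.
#' @returns A tibble of corrected points for `target`.
#' @export
correct_surface <- function(model, target = c("CP", "LA", "LP"),
                            media = optical_media(), n_terms = 15) {
  target <- match.arg(target)
  assert_that(model$state == "raw",
              "correct_surface() expects a raw model (ordering violation)")
  full <- correct_model(model, media = media, n_terms = n_terms)
  dplyr::filter(full$points, .data$surface == target)
}
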