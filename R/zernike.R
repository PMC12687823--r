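# Zernike polynomial surfaces in the OSA/ANSI single-index convention with
# unit-variance normalization. Surfaces are fitted by least squares to 3-D
# point sets over a disc of per-surface normalization radius, and evaluated
# together with analytic gradients (needed for refraction normals).

# n, m for OSA/ANSI single indices j = 0, 1, ...
zernike_nm <- function(j) {
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2 * j - n * (n + 2)
  cbind(n = n, m = m)
}

# Radial polynomial coefficients: R_n^{|m|}(rho) = sum c_s rho^{n - 2s}
zernike_radial_coefs <- function(n, m_abs) {
  s <- 0:((n - m_abs) / 2)
  coefs <- (-1)^s * factorial(n - s) /
    (factorial(s) * factorial((n + m_abs) / 2 - s) * factorial((n - m_abs) / 2 - s))
  list(powers = n - 2 * s, coefs = coefs)
}

# Evaluate terms (and optionally rho/phi derivatives) at polar coords.
# Returns list of matrices n_pts x n_terms.
zernike_terms_polar <- function(rho, phi, n_terms, derivatives = FALSE) {
  nm <- zernike_nm(seq_len(n_terms) - 1)
  Z <- matrix(0, length(rho), n_terms)
  dZr <- if (derivatives) matrix(0, length(rho), n_terms) else NULL
  dZp <- if (derivatives) matrix(0, length(rho), n_terms) else NULL
  for (j in seq_len(n_terms)) {
    n <- nm[j, "n"]; m <- nm[j, "m"]; ma <- abs(m)
    rc <- zernike_radial_coefs(n, ma)
    R <- rep(0, length(rho))
    dR <- rep(0, length(rho))
    for (k in seq_along(rc$powers)) {
      p <- rc$powers[k]
      R <- R + rc$coefs[k] * rho^p
      if (derivatives && p > 0) dR <- dR + rc$coefs[k] * p * rho^(p - 1)
    }
    N <- sqrt(2 * (n + 1) / (1 + (m == 0)))
    if (m >= 0) {
      ang <- cos(ma * phi); dang <- -ma * sin(ma * phi)
    } else {
      ang <- sin(ma * phi); dang <- ma * cos(ma * phi)
    }
    Z[, j] <- N * R * ang
    if (derivatives) {
      dZr[, j] <- N * dR * ang
      dZp[, j] <- N * R * dang
    }
  }
  list(Z = Z, dZr = dZr, dZp = dZp)
}

#' Fit a Zernike expansion to a 3-D surface point set
#'
#' Least-squares fit of `z` as an OSA/ANSI-ordered Zernike expansion of the
#' lateral coordinates, over a disc of radius `radius` centred on the lateral
#' midrange of the data (15 terms by default, i.e. radial orders up to 4).
#' The normal equations are solved through a rank-revealing QR decomposition;
#' a warning is emitted when the design is ill-conditioned.
#'
#' @param points data frame or matrix with columns/cols `x`, `y`, `z` (mm).
#' @param n_terms number of Zernike terms (default 15).
#' @param radius normalization radius (mm); default: maximum lateral data
#'   radius about the centre, times 1.001.
#' @param centre lateral centre `c(x, y)` of the unit disc; default lateral
#'   midrange of the data.
#' @param label optional surface label stored with the fit.
#' @param rotation optional 3 x 3 rotation applied to the points before
#'   fitting (a de-tilt for oblique incidences, so the expansion is taken
#'   about the surface's own axis); stored with the fit and honoured by the
#'   point-wise evaluation helpers.
#' @returns An object of class `zernike_surface` with elements `coef`,
#'   `radius`, `centre`, `rms`, `condition`, `mask`, `label`.
#' @export
fit_zernike <- function(points, n_terms = 15, radius = NULL, centre = NULL,
                        label = NULL, rotation = NULL) {
  pts <- as_xyz(points)
  if (!is.null(rotation)) pts <- pts %*% t(rotation)
  assert_that(nrow(pts) >= n_terms,
              paste0("need at least ", n_terms,
                     " points to fit ", n_terms,
                     " Zernike terms; reduce n_terms"))
  if (is.null(centre)) {
    centre <- c(mean(range(pts[, 1])), mean(range(pts[, 2])))
  }
  u <- pts[, 1] - centre[1]
  v <- pts[, 2] - centre[2]
  r <- sqrt(u^2 + v^2)
  if (is.null(radius)) radius <- max(r) * 1.001
  assert_that(radius > 0, "normalization radius must be positive")
  rho <- pmin(r / radius, 1)
  phi <- atan2(v, u)
  X <- zernike_terms_polar(rho, phi, n_terms)$Z
  qr_fit <- lm.fit(X, pts[, 3])
  resid <- qr_fit$residuals
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (cond > 1e8) {
    warn(sprintf("Zernike design matrix is ill-conditioned (kappa = %.3g)", cond))
  }
  structure(list(
    coef = unname(qr_fit$coefficients),
    n_terms = n_terms,
    radius = radius,
    centre = centre,
    rms = sqrt(mean(resid^2)),
    n_points = nrow(pts),
    condition = cond,
    mask = domain_mask(u, v, radius),
    label = label,
    rotation = rotation
  ), class = "zernike_surface")
}

as_xyz <- function(points) {
  if (is.matrix(points)) {
    assert_that(ncol(points) >= 3, "points must have 3 columns")
    m <- points[, 1:3, drop = FALSE]
  } else {
    assert_that(all(c("x", "y", "z") %in% names(points)),
                "points must have columns x, y, z")
    m <- cbind(points$x, points$y, points$z)
  }
  m[stats::complete.cases(m), , drop = FALSE]
}

# Rasterized occupancy mask over the support of the fitted data, on a polar
# (radius x angle) grid about the fit centre. Plays the role of a concave
# support hull: evaluation is refused outside occupied bins and their
# immediate neighbours, so partial (off-axis) domains are never silently
# extrapolated.
domain_mask <- function(u, v, radius, nr = 16, na = 36) {
  r_bin <- pmin(pmax(ceiling(sqrt(u^2 + v^2) / radius * nr), 1L), nr)
  a_bin <- (floor((atan2(v, u) + pi) / (2 * pi) * na)) %% na + 1L
  occ <- matrix(FALSE, nr, na)
  occ[cbind(r_bin, a_bin)] <- TRUE
  # dilate once (angular wrap, radial clamp)
  d <- occ
  for (dr in -1:1) for (da in -1:1) {
    rr <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    aa <- (seq_len(na) + da - 1L) %% na + 1L
    d <- d | occ[rr, aa, drop = FALSE]
  }
  # any occupancy in the innermost ring covers the full centre disc
  if (any(occ[1, ])) d[1, ] <- TRUE
  list(occ = d, nr = nr, na = na, radius = radius)
}

in_domain <- function(surface, u, v) {
  m <- surface$mask
  r <- sqrt(u^2 + v^2)
  inside <- r <= m$radius
  r_bin <- pmin(pmax(ceiling(r / m$radius * m$nr), 1L), m$nr)
  a_bin <- (floor((atan2(v, u) + pi) / (2 * pi) * m$na)) %% m$na + 1L
  inside & m$occ[cbind(r_bin, a_bin)]
}

#' Evaluate a fitted Zernike surface
#'
#' Evaluates elevation (and optionally the lateral gradient) at Cartesian
#' query locations. Queries outside the normalization disc or outside the
#' support mask of the fitted data are flagged `NA` rather than extrapolated.
#'
#' @param surface a [fit_zernike()] object.
#' @param x,y query coordinates (mm).
#' @param derivatives if `TRUE` also return `dzdx`, `dzdy`.
#' @param enforce_domain if `FALSE`, evaluate anywhere inside the disc.
#' @returns A tibble with columns `x`, `y`, `z`, `in_domain` (and gradients
#'   when requested).
#' @export
evaluate_zernike <- function(surface, x, y, derivatives = FALSE,
                             enforce_domain = TRUE) {
  u <- x - surface$centre[1]
  v <- y - surface$centre[2]
  r <- sqrt(u^2 + v^2)
  rho <- r / surface$radius
  ok <- rho <= 1 + 1e-12
  if (enforce_domain) ok <- ok & in_domain(surface, u, v)
  rho_c <- pmax(pmin(rho, 1), 1e-9)
  phi <- atan2(v, u)
  tm <- zernike_terms_polar(rho_c, phi, surface$n_terms, derivatives = derivatives)
  z <- as.numeric(tm$Z %*% surface$coef)
  z[!ok] <- NA_real_
  out <- tibble::tibble(x = x, y = y, z = z, in_domain = ok)
  if (derivatives) {
    dzdrho <- as.numeric(tm$dZr %*% surface$coef)
    dzdphi <- as.numeric(tm$dZp %*% surface$coef)
    cphi <- cos(phi); sphi <- sin(phi)
    a <- surface$radius
    out$dzdx <- (dzdrho * cphi - dzdphi * sphi / rho_c) / a
    out$dzdy <- (dzdrho * sphi + dzdphi * cphi / rho_c) / a
    out$dzdx[!ok] <- NA_real_
    out$dzdy[!ok] <- NA_real_
  }
  out
}

# Unit surface normals oriented towards -Z (the incoming medium side),
# queried in the fit frame.
zernike_normal <- function(surface, x, y, enforce_domain = FALSE) {
  ev <- evaluate_zernike(surface, x, y, derivatives = TRUE,
                         enforce_domain = enforce_domain)
  n <- cbind(ev$dzdx, ev$dzdy, -1)
  normalize_rows(n)
}

# Normals at known 3-D surface points given in the instrument frame,
# honouring a fitted de-tilt rotation. Returns instrument-frame normals.
surface_normal_at <- function(surface, pts3) {
  p <- if (is.matrix(pts3)) pts3 else matrix(pts3, ncol = 3)
  if (!is.null(surface$rotation)) p <- p %*% t(surface$rotation)
  n <- zernike_normal(surface, p[, 1], p[, 2])
  if (!is.null(surface$rotation)) n <- n %*% surface$rotation
  n
}

# Domain membership of instrument-frame 3-D points.
in_domain_at <- function(surface, pts3) {
  p <- if (is.matrix(pts3)) pts3 else matrix(pts3, ncol = 3)
  if (!is.null(surface$rotation)) p <- p %*% t(surface$rotation)
  in_domain(surface, p[, 1] - surface$centre[1], p[, 2] - surface$centre[2])
}

#' @export
print.zernike_surface <- function(x, ...) {
  cat(sprintf("<zernike_surface%s> %d terms, radius %.3f mm, RMS residual %.3g mm (n = %d)\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n_terms, x$radius, x$rms, x$n_points))
  invisible(x)
}

#' @method tidy zernike_surface
#' @export
tidy.zernike_surface <- function(x, ...) {
  nm <- zernike_nm(seq_len(x$n_terms) - 1)
  tibble::tibble(term = seq_len(x$n_terms) - 1L,
                 radial_order = as.integer(nm[, "n"]),
                 azimuthal_frequency = as.integer(nm[, "m"]),
                 estimate = x$coef)
}

#' @method glance zernike_surface
#' @export
glance.zernike_surface <- function(x, ...) {
  tibble::tibble(n_terms = x$n_terms, n_points = x$n_points,
                 radius_mm = x$radius, rms_mm = x$rms, condition = x$condition)
}
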