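# Eigenlens representation: a lens shape is the M = P x Q vector of radial
# elevations I(theta, phi) (distance from the lens centre) on a fixed polar
# grid, expressed as the mean lens plus a small number of principal
# components ("eigenlenses").

new_lens_polar_grid <- function(I, P, Q, origin = c(0, 0, 0)) {
  structure(list(I = I, P = P, Q = Q,
                 theta = seq(0, pi, length.out = P),
                 phi = seq(0, 2 * pi, length.out = Q + 1)[1:Q],
                 origin = as.numeric(origin)),
            class = "lens_polar_grid")
}

#' @export
print.lens_polar_grid <- function(x, ...) {
  miss <- sum(is.na(x$I))
  cat(sprintf("<lens_polar_grid> P = %d x Q = %d (M = %d), %d missing nodes, radial range %.3f-%.3f mm\n",
              x$P, x$Q, x$P * x$Q, miss,
              min(x$I, na.rm = TRUE), max(x$I, na.rm = TRUE)))
  invisible(x)
}

# Cartesian coordinates of the grid nodes (theta = 0 is the anterior pole,
# towards the instrument at -Z).
polar_grid_points <- function(grid) {
  th <- matrix(grid$theta, grid$P, grid$Q)
  ph <- matrix(grid$phi, grid$P, grid$Q, byrow = TRUE)
  I <- grid$I
  tibble::tibble(
    theta = as.vector(th), phi = as.vector(ph), I = as.vector(I),
    x = as.vector(I * sin(th) * cos(ph)),
    y = as.vector(I * sin(th) * sin(ph)),
    z = as.vector(-I * cos(th)))
}

#' Centre a merged lens cloud at its shape origin
#'
#' Places the lateral origin under the anterior-surface apex (the maximum
#' elevation point of a smooth fit to the merged anterior lens points) and
#' the axial origin at the midpoint between the anterior and posterior apex
#' depths, the reference frame of the eigenlens grid.
#'
#' @param merged tibble with `surface` (`LA` / `LP`), `x`, `y`, `z` (mm),
#'   e.g. `register_all()$merged`.
#' @param n_terms Zernike terms for the apex fits.
#' @param apex_radius lateral radius (mm) of data used to locate the apexes.
#' @returns A list with `cloud` (shifted tibble) and `origin` (the subtracted
#'   3-vector in input coordinates).
#' @export
align_lens <- function(merged, n_terms = 10, apex_radius = 2.5) {
  la <- merged[merged$surface == "LA", ]
  lp <- merged[merged$surface == "LP", ]
  assert_that(nrow(la) > n_terms && nrow(lp) > n_terms,
              "need anterior and posterior lens points near the axis")
  ctr0 <- c(median(la$x), median(la$y))
  near <- function(d) d[(d$x - ctr0[1])^2 + (d$y - ctr0[2])^2 < apex_radius^2, ]
  fa <- fit_zernike(near(la), n_terms = n_terms, label = "LA")
  # apex: minimum z (closest to the instrument) of the fitted surface
  obj <- function(p) evaluate_zernike(fa, p[1], p[2], enforce_domain = FALSE)$z
  opt <- optim(ctr0, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12))
  apex_xy <- opt$par
  z_la <- opt$value
  fp <- fit_zernike(near(lp), n_terms = n_terms, label = "LP")
  z_lp <- evaluate_zernike(fp, apex_xy[1], apex_xy[2],
                           enforce_domain = FALSE)$z
  origin <- c(apex_xy, (z_la + z_lp) / 2)
  cloud <- dplyr::mutate(merged,
                         x = .data$x - origin[1],
                         y = .data$y - origin[2],
                         z = .data$z - origin[3])
  list(cloud = cloud, origin = origin)
}

#' Resample an aligned lens cloud onto the fixed polar grid
#'
#' Converts the aligned cloud to polar coordinates about the origin and
#' interpolates the radial elevation I onto the P x Q grid of equidistant
#' elevation and azimuth angles by local weighted-linear regression in the
#' tangent plane of each node direction. Nodes without nearby support are
#' flagged missing (to be completed by the eigenlens projection). Apparent
#' violations of star-convexity (widely spread radii within one angular
#' neighbourhood) are counted and reported via the `"nonstar_fraction"`
#' attribute.
#'
#' @param cloud tibble with `x`, `y`, `z` of lens-surface points, centred.
#' @param P,Q grid dimensions (default 100 x 100).
#' @param max_angle angular support radius (rad) beyond which a node is
#'   declared missing.
#' @param max_points random subsample cap on the input cloud.
#' @returns A `lens_polar_grid`.
#' @export
to_polar_grid <- function(cloud, P = 100, Q = 100, max_angle = 0.06,
                          max_points = 60000) {
  pts <- as_xyz(cloud)
  pts <- subsample_rows(pts, max_points)
  rho <- row_norm(pts)
  keep <- rho > 1e-9
  pts <- pts[keep, , drop = FALSE]
  rho <- rho[keep]
  u <- pts / rho  # unit directions
  theta_p <- acos(pmax(-1, pmin(1, -u[, 3])))
  phi_p <- atan2(u[, 2], u[, 1]) %% (2 * pi)

  grid <- new_lens_polar_grid(matrix(NA_real_, P, Q), P, Q)
  th_g <- grid$theta
  ph_g <- grid$phi

  # bucket the cloud on a coarse (theta, phi) raster for local search
  nb_t <- max(8L, ceiling(pi / max_angle / 2))
  nb_p <- max(8L, ceiling(2 * pi / max_angle / 2))
  bt <- pmin(pmax(ceiling(theta_p / pi * nb_t), 1L), nb_t)
  bp <- (floor(phi_p / (2 * pi) * nb_p)) %% nb_p + 1L
  bucket <- split(seq_along(rho), (bt - 1L) * nb_p + bp)

  gather <- function(it, ip, rings) {
    # indices of cloud points in the raster neighbourhood of node (it, ip)
    ts <- pmin(pmax((it - rings):(it + rings), 1L), nb_t)
    ps <- ((ip - rings):(ip + rings) - 1L) %% nb_p + 1L
    keys <- as.character(outer((unique(ts) - 1L) * nb_p, unique(ps), "+"))
    unlist(bucket[keys], use.names = FALSE)
  }

  I_out <- matrix(NA_real_, P, Q)
  nonstar <- 0L
  checked <- 0L
  for (i in seq_len(P)) {
    ti <- th_g[i]
    nit <- pmin(pmax(ceiling(ti / pi * nb_t), 1L), nb_t)
    # node direction batch over phi
    for (j in seq_len(Q)) {
      pj <- ph_g[j]
      njp <- (floor(pj / (2 * pi) * nb_p)) %% nb_p + 1L
      idx <- gather(nit, njp, 1L)
      if (length(idx) < 4) idx <- gather(nit, njp, 2L)
      if (length(idx) < 4) next
      nd <- c(sin(ti) * cos(pj), sin(ti) * sin(pj), -cos(ti))
      ca <- u[idx, , drop = FALSE] %*% nd
      ang <- acos(pmax(-1, pmin(1, ca)))
      sel <- ang <= max_angle
      if (sum(sel) < 4) next
      ids <- idx[sel]
      w <- exp(-(ang[sel] / (max_angle / 2))^2)
      # tangent-plane coordinates
      ref <- if (abs(nd[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- as_unit(pracma_cross(nd, ref))
      e2 <- pracma_cross(nd, e1)
      t1 <- as.numeric(u[ids, , drop = FALSE] %*% e1)
      t2 <- as.numeric(u[ids, , drop = FALSE] %*% e2)
      rr <- rho[ids]
      checked <- checked + 1L
      if ((max(rr) - min(rr)) > 0.25 * median(rr)) nonstar <- nonstar + 1L
      # local quadratic where supported (curvature-unbiased), linear fallback
      X <- if (length(ids) >= 8) {
        cbind(1, t1, t2, t1^2, t1 * t2, t2^2)
      } else {
        cbind(1, t1, t2)
      }
      fit <- tryCatch(suppressWarnings(lm.fit(X * w, rr * w)),
                      error = function(e) NULL)
      if (is.null(fit) || is.na(fit$coefficients[1])) next
      I_out[i, j] <- fit$coefficients[1]
    }
  }
  # poles: all azimuth nodes of a pole row share one direction; average
  for (i in c(1L, P)) {
    v <- I_out[i, ]
    if (any(!is.na(v))) I_out[i, ] <- mean(v, na.rm = TRUE)
  }
  grid$I <- I_out
  if (checked > 0 && nonstar / checked > 0.02) {
    warn(sprintf("to_polar_grid: %.1f%% of nodes show radial spread inconsistent with star-convexity",
                 100 * nonstar / checked))
  }
  attr(grid, "nonstar_fraction") <- if (checked > 0) nonstar / checked else NA
  grid
}

# Training population ------------------------------------------------------

#' Synthetic training population for the eigenlens basis
#'
#' Generates rotationally symmetric two-conicoid-cap lenses with equatorial
#' diameter uniform on 8-10.5 mm, thickness uniform on 3.2-4.8 mm and the
#' anterior share of the thickness uniform on 0.38-0.52 (the caps are
#' vertical-tangent conicoids, so asphericity and apex radii vary with all
#' three draws and the equator is smooth), plus a small random elliptical
#' (toric) lateral scaling. Each lens is sampled analytically on the polar
#' grid.
#'
#' @param n number of training lenses.
#' @param P,Q grid dimensions.
#' @param seed RNG seed (fixed default so the basis is reproducible).
#' @returns A list of `lens_polar_grid`s.
#' @export
training_lens_family <- function(n = 80, P = 100, Q = 100, seed = 20240101) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        dia <- runif(1, 8, 10.5)
        thick <- runif(1, 3.2, 4.8)
        split <- runif(1, 0.38, 0.52)
        ell <- 1 + rnorm(1, 0, 0.01)
        ax <- runif(1, 0, pi)
        ph <- tryCatch(
          make_phantom(NULL, lens_dia = dia, lens_thickness = thick,
                       lens_split = split, pupil_radius = dia / 4),
          error = function(e) NULL)
        if (!is.null(ph)) break
      }
      prof <- phantom_radial_profile(ph, P)
      grid <- new_lens_polar_grid(matrix(NA_real_, P, Q), P, Q)
      th <- matrix(grid$theta, P, Q)
      phm <- matrix(grid$phi, P, Q, byrow = TRUE)
      # elliptical lateral scaling along azimuth `ax`: direction transform
      dx <- sin(th) * cos(phm - ax) / ell
      dy <- sin(th) * sin(phm - ax)
      dz <- -cos(th)
      g <- sqrt(dx^2 + dy^2 + dz^2)
      th2 <- acos(pmax(-1, pmin(1, -dz / g)))
      Isym <- stats::approx(grid$theta, prof, xout = as.vector(th2),
                            rule = 2)$y
      grid$I <- matrix(Isym / as.vector(g), P, Q)
      grid
    })
  })
}

#' Build an eigenlens basis from training lenses
#'
#' Per-node mean lens plus the first `K` principal components (eigenlenses)
#' of the centred training matrix, ordered by decreasing eigenvalue, computed
#' by singular value decomposition.
#'
#' @param training list of complete `lens_polar_grid`s on a common grid.
#' @param K number of eigenlenses to keep (default 6).
#' @returns An object of class `eigenlens_basis` with `mean` (M-vector),
#'   `basis` (M x K orthonormal), `eigenvalues`, grid spec.
#' @export
build_basis <- function(training, K = 6) {
  assert_that(length(training) > K,
              paste0("need more than K = ", K, " training lenses"))
  P <- training[[1]]$P; Q <- training[[1]]$Q
  for (tr in training) {
    assert_that(tr$P == P && tr$Q == Q, "training grids disagree in size")
    assert_that(!anyNA(tr$I), "training grids must be complete (no missing nodes)")
  }
  X <- t(vapply(training, function(tr) as.vector(tr$I),
                numeric(P * Q)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = K)
  structure(list(mean = mu, basis = sv$v[, seq_len(K), drop = FALSE],
                 eigenvalues = (sv$d^2 / (nrow(X) - 1))[seq_len(K)],
                 all_eigenvalues = sv$d^2 / (nrow(X) - 1),
                 P = P, Q = Q, K = K, n_training = nrow(X)),
            class = "eigenlens_basis")
}

#' @export
print.eigenlens_basis <- function(x, ...) {
  cat(sprintf("<eigenlens_basis> K = %d on %d x %d grid, %d training lenses\n",
              x$K, x$P, x$Q, x$n_training))
  cat("  eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  invisible(x)
}

#' @method tidy eigenlens_basis
#' @export
tidy.eigenlens_basis <- function(x, ...) {
  tibble::tibble(component = seq_len(x$K),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$eigenvalues / sum(x$all_eigenvalues))
}

#' @method glance eigenlens_basis
#' @export
glance.eigenlens_basis <- function(x, ...) {
  tibble::tibble(K = x$K, M = x$P * x$Q, n_training = x$n_training,
                 variance_captured = sum(x$eigenvalues) / sum(x$all_eigenvalues))
}

#' Project a lens onto the eigenlens basis
#'
#' For a complete grid the coefficients are `a = t(M) (I - mean)`. When
#' nodes are missing, the least-squares projection restricted to the
#' observed rows is solved instead, which is what lets small unrecovered
#' portions of the lens be completed by the basis.
#'
#' @param grid a `lens_polar_grid` (missing nodes allowed).
#' @param basis an [build_basis()] object.
#' @returns An object of class `eigen_coefficients` (numeric vector `a` plus
#'   projection metadata).
#' @export
project_lens <- function(grid, basis) {
  assert_that(grid$P == basis$P && grid$Q == basis$Q,
              "grid and basis dimensions disagree")
  I <- as.vector(grid$I)
  obs <- !is.na(I)
  r <- I[obs] - basis$mean[obs]
  if (all(obs)) {
    a <- as.numeric(crossprod(basis$basis, I - basis$mean))
  } else {
    Mo <- basis$basis[obs, , drop = FALSE]
    a <- as.numeric(solve(crossprod(Mo), crossprod(Mo, r)))
  }
  structure(list(a = a, K = basis$K, n_observed = sum(obs),
                 n_nodes = length(I),
                 rms_residual = sqrt(mean((r - basis$basis[obs, , drop = FALSE] %*% a)^2))),
            class = "eigen_coefficients")
}

#' @export
print.eigen_coefficients <- function(x, ...) {
  cat("<eigen_coefficients>", format(signif(x$a, 5)), "\n")
  cat(sprintf("  observed %d / %d nodes, residual RMS %.4g mm\n",
              x$n_observed, x$n_nodes, x$rms_residual))
  invisible(x)
}

#' @method tidy eigen_coefficients
#' @export
tidy.eigen_coefficients <- function(x, ...) {
  tibble::tibble(component = seq_along(x$a), coefficient = x$a)
}

#' Reconstruct the closed full lens shape from eigenlens coefficients
#'
#' `I_hat = mean + sum_k a_k e_k`, defined over the entire grid including
#' nodes that were missing at projection time.
#'
#' @param coefficients an [project_lens()] object or plain numeric vector of
#'   length `K`.
#' @param basis the [build_basis()] object.
#' @returns A complete `lens_polar_grid`.
#' @export
reconstruct_lens <- function(coefficients, basis) {
  a <- if (inherits(coefficients, "eigen_coefficients")) coefficients$a
       else as.numeric(coefficients)
  assert_that(length(a) == basis$K, "coefficient length must equal basis K")
  I <- basis$mean + as.numeric(basis$basis %*% a)
  new_lens_polar_grid(matrix(I, basis$P, basis$Q), basis$P, basis$Q)
}

#' Serialize / load an eigenlens basis
#'
#' Portable JSON representation (grid spec, mean, basis columns,
#' eigenvalues) with an embedded checksum of the numeric payload.
#'
#' @param basis an `eigenlens_basis`.
#' @param path output / input file.
#' @export
write_basis <- function(basis, path) {
  payload <- list(P = basis$P, Q = basis$Q, K = basis$K,
                  n_training = basis$n_training,
                  mean = basis$mean, basis = as.vector(basis$basis),
                  eigenvalues = basis$eigenvalues,
                  all_eigenvalues = basis$all_eigenvalues)
  payload$checksum <- basis_checksum(payload)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  chk <- p$checksum
  p$checksum <- NULL
  assert_that(isTRUE(all.equal(basis_checksum(p), chk, tolerance = 1e-8)),
              "basis file checksum mismatch")
  structure(list(mean = p$mean,
                 basis = matrix(p$basis, ncol = p$K),
                 eigenvalues = p$eigenvalues,
                 all_eigenvalues = p$all_eigenvalues,
                 P = p$P, Q = p$Q, K = p$K, n_training = p$n_training),
            class = "eigenlens_basis")
}

basis_checksum <- function(p) {
  sum(abs(p$mean)) + sum(abs(p$basis)) + sum(p$eigenvalues) + p$P + p$Q + p$K
}
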