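# Rigid transforms --------------------------------------------------------

#' Rigid transform utilities
#'
#' A rigid transform is a rotation (3 x 3 orthonormal, det +1) plus a
#' translation; points map as `p' = R p + t`.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @returns An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  assert_that(max(abs(crossprod(rotation) - diag(3))) < 1e-8,
              "rotation must be orthonormal")
  assert_that(abs(det(rotation) - 1) < 1e-8, "rotation must have det +1")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param tf a `rigid_transform`.
#' @param points n x 3 matrix or data frame with `x`, `y`, `z`.
#' @export
apply_transform <- function(tf, points) {
  if (is.data.frame(points)) {
    m <- cbind(points$x, points$y, points$z)
    m2 <- m %*% t(tf$R) + matrix(tf$t, nrow(m), 3, byrow = TRUE)
    out <- points
    out$x <- m2[, 1]; out$y <- m2[, 2]; out$z <- m2[, 3]
    return(out)
  }
  points %*% t(tf$R) + matrix(tf$t, nrow(points), 3, byrow = TRUE)
}

#' @rdname rigid_transform
#' @param a,b transforms; `compose_transform(a, b)` applies `b` first.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$R) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' @method tidy rigid_transform
#' @export
tidy.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$R)
  axis <- if (ang < 1e-12) c(0, 0, 1) else {
    v <- c(x$R[3, 2] - x$R[2, 3], x$R[1, 3] - x$R[3, 1], x$R[2, 1] - x$R[1, 2])
    v / (2 * sin(ang))
  }
  tibble::tibble(angle_deg = ang * 180 / pi,
                 axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
                 tx_mm = x$t[1], ty_mm = x$t[2], tz_mm = x$t[3])
}

# Iris fitting -------------------------------------------------------------

#' Fit a plane and circle to segmented iris points
#'
#' Total-least-squares plane (smallest principal direction of the centred
#' covariance), followed by an in-plane circle fit (Taubin algebraic fit
#' polished by Gauss-Newton). The plane normal is oriented towards the
#' instrument (negative-Z hemisphere).
#'
#' @param points iris 3-D points (data frame with `x`, `y`, `z`, or matrix).
#' @returns An object of class `iris_fit` with `normal`, `offset`, `centre`,
#'   `radius`, `n_points`, `rms_plane`, `rms_circle`.
#' @export
fit_iris <- function(points) {
  m <- as_xyz(points)
  assert_that(nrow(m) >= 3, "need at least 3 iris points")
  ctr <- colMeans(m)
  cm <- sweep(m, 2, ctr)
  sv <- svd(cm, nu = 0)
  assert_that(sv$d[2] > 1e-9 * max(sv$d[1], 1),
              "iris points are collinear or degenerate")
  normal <- sv$v[, 3]
  if (normal[3] > 0) normal <- -normal
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  uv <- cbind(cm %*% e1, cm %*% e2)
  circ <- fit_circle_2d(uv)
  centre3 <- ctr + circ$centre[1] * e1 + circ$centre[2] * e2
  structure(list(normal = as.numeric(normal),
                 offset = sum(normal * centre3),
                 centre = as.numeric(centre3),
                 radius = circ$radius,
                 n_points = nrow(m),
                 rms_plane = sqrt(mean((cm %*% normal)^2)),
                 rms_circle = circ$rms), class = "iris_fit")
}

# Taubin algebraic circle fit + Gauss-Newton geometric polish (2-D).
fit_circle_2d <- function(uv, gn_iter = 20) {
  u <- uv[, 1]; v <- uv[, 2]
  mu <- mean(u); mv <- mean(v)
  x <- u - mu; y <- v - mv
  z <- x^2 + y^2
  zm <- mean(z)
  # Taubin: minimize algebraic distance with gradient normalization
  M <- cbind(z - zm, x, y)
  sv <- svd(M, nu = 0)
  w <- sv$v[, 3]
  if (abs(w[1]) < 1e-12) {
    cx <- -w[2] / 2 * 0; cy <- 0  # nearly straight: fall back to centroid
  } else {
    cx <- -w[2] / (2 * w[1])
    cy <- -w[3] / (2 * w[1])
  }
  r <- sqrt(mean((x - cx)^2 + (y - cy)^2))
  # Gauss-Newton on (cx, cy, r)
  for (it in seq_len(gn_iter)) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    res <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 3))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (max(abs(step)) < 1e-12) break
  }
  dx <- x - cx; dy <- y - cy
  list(centre = c(cx + mu, cy + mv), radius = r,
       rms = sqrt(mean((sqrt(dx^2 + dy^2) - r)^2)))
}

#' @export
print.iris_fit <- function(x, ...) {
  cat(sprintf("<iris_fit> centre (%.3f, %.3f, %.3f) mm, radius %.3f mm, tilt %.2f deg (n = %d)\n",
              x$centre[1], x$centre[2], x$centre[3], x$radius,
              acos(min(1, abs(x$normal[3]))) * 180 / pi, x$n_points))
  invisible(x)
}

# Alignment ----------------------------------------------------------------

#' Initial iris-based alignment of an eye model
#'
#' The minimal rotation carrying the iris-plane normal onto the instrument
#' axis undoes the gaze tilt; the translation then places the iris circle
#' centre at the coordinate origin. The returned transform is also applied
#' to all surfaces and iris points when a full model is given.
#'
#' @param model an `eye_model` (corrected) or a plain iris point set.
#' @param iris optional [fit_iris()] result (computed from the model's iris
#'   points when absent).
#' @returns A list with `transform` (the `rigid_transform`), `model` (the
#'   transformed model when a model was given) and `iris_fit`.
#' @export
initial_align <- function(model, iris = NULL) {
  iris_pts <- if (inherits(model, "eye_model")) model$iris else model
  fit <- iris %||% fit_iris(iris_pts)
  Rr <- rotation_between(fit$normal, c(0, 0, -1))
  tr <- -as.numeric(Rr %*% fit$centre)
  tf <- rigid_transform(Rr, tr)
  out_model <- NULL
  if (inherits(model, "eye_model")) {
    out_model <- model
    out_model$points <- apply_transform(tf, model$points)
    out_model$iris <- apply_transform(tf, model$iris)
    out_model$surfaces <- NULL  # fits are frame-specific; refit on demand
  }
  list(transform = tf, model = out_model, iris_fit = fit)
}

#' Trimmed iterative closest point refinement
#'
#' Point-to-point ICP: nearest-neighbour correspondences within a gate
#' distance, trimmed to the best `1 - trim_fraction` matches, closed-form
#' rigid update by SVD of the cross-covariance (Kabsch), iterated until the
#' trimmed MSE improves by less than `tol` or `max_iter` is reached.
#'
#' @param source,reference n x 3 matrices or data frames with `x`, `y`, `z`.
#' @param max_iter iteration cap.
#' @param tol MSE improvement threshold (mm^2).
#' @param trim_fraction worst-match fraction discarded each iteration.
#' @param gate_mm correspondence gate distance.
#' @returns A `rigid_transform` with attributes `history` (tibble of per-
#'   iteration trimmed MSE) and `rms` (final trimmed RMS, mm).
#' @export
icp_refine <- function(source, reference, max_iter = 100, tol = 1e-8,
                       trim_fraction = 0.2, gate_mm = 0.5) {
  src <- as_xyz(source)
  ref <- as_xyz(reference)
  assert_that(nrow(src) >= 3 && nrow(ref) >= 3, "need at least 3 points each")
  tf <- rigid_transform()
  cur <- src
  mse_prev <- Inf
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    nn <- nearest_neighbour(cur, ref)
    ok <- nn$dist <= gate_mm
    assert_that(sum(ok) >= 3, "no overlap: too few ICP correspondences within gate")
    d_ok <- nn$dist[ok]
    keep_n <- max(3L, floor(sum(ok) * (1 - trim_fraction)))
    thr <- sort(d_ok)[keep_n]
    sel <- which(ok)[d_ok <= thr]
    P <- cur[sel, , drop = FALSE]
    Q <- ref[nn$index[sel], , drop = FALSE]
    mse <- mean(rowSums((P - Q)^2))
    hist <- c(hist, mse)
    # closed-form rigid solve
    cp <- colMeans(P); cq <- colMeans(Q)
    H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    Rk <- sv$v %*% D %*% t(sv$u)
    tk <- cq - as.numeric(Rk %*% cp)
    step_tf <- rigid_transform(Rk, tk)
    tf <- compose_transform(step_tf, tf)
    cur <- apply_transform(step_tf, cur)
    if (is.finite(mse_prev) && mse_prev - mse < tol) break
    mse_prev <- mse
  }
  attr(tf, "history") <- tibble::tibble(iteration = seq_along(hist), mse = hist)
  attr(tf, "rms") <- sqrt(hist[length(hist)])
  tf
}

#' Register all per-incidence models into one frame
#'
#' Every model is first iris-aligned ([initial_align()]); the on-axis model
#' is the reference, and the remaining models, in order of increasing gaze
#' angle, are refined by trimmed ICP of their lens surfaces (LA + LP) against
#' the union of already-registered lens points. Redundant overlap between
#' incidences is summarized as a per-pair RMS, a practical check of
#' registration accuracy.
#'
#' @param models list of corrected `eye_model`s (names or `$incidence` give
#'   the labels; the reference is `"on_axis"` when present, else the first).
#' @param icp list of ICP settings (`max_iter`, `tol`, `trim_fraction`,
#'   `gate_mm`).
#' @param max_icp_points subsample cap for ICP point sets.
#' @returns A list with `merged` (tibble `surface`, `x`, `y`, `z`,
#'   `incidence`), `transforms` (named list of `rigid_transform`s, including
#'   the iris pre-alignment), `overlap` (pairwise RMS tibble), `iris_fits`.
#' @export
register_all <- function(models,
                         icp = list(max_iter = 100, tol = 1e-8,
                                    trim_fraction = 0.2, gate_mm = 0.5),
                         max_icp_points = 2000) {
  labels <- vapply(models, function(m) m$incidence, character(1))
  names(models) <- labels
  aligned <- lapply(models, initial_align)
  # order: reference first, then increasing initial tilt angle
  tilt <- vapply(aligned, function(al)
    rotation_angle(al$transform$R), numeric(1))
  ref_lab <- if ("on_axis" %in% labels) "on_axis" else labels[which.min(tilt)]
  rest <- setdiff(labels[order(tilt)], ref_lab)

  lens_pts <- function(m) {
    p <- m$points[m$points$surface %in% c("LA", "LP"), c("x", "y", "z")]
    as.matrix(p)
  }
  transforms <- list()
  transforms[[ref_lab]] <- aligned[[ref_lab]]$transform
  merged <- list()
  m0 <- aligned[[ref_lab]]$model
  merged[[ref_lab]] <- dplyr::mutate(m0$points, incidence = ref_lab)
  ref_cloud <- subsample_rows(lens_pts(m0), 4 * max_icp_points)
  for (lab in rest) {
    mi <- aligned[[lab]]$model
    src <- subsample_rows(lens_pts(mi), max_icp_points)
    tf_icp <- icp_refine(src, ref_cloud, max_iter = icp$max_iter,
                         tol = icp$tol, trim_fraction = icp$trim_fraction,
                         gate_mm = icp$gate_mm)
    transforms[[lab]] <- compose_transform(tf_icp, aligned[[lab]]$transform)
    mi$points <- apply_transform(tf_icp, mi$points)
    mi$iris <- apply_transform(tf_icp, mi$iris)
    merged[[lab]] <- dplyr::mutate(mi$points, incidence = lab)
    ref_cloud <- rbind(ref_cloud,
                       subsample_rows(lens_pts(mi), 2 * max_icp_points))
  }
  merged_tb <- dplyr::bind_rows(merged)
  overlap <- overlap_rms(merged_tb, gate_mm = 0.3)
  list(merged = merged_tb,
       transforms = transforms,
       overlap = overlap,
       iris_fits = lapply(aligned, function(al) al$iris_fit))
}

# Pairwise lens-surface overlap RMS between registered incidences.
overlap_rms <- function(merged, gate_mm = 0.3, max_points = 1500) {
  labs <- unique(merged$incidence)
  if (length(labs) < 2) {
    return(tibble::tibble(a = character(), b = character(),
                          rms_mm = numeric(), n = integer()))
  }
  clouds <- lapply(labs, function(lb) {
    subsample_rows(as.matrix(
      merged[merged$incidence == lb & merged$surface %in% c("LA", "LP"),
             c("x", "y", "z")]), max_points)
  })
  names(clouds) <- labs
  rows <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    nn <- nearest_neighbour(clouds[[i]], clouds[[j]])
    sel <- nn$dist <= gate_mm
    if (sum(sel) < 10) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      a = labs[i], b = labs[j],
      rms_mm = sqrt(mean(nn$dist[sel]^2)), n = sum(sel))
  }
  dplyr::bind_rows(rows)
}
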