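# Conicoid (conic section of revolution) primitives. All phantom surfaces are
# axis-aligned conicoids in the phantom frame: apex at (0, 0, z0), axis +Z,
# signed apex radius R (R > 0 opens towards +Z), conic constant K.
# Sag relation: z - z0 = r^2 / (R (1 + sqrt(1 - (1 + K) r^2 / R^2))).
# Implicit form: F(x, y, z') = x^2 + y^2 - 2 R z' + (1 + K) z'^2 = 0.

conicoid <- function(radius, conic, apex_z, r_max) {
  assert_that(is.finite(radius) && radius != 0, "conicoid apex radius must be non-zero")
  assert_that(r_max > 0, "conicoid r_max must be positive")
  structure(list(radius = radius, conic = conic, apex_z = apex_z, r_max = r_max),
            class = "conicoid")
}

# Sag (z - apex_z) at lateral radius r; NA where the surface is not real.
conicoid_sag <- function(s, r) {
  R <- s$radius
  arg <- 1 - (1 + s$conic) * r^2 / R^2
  out <- rep(NA_real_, length(r))
  ok <- arg >= -1e-12
  out[ok] <- r[ok]^2 / (R * (1 + sqrt(pmax(arg[ok], 0))))
  out
}

# d sag / d r
conicoid_sag_deriv <- function(s, r) {
  R <- s$radius
  arg <- 1 - (1 + s$conic) * r^2 / R^2
  out <- rep(NA_real_, length(r))
  ok <- arg > 0
  # dz/dr = r / (R * sqrt(arg)) in the standard conicoid form
  out[ok] <- r[ok] / (R * sqrt(arg[ok]))
  out
}

# Outward-ish unit normal with sign chosen to point towards -Z at the apex for
# R > 0 (towards the instrument) and towards +Z for R < 0. Input: n x 3 points
# on the surface (phantom frame).
conicoid_normal <- function(s, pts) {
  zp <- pts[, 3] - s$apex_z
  g <- cbind(2 * pts[, 1], 2 * pts[, 2], -2 * s$radius + 2 * (1 + s$conic) * zp)
  n <- normalize_rows(g)
  # gradient z-component at apex is -2R: already -Z for R > 0, +Z for R < 0
  n
}

# Vectorized ray/conicoid intersection. o, d: n x 3 matrices (phantom frame,
# d unit). Returns list(t, point) with NA t where the ray misses the cap
# branch (|r| <= r_max and sag branch between apex and rim).
conicoid_intersect <- function(s, o, d, t_min = 1e-9) {
  R <- s$radius
  Kp <- 1 + s$conic
  oz <- o[, 3] - s$apex_z
  A <- d[, 1]^2 + d[, 2]^2 + Kp * d[, 3]^2
  B <- 2 * (o[, 1] * d[, 1] + o[, 2] * d[, 2]) + 2 * Kp * oz * d[, 3] - 2 * R * d[, 3]
  C <- o[, 1]^2 + o[, 2]^2 + Kp * oz^2 - 2 * R * oz
  n <- nrow(o)
  t_out <- rep(NA_real_, n)
  # branch extent in z' at the rim
  z_rim <- conicoid_sag(s, s$r_max)
  z_lo <- min(0, z_rim) - 1e-7
  z_hi <- max(0, z_rim) + 1e-7
  cand <- matrix(NA_real_, n, 2)
  lin <- !is.na(A) & abs(A) < 1e-14
  lsel <- lin & !is.na(B) & abs(B) > 1e-14
  cand[lsel, 1] <- -C[lsel] / B[lsel]
  disc <- B^2 - 4 * A * C
  qok <- !is.na(disc) & !lin & disc >= 0
  sq <- sqrt(pmax(disc, 0))
  cand[qok, 1] <- (-B[qok] - sq[qok]) / (2 * A[qok])
  cand[qok, 2] <- (-B[qok] + sq[qok]) / (2 * A[qok])
  for (k in 1:2) {
    tk <- cand[, k]
    px <- o[, 1] + tk * d[, 1]
    py <- o[, 2] + tk * d[, 2]
    pz <- o[, 3] + tk * d[, 3] - s$apex_z
    r2 <- px^2 + py^2
    ok <- !is.na(tk) & tk > t_min & r2 <= s$r_max^2 + 1e-9 &
      pz >= z_lo & pz <= z_hi
    take <- ok & (is.na(t_out) | tk < t_out)
    t_out[take] <- tk[take]
  }
  pt <- o + t_out * d
  list(t = t_out, point = pt)
}

# Solve for the shared conic-constant offset that makes two caps of apex radii
# r_ant (front, R > 0 opening +Z) and r_post meet at lateral radius `re` with
# total axial extent `thickness`. Returns the two conic constants.
solve_cap_conics <- function(re, thickness, r_ant, r_post,
                             k_ant0 = 0, k_post0 = 0) {
  sag_sum <- function(delta) {
    sa <- conicoid_sag(conicoid(r_ant, k_ant0 + delta, 0, re), re)
    sp <- conicoid_sag(conicoid(-r_post, k_post0 + delta, 0, re), re)
    if (is.na(sa) || is.na(sp)) return(NA_real_)
    sa - sp
  }
  d_hi <- min(r_ant^2 / re^2 - 1 - k_ant0, r_post^2 / re^2 - 1 - k_post0) - 1e-9
  d_lo <- -60
  f_lo <- sag_sum(d_lo)
  f_hi <- sag_sum(d_hi)
  if (is.na(f_lo) || is.na(f_hi) || (f_lo - thickness) * (f_hi - thickness) > 0) {
    abort(paste0(
      "invalid lens geometry: caps with radii ", r_ant, "/", r_post,
      " cannot intersect at diameter ", 2 * re, " with thickness ", thickness))
  }
  delta <- uniroot(function(d) sag_sum(d) - thickness, c(d_lo, d_hi),
                   tol = 1e-12)$root
  c(k_ant = k_ant0 + delta, k_post = k_post0 + delta)
}
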