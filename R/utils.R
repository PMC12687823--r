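# Internal numerical helpers shared across modules.

SURFACE_LABELS <- c("CA", "CP", "LA", "LP", "IRIS")

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Row-wise euclidean norm of an n x 3 matrix.
row_norm <- function(m) sqrt(rowSums(m^2))

normalize_rows <- function(m) m / row_norm(m)

as_unit <- function(v) {
  n <- sqrt(sum(v^2))
  assert_that(n > 0, "cannot normalize a zero vector")
  v / n
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- as_unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Minimal rotation carrying unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- as_unit(a)
  b <- as_unit(b)
  c_ab <- sum(a * b)
  if (c_ab > 1 - 1e-14) return(diag(3))
  if (c_ab < -1 + 1e-12) {
    # pick any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- as_unit(pracma_cross(a, ref))
    return(rotation_about_axis(axis, pi))
  }
  axis <- pracma_cross(a, b)
  rotation_about_axis(as_unit(axis), acos(max(-1, min(1, c_ab))))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Nearest-neighbour indices (and squared distances) of each row of `query`
# in `ref`. Uses RANN when installed, otherwise a chunked brute-force search
# sized so intermediate distance matrices stay small.
nearest_neighbour <- function(query, ref, chunk = 512L) {
  query <- as.matrix(query)
  ref <- as.matrix(ref)
  if (requireNamespace("RANN", quietly = TRUE)) {
    res <- RANN::nn2(ref, query, k = 1L)
    return(list(index = as.integer(res$nn.idx[, 1]),
                dist = as.numeric(res$nn.dists[, 1])))
  }
  n <- nrow(query)
  idx <- integer(n)
  dst <- numeric(n)
  ref_sq <- rowSums(ref^2)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    q <- query[s:e, , drop = FALSE]
    # squared distances via the expansion |q - r|^2 = |q|^2 - 2 q.r + |r|^2
    d2 <- outer(rowSums(q^2), ref_sq, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dst[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), j)], 0))
  }
  list(index = idx, dist = dst)
}

# Deterministic subsample of at most n rows.
subsample_rows <- function(m, n) {
  if (nrow(m) <= n) return(m)
  keep <- round(seq(1, nrow(m), length.out = n))
  m[keep, , drop = FALSE]
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Evaluate with a local RNG state derived from `seed`, restoring the caller's.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
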