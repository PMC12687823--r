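#' Iterative polynomial artifact rejection for a boundary trace
#'
#' Eyelash-type spikes in a segmented boundary are removed by repeatedly
#' fitting a low-order polynomial of the axial coordinate against the lateral
#' coordinate and discarding samples whose residual exceeds `k_sd` residual
#' standard deviations (3 by default), refitting until no sample is removed
#' or `max_iter` passes have run.
#'
#' @param trace data frame with columns `lateral` and `axial` (any units),
#'   laterally sorted or not.
#' @param poly_order polynomial order (default 4).
#' @param k_sd rejection threshold in residual SDs (default 3).
#' @param max_iter iteration cap (default 10).
#' @returns The surviving rows, laterally sorted, with attributes
#'   `"removed"` (count) and `"iterations"`.
#' @export
reject_artifacts <- function(trace, poly_order = 4, k_sd = 3, max_iter = 10) {
  assert_that(all(c("lateral", "axial") %in% names(trace)),
              "trace must have columns lateral and axial")
  d <- trace[order(trace$lateral), , drop = FALSE]
  d <- d[is.finite(d$lateral) & is.finite(d$axial), , drop = FALSE]
  assert_that(nrow(d) >= poly_order + 2,
              "need at least poly_order + 2 samples")
  removed <- 0L
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    X <- stats::poly(d$lateral, degree = poly_order, raw = TRUE)
    fit <- lm.fit(cbind(1, X), d$axial)
    res <- fit$residuals
    s <- sqrt(sum(res^2) / max(length(res) - poly_order - 1, 1))
    if (s < 1e-12) break
    drop <- abs(res) > k_sd * s
    if (!any(drop)) break
    removed <- removed + sum(drop)
    d <- d[!drop, , drop = FALSE]
    assert_that(nrow(d) >= poly_order + 2, "degenerate trace: all samples removed")
  }
  attr(d, "removed") <- removed
  attr(d, "iterations") <- iters
  d
}

#' Densify sparse manual click-points into a boundary trace
#'
#' C2 cubic-spline interpolation (Forsythe-Malcolm-Moler end conditions) of
#' at least five manually clicked points, evaluated on the A-scan lateral
#' grid. Queries outside the clicked lateral span are flagged missing rather
#' than extrapolated: a region not covered by clicks is treated as invisible
#' and stays missing downstream. On smooth anatomical boundaries the spline
#' stays within the interpolation error of the clicks; a monotone limiter
#' was deliberately not used, as it costs an order of accuracy at curvature
#' extrema such as the surface apex.
#'
#' @param points data frame with columns `lateral`, `axial` (>= 5 rows,
#'   distinct lateral positions).
#' @param grid lateral query positions (the A-scan grid).
#' @returns A tibble with `lateral`, `axial`, `missing`.
#' @export
densify_manual <- function(points, grid) {
  assert_that(all(c("lateral", "axial") %in% names(points)),
              "points must have columns lateral and axial")
  assert_that(nrow(points) >= 5, "at least five manual points are required")
  p <- points[order(points$lateral), ]
  assert_that(!any(duplicated(p$lateral)),
              "duplicate lateral positions in manual points")
  assert_that(diff(range(p$lateral)) > 0, "manual points have no lateral extent")
  inside <- grid >= min(p$lateral) & grid <= max(p$lateral)
  ax <- rep(NA_real_, length(grid))
  if (any(inside)) {
    f <- stats::splinefun(p$lateral, p$axial, method = "fmm")
    ax[inside] <- f(grid[inside])
  }
  tibble::tibble(lateral = grid, axial = ax, missing = !inside)
}

#' Clip a lens trace to the pupil using the iris trace
#'
#' Lens samples lateral to the innermost iris points (the pupil edges) are
#' flagged missing, restricting processing to the region actually visible
#' through the pupil.
#'
#' @param lens_trace data frame with `lateral`, `axial` (and optionally
#'   `missing`).
#' @param iris_trace data frame with `lateral` for the segmented iris; must
#'   contain points on both sides of the pupil (negative and positive
#'   lateral), else the lens trace is returned unchanged.
#' @returns `lens_trace` with an updated `missing` column.
#' @export
clip_to_pupil <- function(lens_trace, iris_trace) {
  out <- lens_trace
  if (!"missing" %in% names(out)) out$missing <- FALSE
  if (is.null(iris_trace) || nrow(iris_trace) == 0) return(out)
  left <- iris_trace$lateral[iris_trace$lateral < 0]
  right <- iris_trace$lateral[iris_trace$lateral > 0]
  if (length(left) == 0 || length(right) == 0) return(out)
  lo <- max(left)   # innermost left iris point
  hi <- min(right)  # innermost right iris point
  out$missing <- out$missing | out$lateral < lo | out$lateral > hi
  out
}
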