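# ggplot2 views of the main result types.

#' @method autoplot lens_polar_grid
#' @export
autoplot.lens_polar_grid <- function(object, ...) {
  pts <- polar_grid_points(object)
  pts$r <- sqrt(pts$x^2 + pts$y^2)
  # meridional profile at two orthogonal azimuths
  j0 <- 1
  j90 <- round(object$Q / 4) + 1
  sel <- pts$phi %in% object$phi[c(j0, j90)] |
    pts$phi %in% ((object$phi[c(j0, j90)] + pi) %% (2 * pi))
  d <- pts[sel, ]
  d$signed_r <- ifelse(cos(d$phi - object$phi[j0]) < 0 |
                         cos(d$phi - object$phi[j90]) < 0, -d$r, d$r)
  d$azimuth <- ifelse(abs(sin(d$phi - object$phi[j0])) < 1e-9, "0 deg",
                      "90 deg")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed_r, y = .data$z,
                                  colour = .data$azimuth)) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (mm)", y = "axial (mm)",
                  title = "Lens meridional profiles") +
    ggplot2::theme_minimal()
}

#' @method autoplot eye_model
#' @export
autoplot.eye_model <- function(object, ...) {
  d <- dplyr::bind_rows(object$points,
                        dplyr::mutate(object$iris, surface = "IRIS"))
  d <- d[abs(d$y) < 0.25, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$z,
                                  colour = .data$surface)) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)",
                  title = sprintf("Eye model (%s, %s) - central section",
                                  object$incidence, object$state)) +
    ggplot2::theme_minimal()
}

#' @method autoplot lens_reconstruction
#' @export
autoplot.lens_reconstruction <- function(object, ...) {
  autoplot(object$shape) +
    ggplot2::labs(subtitle = sprintf("DIA %.2f mm, VOL %.1f mm^3, LSA %.1f mm^2",
                                     object$metrics$dia_mm,
                                     object$metrics$vol_mm3,
                                     object$metrics$lsa_mm2))
}

#' Bland-Altman plot of two methods
#'
#' @param method_a,method_b paired measurements.
#' @param label axis label for the measured quantity.
#' @returns A ggplot.
#' @export
plot_bland_altman <- function(method_a, method_b, label = "value") {
  ba <- bland_altman(method_a, method_b)
  d <- tibble::tibble(mean = (method_a + method_b) / 2,
                      diff = method_a - method_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$md, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = paste("mean", label), y = paste("difference", label),
                  title = sprintf("Bland-Altman: MD %.3g, LoA (%.3g, %.3g)",
                                  ba$md, ba$loa_low, ba$loa_high)) +
    ggplot2::theme_minimal()
}

#' ICP convergence plot
#'
#' @param transform an [icp_refine()] result.
#' @returns A ggplot of trimmed MSE per iteration.
#' @export
plot_icp_history <- function(transform) {
  h <- attr(transform, "history")
  assert_that(!is.null(h), "transform carries no ICP history")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data$mse)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "trimmed MSE (mm^2)",
                  title = "ICP convergence") +
    ggplot2::theme_minimal()
}
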