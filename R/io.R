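#' OCT calibration constants
#'
#' Axial scale 9.2 um/pixel; lateral pitch defaults to the 14 mm scan range
#' divided by 256 A-scans.
#'
#' @param axial_scale um per axial pixel.
#' @param lateral_scale mm per A-scan step.
#' @returns A list of class `oct_calibration`.
#' @export
oct_calibration <- function(axial_scale = 9.2, lateral_scale = 14 / 256) {
  assert_that(axial_scale > 0 && lateral_scale > 0,
              "calibration scales must be positive")
  structure(list(axial_scale = axial_scale, lateral_scale = lateral_scale),
            class = "oct_calibration")
}

#' Convert segmented meridian samples from pixels to millimetres
#'
#' Axial millimetres are `z_px * axial_scale / 1000`; lateral millimetres are
#' `(ascan_index - (n_ascans - 1)/2) * lateral_scale * direction`, so the
#' central A-scan maps to lateral 0 and the direction flag mirrors scans that
#' start from the opposite quadrant. Missing flags are preserved.
#'
#' @param meridians tibble in the segmented-meridian schema (see
#'   [forward_simulate()]).
#' @param cal an [oct_calibration()].
#' @param n_ascans A-scans per B-scan (used for the lateral centre).
#' @returns The input tibble with added columns `lateral_mm` and `z_mm`.
#' @export
pixels_to_mm <- function(meridians, cal = oct_calibration(), n_ascans = 256) {
  centre <- (n_ascans - 1) / 2
  dplyr::mutate(meridians,
    lateral_mm = (.data$ascan_index - centre) * cal$lateral_scale *
      .data$direction,
    z_mm = .data$z_px * cal$axial_scale / 1000)
}

mm_to_pixels <- function(meridians, cal = oct_calibration(), n_ascans = 256) {
  centre <- (n_ascans - 1) / 2
  dplyr::mutate(meridians,
    ascan_index = .data$lateral_mm / (cal$lateral_scale * .data$direction) +
      centre,
    z_px = .data$z_mm * 1000 / cal$axial_scale)
}

#' Map per-meridian samples into the common 3-D instrument frame
#'
#' Each meridian of angle `theta` contributes points
#' `(lateral * cos(theta), lateral * sin(theta), z)`. Meridian angles must lie
#' in `[0, pi)`; angles at exactly `pi` are normalized to 0 with the direction
#' flag flipped.
#'
#' @param meridians tibble with `lateral_mm`, `z_mm` (see [pixels_to_mm()]),
#'   one incidence at a time.
#' @param keep_missing keep rows flagged missing (with `NA` coordinates)?
#' @returns A tibble with columns `surface`, `meridian_index`, `ascan_index`,
#'   `x`, `y`, `z` (mm).
#' @export
map_meridians_to_3d <- function(meridians, keep_missing = FALSE) {
  assert_that(all(c("lateral_mm", "z_mm") %in% names(meridians)),
              "run pixels_to_mm() first (lateral_mm / z_mm missing)")
  dup <- meridians |>
    dplyr::distinct(.data$meridian_index, .data$meridian_angle) |>
    dplyr::count(.data$meridian_index) |>
    dplyr::filter(.data$n > 1)
  assert_that(nrow(dup) == 0,
              paste("duplicate meridian_index with conflicting angles:",
                    paste(dup$meridian_index, collapse = ", ")))
  m <- meridians
  flip <- m$meridian_angle >= pi - 1e-12
  m$meridian_angle[flip] <- m$meridian_angle[flip] - pi
  m$lateral_mm[flip] <- -m$lateral_mm[flip]
  assert_that(all(m$meridian_angle >= 0 & m$meridian_angle < pi),
              "meridian angles must lie in [0, pi)")
  out <- dplyr::transmute(m,
    surface = .data$surface,
    meridian_index = .data$meridian_index,
    ascan_index = .data$ascan_index,
    x = .data$lateral_mm * cos(.data$meridian_angle),
    y = .data$lateral_mm * sin(.data$meridian_angle),
    z = .data$z_mm,
    missing = .data$missing)
  if (!keep_missing) out <- dplyr::filter(out, !.data$missing)
  dplyr::select(out, -"missing")
}

acq_schema <- c("meridian_index", "meridian_angle_rad", "direction",
                "ascan_index", "surface_label", "x_px", "z_px", "missing_flag")

#' Write / read a simulated or segmented acquisition
#'
#' One CSV per incidence (columns `meridian_index`, `meridian_angle_rad`,
#' `direction`, `ascan_index`, `surface_label`, `x_px`, `z_px`,
#' `missing_flag`) plus a JSON sidecar with the protocol metadata. The same
#' schema is the pipeline's input dialect for real segmented data.
#'
#' @param meridians tibble as produced by [forward_simulate()] /
#'   [simulate_protocol()].
#' @param dir output directory (created if needed).
#' @param protocol the [acquisition_protocol()] to record in the sidecar.
#' @returns `write_acquisition()`: invisibly, the written paths.
#' @export
write_acquisition <- function(meridians, dir, protocol = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (inc in unique(meridians$incidence)) {
    d <- meridians[meridians$incidence == inc, ]
    out <- tibble::tibble(
      meridian_index = d$meridian_index,
      meridian_angle_rad = d$meridian_angle,
      direction = d$direction,
      ascan_index = d$ascan_index,
      surface_label = d$surface,
      x_px = d$x_px,
      z_px = d$z_px,
      missing_flag = as.integer(d$missing))
    p <- file.path(dir, paste0("incidence_", inc, ".csv"))
    readr::write_csv(out, p, progress = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(protocol)) {
    meta <- unclass(protocol)
    meta$orientations <- as.data.frame(protocol$orientations)
    gz <- attr(meridians, "gaze")
    if (!is.null(gz)) {
      if (!is.null(gz$axis)) gz <- setNames(list(gz), unique(meridians$incidence)[1])
      meta$gaze <- lapply(gz, function(g)
        list(axis = g$axis, angle_deg = g$angle_deg, centre = g$centre))
    }
    jp <- file.path(dir, "protocol.json")
    jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, jp)
  }
  invisible(paths)
}

#' @rdname write_acquisition
#' @param path directory holding `incidence_*.csv` (and optionally
#'   `protocol.json`).
#' @returns `read_acquisition()`: the meridian tibble (all incidences), with
#'   the protocol metadata attached as attribute `"protocol_meta"` when the
#'   sidecar is present.
#' @export
read_acquisition <- function(path) {
  files <- list.files(path, pattern = "^incidence_.*\\.csv$", full.names = TRUE)
  assert_that(length(files) > 0, paste("no incidence_*.csv files in", path))
  sets <- lapply(files, function(f) {
    d <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    missing_cols <- setdiff(acq_schema, names(d))
    assert_that(length(missing_cols) == 0,
                paste0(basename(f), " lacks columns: ",
                       paste(missing_cols, collapse = ", ")))
    bad <- setdiff(unique(d$surface_label), SURFACE_LABELS)
    assert_that(length(bad) == 0,
                paste0(basename(f), " has unknown surface labels: ",
                       paste(bad, collapse = ", ")))
    inc <- sub("^incidence_(.*)\\.csv$", "\\1", basename(f))
    tibble::tibble(
      incidence = inc,
      meridian_index = as.integer(d$meridian_index),
      meridian_angle = d$meridian_angle_rad,
      direction = as.integer(d$direction),
      ascan_index = as.integer(d$ascan_index),
      surface = d$surface_label,
      x_px = d$x_px,
      z_px = d$z_px,
      missing = as.logical(d$missing_flag))
  })
  out <- dplyr::bind_rows(sets)
  jp <- file.path(path, "protocol.json")
  if (file.exists(jp)) {
    attr(out, "protocol_meta") <- jsonlite::read_json(jp, simplifyVector = TRUE)
  }
  out
}

#' Write a reconstructed per-incidence model
#'
#' Surface point sets go to one CSV, the iris to another, and an ASCII PLY
#' point cloud is written for visual inspection.
#'
#' @param model an `eye_model`.
#' @param dir output directory.
#' @returns Invisibly, the written paths.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "surfaces.csv")
  readr::write_csv(model$points, pp, progress = FALSE)
  ip <- file.path(dir, "iris.csv")
  readr::write_csv(model$iris, ip, progress = FALSE)
  mp <- file.path(dir, "model.json")
  jsonlite::write_json(list(incidence = model$incidence, state = model$state),
                       mp, auto_unbox = TRUE)
  ply <- file.path(dir, "points.ply")
  write_ply(as.matrix(model$points[, c("x", "y", "z")]), faces = NULL, ply)
  invisible(c(pp, ip, mp, ply))
}

#' @rdname write_model
#' @export
read_model_points <- function(dir) {
  readr::read_csv(file.path(dir, "surfaces.csv"), show_col_types = FALSE,
                  progress = FALSE)
}

# Minimal ASCII PLY writer (point cloud or triangle mesh).
write_ply <- function(vertices, faces = NULL, path) {
  vertices <- as.matrix(vertices)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(vertices)),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(faces)) {
    writeLines(c(paste("element face", nrow(faces)),
                 "property list uchar int vertex_indices"), con)
  }
  writeLines("end_header", con)
  writeLines(sprintf("%.6f %.6f %.6f", vertices[, 1], vertices[, 2],
                     vertices[, 3]), con)
  if (!is.null(faces)) {
    writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                       faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Reads and validates a YAML configuration. Unknown keys are rejected with
#' the offending name; `media` is required.
#'
#' @param path YAML file.
#' @returns A validated config list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param overrides named list merged over the defaults.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    media = list(n_air = 1.0, n_cornea = 1.385, n_aqueous = 1.345,
                 n_lens = 1.417),
    zernike_terms = 15,
    icp = list(max_iter = 100, tol = 1e-8, trim_fraction = 0.2, gate_mm = 0.5),
    eigenlens = list(K = 6, P = 100, Q = 100, n_train = 80, seed = 20240101),
    correct_iris = TRUE,
    rng_seed = 1
  )
  cfg <- utils::modifyList(cfg, overrides)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known <- c("media", "zernike_terms", "icp", "eigenlens", "correct_iris",
             "rng_seed", "paths", "protocol")
  unknown <- setdiff(names(cfg), known)
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  for (req in c("media")) {
    assert_that(!is.null(cfg[[req]]), paste0("config key '", req, "' is required"))
  }
  med <- cfg$media
  for (k in c("n_cornea", "n_aqueous", "n_lens")) {
    assert_that(!is.null(med[[k]]), paste0("config key 'media.", k, "' is required"))
  }
  cfg$media <- optical_media(med$n_air %||% 1.0, med$n_cornea, med$n_aqueous,
                             med$n_lens)
  structure(cfg, class = "pipeline_config")
}

#' Read a deposited per-subject morphometry table
#'
#' Ingests tables of per-subject DIA / VOL / LSA (and optionally age and a
#' second method's values) for the statistics module. CSV is the canonical
#' dialect; `.xlsx` sheets are read through readxl when installed.
#'
#' @param path CSV or XLSX file with a header row.
#' @param sheet sheet name or index for XLSX input.
#' @returns A tibble with lower-cased column names.
#' @export
read_cohort_table <- function(path, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  d <- if (ext %in% c("xlsx", "xls")) {
    assert_that(requireNamespace("readxl", quietly = TRUE),
                "reading .xlsx needs the readxl package")
    readxl::read_excel(path, sheet = sheet)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  names(d) <- tolower(names(d))
  tibble::as_tibble(d)
}
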