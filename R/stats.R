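# Repeatability and agreement statistics.

#' Coefficient of variation of repeated measurements
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation, the
#' convention that reproduces repeatability CVs of repeated ocular biometry
#' to their printed precision.
#'
#' @param values numeric vector of at least two repeated measurements.
#' @returns CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  assert_that(length(values) >= 2, "need at least 2 repeated measurements")
  m <- mean(values)
  assert_that(abs(m) > .Machine$double.eps, "mean of values is zero")
  100 * sd(values) / m
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Midranks handle ties. For n <= 9 the two-sided p-value is computed by
#' exhaustive enumeration of all permutations of one rank vector; for larger
#' n the usual t-approximation on the rank correlation is used.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @returns A one-row tibble with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_rank <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  rho <- rank_cor(rx, ry)
  if (n <= 9) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) rank_cor(rx, ry[p]))
    p_val <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p_val <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = p_val, n = n, method = method)
}

rank_cor <- function(rx, ry) {
  sx <- sd(rx); sy <- sd(ry)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((length(rx) - 1) * sx * sy)
}

# All permutations of 1..n as an (n!) x n matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, setdiff(seq_len(n), pos)] <- sub
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Bland-Altman agreement between two methods
#'
#' Differences `a - b`; mean difference (MD) and limits of agreement
#' MD +/- 1.96 x SD of the differences (sample SD).
#'
#' @param method_a,method_b paired numeric vectors.
#' @returns A one-row tibble with `md`, `loa_low`, `loa_high`, `sd_diff`,
#'   `n`.
#' @export
bland_altman <- function(method_a, method_b) {
  assert_that(length(method_a) == length(method_b),
              "method vectors must have equal length")
  ok <- is.finite(method_a) & is.finite(method_b)
  d <- method_a[ok] - method_b[ok]
  assert_that(length(d) >= 2, "need at least 2 paired values")
  md <- mean(d)
  s <- sd(d)
  tibble::tibble(md = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 sd_diff = s, n = length(d))
}

#' Shapiro-Wilk normality gate
#'
#' Tests normality and routes the analysis: when p < alpha the variable is
#' flagged for non-parametric summaries (as done for lens volume in vivo).
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha decision level (default 0.05).
#' @returns A one-row tibble with `W`, `p_value`, `n`, `normal` (logical).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  assert_that(n >= 3 && n <= 5000, "Shapiro-Wilk needs 3 <= n <= 5000")
  assert_that(sd(values) > 0, "values are constant; normality is undefined")
  sw <- shapiro.test(values)
  tibble::tibble(W = unname(sw$statistic), p_value = sw$p.value, n = n,
                 normal = sw$p.value >= alpha)
}

#' Cohort statistics report
#'
#' For a per-subject table of geometric parameters: Shapiro-Wilk screen per
#' parameter, Spearman correlation of each parameter with age, and (when a
#' second method's columns `<param>_b` are present) Bland-Altman agreement.
#'
#' @param cohort tibble with column `age` and parameter columns (e.g.
#'   `dia_mm`, `vol_mm3`, `lsa_mm2`), optionally `<param>_b` counterparts.
#' @param params parameter column names.
#' @returns A list of tibbles: `normality`, `age_correlation`, `agreement`.
#' @export
cohort_stats <- function(cohort, params = intersect(
                           c("dia_mm", "vol_mm3", "lsa_mm2"), names(cohort))) {
  assert_that(length(params) > 0, "no parameter columns found")
  normality <- purrr::map_dfr(params, function(p)
    dplyr::mutate(normality_gate(cohort[[p]]), parameter = p, .before = 1))
  age_cor <- NULL
  if ("age" %in% names(cohort)) {
    age_cor <- purrr::map_dfr(params, function(p)
      dplyr::mutate(spearman_rank(cohort$age, cohort[[p]]),
                    parameter = p, .before = 1))
  }
  agree <- NULL
  with_b <- params[paste0(params, "_b") %in% names(cohort)]
  if (length(with_b) > 0) {
    agree <- purrr::map_dfr(with_b, function(p)
      dplyr::mutate(bland_altman(cohort[[paste0(p, "_b")]], cohort[[p]]),
                    parameter = p, .before = 1))
  }
  list(normality = normality, age_correlation = age_cor, agreement = agree)
}
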