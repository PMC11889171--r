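#' Halving subset-size series
#'
#' Series of particle subset sizes used for a Rosenthal-Henderson plot:
#' the full group size, then repeated halving (floor), truncated before
#' falling below `min_particles`.
#'
#' @param total_n group size.
#' @param min_particles smallest admissible subset (default 400; groups
#'   below this are rejected, as reliable resolutions cannot be derived
#'   from fewer particles).
#' @return decreasing integer vector of subset sizes.
#' @export
subset_series <- function(total_n, min_particles = 400) {
  if (!is_scalar_number(total_n) || total_n < min_particles) {
    abort_fib(sprintf(
      "group size %s is below the minimum of %d particles",
      format(total_n), min_particles), "fib_insufficient_particles")
  }
  sizes <- integer()
  n <- as.integer(total_n)
  while (n >= min_particles) {
    sizes <- c(sizes, n)
    n <- n %/% 2L
  }
  sizes
}

#' Inverse-square resolution transform
#'
#' The ordinate of a Rosenthal-Henderson plot: `y = 1/resolution^2`
#' (1/A^2). When a resolution standard error is supplied it is propagated
#' as `sigma_y = 2 sigma_res / res^3`.
#'
#' @param resolution_A resolution(s) in angstrom (> 0).
#' @param sigma_res optional standard error(s) of the resolution.
#' @return numeric `y`, or a tibble with `y` and `sigma_y` when
#'   `sigma_res` is given.
#' @export
inverse_sq_transform <- function(resolution_A, sigma_res = NULL) {
  if (any(!is.finite(resolution_A)) || any(resolution_A <= 0)) {
    abort_fib("resolution must be positive", "fib_format_error")
  }
  y <- resolution_A^-2
  if (is.null(sigma_res)) return(y)
  tibble::tibble(y = y, sigma_y = 2 * sigma_res / resolution_A^3)
}

#' Construct a resolution series
#'
#' Records feeding a B-factor fit: one row per (repeat, subset size) with
#' the resolution obtained from that subset.
#'
#' @param group group label.
#' @param repeats integer repeat index per row.
#' @param n_particles subset size per row.
#' @param resolution_A resolution per row, angstrom.
#' @param min_particles admissibility floor for subset sizes.
#' @return tibble of class `resolution_series`.
#' @export
resolution_series <- function(group, repeats, n_particles, resolution_A,
                              min_particles = 400) {
  df <- tibble::tibble(group = group, repeat_index = as.integer(repeats),
                       n_particles = as.integer(n_particles),
                       resolution_A = as.numeric(resolution_A))
  if (any(df$n_particles < min_particles)) {
    abort_fib(sprintf("subset sizes below the minimum of %d particles",
                      min_particles), "fib_insufficient_particles")
  }
  if (any(df$resolution_A <= 0)) {
    abort_fib("resolutions must be positive", "fib_format_error")
  }
  if (length(unique(df$n_particles)) < 2) {
    abort_fib("need at least 2 distinct subset sizes", "fib_format_error")
  }
  class(df) <- unique(c("resolution_series", class(df)))
  df
}

#' Rosenthal-Henderson linear fit
#'
#' Ordinary least squares of `1/resolution^2` on `ln(particle number)`,
#' pooled over all repeats' points. Standard errors are the usual OLS
#' standard errors of slope and intercept.
#'
#' @param series a [resolution_series()] (or tibble with `n_particles` and
#'   `resolution_A`) for one group.
#' @return list of class `linear_fit` with `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `n_points`, `r_squared`.
#' @export
rh_fit <- function(series) {
  df <- tibble::as_tibble(series)
  if (nrow(df) < 4) {
    abort_fib("need at least 4 points for a Rosenthal-Henderson fit",
              "fib_insufficient_particles")
  }
  if (length(unique(df$n_particles)) < 2) {
    abort_fib("degenerate abscissa: all points at one subset size",
              "fib_format_error")
  }
  x <- log(df$n_particles)
  y <- inverse_sq_transform(df$resolution_A)
  fit <- lm(y ~ x)
  # summary() warns on exact fits; zero SEs are a legitimate outcome here
  sm <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    se_slope = sm$coefficients["x", "Std. Error"],
    se_intercept = sm$coefficients["(Intercept)", "Std. Error"],
    n_points = nrow(df),
    r_squared = sm$r.squared
  ), class = "linear_fit")
}

#' Construct a linear fit from known coefficients
#'
#' Used for worked examples where a published B-factor and one
#' (particle count, resolution) anchor define the line: slope `2/B`
#' (SE `2 sigma_B / B^2`), intercept chosen so the line passes through the
#' anchor (its SE 0, as the anchor is taken as exact).
#'
#' @param bfactor_A2,sigma_B B-factor and its SE, A^2.
#' @param anchor_n particle count of the anchoring measurement.
#' @param anchor_resolution_A resolution of the anchoring measurement, A.
#' @return a `linear_fit`.
#' @export
anchored_fit_from_bfactor <- function(bfactor_A2, sigma_B, anchor_n,
                                      anchor_resolution_A) {
  if (bfactor_A2 == 0) abort_fib("B-factor must be nonzero",
                                 "fib_format_error")
  m <- 2 / bfactor_A2
  structure(list(
    slope = m,
    intercept = inverse_sq_transform(anchor_resolution_A) - m * log(anchor_n),
    se_slope = 2 * sigma_B / bfactor_A2^2,
    se_intercept = 0,
    n_points = 1L,
    r_squared = NA_real_
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit: y = %.4g ln(N) %+.4g, se(m) = %.3g, n = %d>\n",
              x$slope, x$intercept, x$se_slope, x$n_points))
  invisible(x)
}

#' B-factor from a Rosenthal-Henderson fit
#'
#' `B = 2/slope` (A^2), with its standard error obtained by propagating
#' the slope's standard error: `sigma_B = 2 sigma_m / m^2`.
#'
#' @param fit a `linear_fit` from [rh_fit()].
#' @param group optional group label carried into the result.
#' @return list of class `bfactor_result` with `B`, `sigma_B`, `fit`,
#'   `group`.
#' @export
bfactor_from_fit <- function(fit, group = NA_character_) {
  stopifnot(inherits(fit, "linear_fit"))
  if (fit$slope == 0) abort_fib("zero slope: B-factor undefined",
                                "fib_format_error")
  structure(list(
    B = 2 / fit$slope,
    sigma_B = 2 * fit$se_slope / fit$slope^2,
    fit = fit,
    group = group
  ), class = "bfactor_result")
}

#' @export
print.bfactor_result <- function(x, ...) {
  cat(sprintf("<bfactor_result%s: B = %.1f +- %.1f A^2>\n",
              if (is.na(x$group)) "" else paste0(" '", x$group, "'"),
              x$B, x$sigma_B))
  invisible(x)
}
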