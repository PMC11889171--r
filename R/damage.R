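#' B-factor ratio between a depth group and its matched control
#'
#' `ratio = B_group / B_control`, with standard error propagated from the
#' two B-factor SEs:
#' `sigma = ratio * sqrt((sigma_g/B_g)^2 + (sigma_c/B_c)^2)`.
#'
#' @param B_group,sigma_group group B-factor and SE (A^2).
#' @param B_control,sigma_control matched-control B-factor and SE (A^2).
#' @return tibble with `ratio` and `sigma`.
#' @export
bfactor_ratio <- function(B_group, sigma_group, B_control, sigma_control) {
  if (any(B_control == 0)) abort_fib("control B-factor is zero",
                                     "fib_format_error")
  ratio <- B_group / B_control
  sigma <- abs(ratio) * sqrt((sigma_group / B_group)^2 +
                               (sigma_control / B_control)^2)
  tibble::tibble(ratio = ratio, sigma = sigma)
}

#' Extrapolate resolution to a target particle number
#'
#' Evaluates a Rosenthal-Henderson line at `x = ln(target_n)`:
#' `y* = m x + c`, resolution `1/sqrt(y*)`. The error in predicted y is
#' `sigma_y = sqrt((sigma_m x)^2 + sigma_c^2)` (no slope-intercept
#' covariance term), propagated to the resolution as
#' `sigma_res = sigma_y / (2 y*^(3/2))`.
#'
#' @param fit a `linear_fit`.
#' @param target_n particle number to extrapolate to (default 5000).
#' @return tibble with `resolution_A`, `sigma`, `y`, `sigma_y`.
#' @export
extrapolate_resolution <- function(fit, target_n = 5000) {
  stopifnot(inherits(fit, "linear_fit"))
  x <- log(target_n)
  y_star <- fit$slope * x + fit$intercept
  if (y_star <= 0) {
    abort_fib("extrapolation beyond validity: predicted 1/res^2 <= 0",
              "fib_extrapolation_error")
  }
  sigma_y <- sqrt((fit$se_slope * x)^2 + fit$se_intercept^2)
  tibble::tibble(
    resolution_A = 1 / sqrt(y_star),
    sigma = sigma_y / (2 * y_star^1.5),
    y = y_star,
    sigma_y = sigma_y
  )
}

#' Extrapolated resolution difference
#'
#' `delta = res_group - res_control` (A), with
#' `sigma = sqrt(sigma_group^2 + sigma_control^2)`.
#'
#' @param res_group,sigma_group group extrapolated resolution and SE.
#' @param res_control,sigma_control control extrapolated resolution and SE.
#' @return tibble with `delta` and `sigma`.
#' @export
resolution_difference <- function(res_group, sigma_group,
                                  res_control, sigma_control) {
  tibble::tibble(delta = res_group - res_control,
                 sigma = sqrt(sigma_group^2 + sigma_control^2))
}

#' Weighted three-parameter exponential decay fit
#'
#' Fits `y = A exp(-k x) + c` by least squares weighted `1/SE^2`
#' (Levenberg-Marquardt). Initialisation: `A = y_first - y_last`, `c =
#' y_last`, `k` from the log-ratio of the first two (offset-corrected)
#' points. R-squared is reported unweighted on the fitted values; a
#' weighted R-squared is also returned for transparency.
#'
#' @param x abscissa (depth bin midpoints, nm).
#' @param y values (B-factor ratios or resolution differences).
#' @param se standard errors of `y` (all > 0).
#' @return list of class `decay_fit` with `A`, `k`, `c`, `se_A`, `se_k`,
#'   `se_c`, `r_squared`, `r_squared_weighted`, `converged`.
#' @export
fit_exponential_decay <- function(x, y, se) {
  if (length(x) < 4) abort_fib("need at least 4 points for a decay fit",
                               "fib_insufficient_particles")
  if (length(y) != length(x) || length(se) != length(x)) {
    abort_fib("x, y and se must have equal length", "fib_format_error")
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    abort_fib("all standard errors must be positive (weights are 1/SE^2)",
              "fib_format_error")
  }
  if (diff(range(y)) == 0) abort_fib("no decay signal: constant values",
                                     "fib_format_error")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; se <- se[ord]
  c0 <- y[length(y)]
  A0 <- y[1] - c0
  r1 <- y[1] - c0; r2 <- y[2] - c0
  k0 <- if (is.finite(r1 / r2) && r1 / r2 > 0) {
    log(r1 / r2) / (x[2] - x[1])
  } else NA_real_
  if (!is.finite(k0) || k0 <= 0) k0 <- 3 / diff(range(x))
  if (A0 == 0) A0 <- diff(range(y))
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-k * x) + c, data = dat,
      start = list(A = A0, k = k0, c = c0),
      weights = 1 / se^2,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(A = NA_real_, k = NA_real_, c = NA_real_,
                          se_A = NA_real_, se_k = NA_real_, se_c = NA_real_,
                          r_squared = NA_real_,
                          r_squared_weighted = NA_real_,
                          converged = FALSE),
                     class = "decay_fit"))
  }
  cf <- coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 3))
  yhat <- predict(fit)
  w <- 1 / se^2
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  ybar_w <- sum(w * y) / sum(w)
  r2w <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar_w)^2)
  structure(list(
    A = unname(cf["A"]), k = unname(cf["k"]), c = unname(cf["c"]),
    se_A = unname(ses["A"]), se_k = unname(ses["k"]), se_c = unname(ses["c"]),
    r_squared = r2, r_squared_weighted = r2w,
    converged = fit$convInfo$isConv %||% TRUE
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit: y = %.4g exp(-%.4g x) %+.4g, R^2 = %.3f%s>\n",
    x$A, x$k, x$c, x$r_squared,
    if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' Spearman rank trend across ordered bins
#'
#' Spearman rank correlation of values against bin order, with
#' average-rank tie handling. The two-sided p-value is exact (full
#' permutation enumeration) for n <= 8 and uses the t approximation
#' otherwise.
#'
#' @param values numeric values in bin order.
#' @return list with `r` and `p_value`.
#' @export
spearman_trend <- function(values) {
  n <- length(values)
  if (n < 3) abort_fib("need at least 3 bins for a trend",
                       "fib_insufficient_particles")
  rk <- rank(values)  # average ranks for ties
  r_obs <- cor(rk, seq_len(n))
  if (n <= 8) {
    perms <- permutations_of(n)
    r_all <- apply(perms, 1, function(p) cor(rk[p], seq_len(n)))
    p_val <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  } else {
    tstat <- r_obs * sqrt((n - 2) / (1 - r_obs^2))
    p_val <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r_obs, p_value = min(1, p_val))
}

# All permutations of 1..n as a matrix (n! rows); n is small (<= 8).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      perm <- append(sub[r, ], n, after = pos - 1L)
      out[row, ] <- perm
      row <- row + 1L
    }
  }
  out
}

#' Backside damage summary
#'
#' Extremes of the per-bin B-factors over the backside distance groups,
#' plus the Spearman trend of B-factor against bin order.
#'
#' @param bfactors numeric B-factors in bin order (A^2).
#' @return list with `min_B`, `max_B`, `spearman_r`, `spearman_p`.
#' @export
backside_group_summary <- function(bfactors) {
  if (length(bfactors) < 2) {
    abort_fib("need at least 2 bins", "fib_insufficient_particles")
  }
  trend <- if (length(bfactors) >= 3) spearman_trend(bfactors) else
    list(r = NA_real_, p_value = NA_real_)
  list(min_B = min(bfactors), max_B = max(bfactors),
       spearman_r = trend$r, spearman_p = trend$p_value)
}

#' Mean length of an amorphous backside region
#'
#' Shoelace area of the segmented region divided by its extent along the
#' axis perpendicular to the milling direction - the standard way of
#' reducing an irregular segmented strip to a mean length.
#'
#' @param region_polygon two-column matrix/data frame of polygon vertices
#'   (um), in order, not self-intersecting.
#' @param milling_axis `"x"` or `"y"`: the direction of milling; the
#'   perpendicular extent is measured along the other axis.
#' @return mean length in micrometres.
#' @export
amorphous_length <- function(region_polygon, milling_axis = c("y", "x")) {
  milling_axis <- match.arg(milling_axis)
  poly <- as.matrix(as.data.frame(region_polygon))
  if (nrow(poly) < 3) abort_fib("degenerate polygon: fewer than 3 vertices",
                                "fib_format_error")
  if (polygon_self_intersects(poly)) {
    abort_fib("self-intersecting polygon", "fib_format_error")
  }
  xs <- poly[, 1]; ys <- poly[, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  perp <- if (milling_axis == "y") diff(range(xs)) else diff(range(ys))
  if (perp <= 0) abort_fib("zero extent perpendicular to the milling axis",
                           "fib_format_error")
  area / perp
}

# O(n^2) proper-crossing test over non-adjacent edges.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4],
                   seg[j, 1], seg[j, 2])
      d2 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4],
                   seg[j, 3], seg[j, 4])
      d3 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4],
                   seg[i, 1], seg[i, 2])
      d4 <- cross2(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4],
                   seg[i, 3], seg[i, 4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Two-sample comparison of amorphous lengths
#'
#' Welch's two-sample t-test (default), computable either from raw values
#' or from summary statistics (mean, SD, n). A pooled-variance t-test and
#' (for raw values) a Wilcoxon rank-sum test are selectable.
#'
#' @param a,b numeric vectors of raw lengths, or lists
#'   `list(mean =, sd =, n =)` of summary statistics.
#' @param method `"welch"`, `"pooled"` or `"wilcoxon"`.
#' @return list with `t` (or `W`), `df`, `p_value`, `method`.
#' @export
compare_length_groups <- function(a, b, method = c("welch", "pooled",
                                                   "wilcoxon")) {
  method <- match.arg(method)
  summarise_arg <- function(v) {
    if (is.list(v)) {
      list(mean = v$mean, sd = v$sd, n = v$n, raw = NULL)
    } else {
      if (length(v) < 2) abort_fib("each group needs n >= 2",
                                   "fib_insufficient_particles")
      list(mean = mean(v), sd = sd(v), n = length(v), raw = v)
    }
  }
  sa <- summarise_arg(a); sb <- summarise_arg(b)
  if (sa$n < 2 || sb$n < 2) abort_fib("each group needs n >= 2",
                                      "fib_insufficient_particles")
  if (method == "wilcoxon") {
    if (is.null(sa$raw) || is.null(sb$raw)) {
      abort_fib("wilcoxon requires raw values", "fib_format_error")
    }
    wt <- stats::wilcox.test(sa$raw, sb$raw)
    return(list(W = unname(wt$statistic), df = NA_real_,
                p_value = wt$p.value, method = "wilcoxon"))
  }
  va <- sa$sd^2 / sa$n; vb <- sb$sd^2 / sb$n
  if (method == "welch") {
    tstat <- (sa$mean - sb$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  } else {
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) /
      (sa$n + sb$n - 2)
    tstat <- (sa$mean - sb$mean) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  }
  list(t = tstat, df = df, p_value = 2 * pt(-abs(tstat), df = df),
       method = method)
}
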