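#' Fourier shell correlation between two half maps
#'
#' Computes the normalised cross-correlation of the two volumes' Fourier
#' transforms in integer-radius shells of width one Fourier voxel (DC
#' excluded), up to the Nyquist shell. No masking or phase-randomisation
#' correction is applied. Shells with zero variance in either half are
#' recorded as correlation 0 with a flag.
#'
#' @param half_a,half_b [volume_grid()] objects with identical dimensions
#'   and voxel size.
#' @return tibble of class `fsc_curve` with columns `shell`, `freq`
#'   (1/A at shell centre), `fsc`, `n_voxels`, `zero_variance`; the voxel
#'   size is attached as attribute `voxel_size_A`.
#' @export
fsc_curve <- function(half_a, half_b) {
  stopifnot(inherits(half_a, "volume_grid"), inherits(half_b, "volume_grid"))
  da <- dim(half_a$data); db <- dim(half_b$data)
  if (!identical(da, db)) {
    abort_fib("half maps have different dimensions", "fib_format_error")
  }
  if (abs(half_a$voxel_size_A - half_b$voxel_size_A) > 1e-9) {
    abort_fib("half maps have different voxel sizes", "fib_format_error")
  }
  fa <- fft(half_a$data)
  fb <- fft(half_b$data)
  shell <- fourier_shell_index(da)
  n_ref <- min(da)
  n_shell <- n_ref %/% 2
  keep <- shell >= 1L & shell <= n_shell
  sh <- shell[keep]
  shells <- sort(unique(sh))
  shf <- factor(sh, levels = shells)
  cross <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2
  num <- as.numeric(tapply(cross, shf, sum))
  va <- as.numeric(tapply(pa, shf, sum))
  vb <- as.numeric(tapply(pb, shf, sum))
  nvox <- as.integer(tapply(sh, shf, length))
  zero_var <- va <= 0 | vb <= 0
  fsc <- ifelse(zero_var, 0, num / sqrt(pmax(va, .Machine$double.xmin) *
                                          pmax(vb, .Machine$double.xmin)))
  out <- tibble::tibble(
    shell = shells,
    freq = shells / (n_ref * half_a$voxel_size_A),
    fsc = fsc,
    n_voxels = nvox,
    zero_variance = zero_var
  )
  attr(out, "voxel_size_A") <- half_a$voxel_size_A
  class(out) <- unique(c("fsc_curve", class(out)))
  out
}

# Integer shell index for every voxel of an FFT array: the radius (rounded)
# in units of the reference (smallest) dimension's Fourier voxel, using
# wrapped frequencies so rectangular grids bin on normalised |k|.
fourier_shell_index <- function(dims) {
  n_ref <- min(dims)
  axis_freq <- function(n) {
    k <- 0:(n - 1)
    pmin(k, n - k) / n
  }
  fx <- axis_freq(dims[1]); fy <- axis_freq(dims[2]); fz <- axis_freq(dims[3])
  r2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  as.integer(round(sqrt(r2) * n_ref))
}

#' Resolution at an FSC threshold
#'
#' Reads resolution as 1/f* where f* is the first downward crossing of the
#' threshold, located by linear interpolation between adjacent shells (a
#' shell exactly at the threshold counts as crossed). Curves that never
#' fall below the threshold are capped at the Nyquist resolution; curves
#' already below the threshold at the first shell return a flagged
#' sentinel (`NA`).
#'
#' @param curve an [fsc_curve()], or tibble with `freq` and `fsc` columns.
#' @param threshold FSC criterion (default 0.143).
#' @param voxel_size_A voxel size; default from the curve's attribute.
#' @return list with `resolution_A`, `capped`, `below_first_shell`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143,
                                    voxel_size_A = NULL) {
  if (nrow(curve) == 0) abort_fib("empty FSC curve", "fib_empty_input")
  voxel_size_A <- voxel_size_A %||% attr(curve, "voxel_size_A")
  f <- curve$freq; v <- curve$fsc
  if (is.unsorted(f, strictly = TRUE)) {
    abort_fib("FSC curve frequencies must be strictly increasing",
              "fib_format_error")
  }
  below <- which(v <= threshold)
  if (length(below) == 0) {
    if (is.null(voxel_size_A)) {
      abort_fib("voxel size needed for the Nyquist cap", "fib_format_error")
    }
    return(list(resolution_A = nyquist_resolution(voxel_size_A),
                capped = TRUE, below_first_shell = FALSE))
  }
  i <- below[1]
  if (i == 1) {
    return(list(resolution_A = NA_real_, capped = FALSE,
                below_first_shell = TRUE))
  }
  f_star <- f[i - 1] + (v[i - 1] - threshold) / (v[i - 1] - v[i]) *
    (f[i] - f[i - 1])
  list(resolution_A = 1 / f_star, capped = FALSE, below_first_shell = FALSE)
}

#' Nyquist resolution for a sampling rate
#'
#' The best resolution representable at a given voxel size: twice the
#' voxel size (e.g. 1.90 A/px gives 3.8 A).
#'
#' @param voxel_size_A voxel size in angstrom (> 0).
#' @return resolution in angstrom.
#' @export
nyquist_resolution <- function(voxel_size_A) {
  if (!is_scalar_number(voxel_size_A) || voxel_size_A <= 0) {
    abort_fib("voxel size must be positive", "fib_format_error")
  }
  2 * voxel_size_A
}

#' Write an FSC curve to CSV
#'
#' @param curve an [fsc_curve()].
#' @param path output CSV path.
#' @export
write_fsc_csv <- function(curve, path) {
  write.csv(as.data.frame(curve)[, c("freq", "fsc", "n_voxels")], path,
            row.names = FALSE)
  invisible(path)
}
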