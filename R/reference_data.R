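#' Bundled reference B-factor measurements
#'
#' Per-distance-group B-factor analyses from a xenon plasma FIB milling
#' damage experiment on ribosomes in high-pressure frozen *E. coli*
#' lamellae, shipped with the package as worked-example inputs. B-factors
#' are reported as mean +- SE over n = 3 technical replicates of the
#' subset-series analysis; the resolution column is the full-group global
#' resolution for one replicate.
#'
#' `reference_backside_table()` holds the five 1-um distance groups from
#' the backside amorphous boundary; `reference_surface_table()` holds the
#' 5-nm milling-surface distance groups (with their tomogram-matched
#' controls) and the three 10,000-particle threshold comparison sets. The
#' shallowest (0-5 nm) surface group has no B-factor: its 25 particles are
#' below the 400-particle minimum for a reliable fit.
#'
#' @return a tibble.
#' @export
reference_backside_table <- function() {
  path <- system.file("extdata", "backside_bfactors.csv",
                      package = "fibdamage", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname reference_backside_table
#' @export
reference_surface_table <- function() {
  path <- system.file("extdata", "surface_bfactors.csv",
                      package = "fibdamage", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Backside damage worked example
#'
#' Runs the backside damage summary on the bundled reference table:
#' B-factor extremes across the 1-um distance groups and the Spearman
#' trend of B-factor against distance from the amorphous boundary.
#'
#' @param table reference table; defaults to [reference_backside_table()].
#' @return list with `table`, `min_B`, `max_B`, `spearman_r`, `spearman_p`.
#' @export
backside_worked_example <- function(table = reference_backside_table()) {
  s <- backside_group_summary(table$bfactor_A2)
  c(list(table = table), s)
}

#' Surface damage worked example
#'
#' Reconstructs the full depth-damage analysis from the bundled reference
#' surface table: per-row Rosenthal-Henderson lines (slope `2/B`, anchored
#' at the row's particle count and global resolution), extrapolation of
#' group and matched control to `target_n` particles, their difference,
#' the B-factor ratio curve, and weighted three-parameter exponential
#' decay fits of both curves against depth-bin midpoints.
#'
#' @param table reference table; defaults to [reference_surface_table()].
#' @param target_n extrapolation particle number (default 5000).
#' @return list with `points` (per-bin tibble: midpoints, ratios,
#'   resolution differences, SEs), `dres_fit` and `ratio_fit`
#'   (`decay_fit` objects).
#' @export
surface_worked_example <- function(table = reference_surface_table(),
                                   target_n = 5000) {
  df <- table[grepl("^depth_", table$group) & !is.na(table$bfactor_A2), ]
  groups <- df[df$set == "group", ]
  controls <- df[df$set == "control", ]
  stopifnot(identical(groups$group, controls$group))
  mid <- (groups$lower_nm + groups$upper_nm) / 2
  extrap <- function(row) {
    fit <- anchored_fit_from_bfactor(row$bfactor_A2, row$bfactor_se_A2,
                                     row$n_particles, row$resolution_A)
    extrapolate_resolution(fit, target_n)
  }
  g_ex <- do.call(rbind, lapply(seq_len(nrow(groups)),
                                function(i) extrap(groups[i, ])))
  c_ex <- do.call(rbind, lapply(seq_len(nrow(controls)),
                                function(i) extrap(controls[i, ])))
  dres <- resolution_difference(g_ex$resolution_A, g_ex$sigma,
                                c_ex$resolution_A, c_ex$sigma)
  rat <- bfactor_ratio(groups$bfactor_A2, groups$bfactor_se_A2,
                       controls$bfactor_A2, controls$bfactor_se_A2)
  points <- tibble::tibble(
    bin = groups$group,
    x_mid_nm = mid,
    ratio = rat$ratio, ratio_se = rat$sigma,
    dres_A = dres$delta, dres_se = dres$sigma,
    res_group_A = g_ex$resolution_A, res_control_A = c_ex$resolution_A
  )
  list(
    points = points,
    dres_fit = fit_exponential_decay(mid, dres$delta, dres$sigma),
    ratio_fit = fit_exponential_decay(mid, rat$ratio, rat$sigma),
    target_n = target_n
  )
}
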