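#' Milling-surface annotation sets
#'
#' Sparse manual annotations of the two milling surfaces of a lamella,
#' recorded as ordered point lists on a subset of slices (typically every
#' ~100 slices) along one lateral axis of the tomogram. The on-disk format
#' is plain CSV with columns `tomogram_id`, `sheet` (`"front"`/`"back"`),
#' `slice_index` (position along the slice axis, voxels), `point_u`
#' (lateral position within the slice, voxels) and `point_v` (height along
#' the beam axis, voxels).
#'
#' @param df data frame with the five columns above.
#' @return a tibble of class `annotation_set`.
#' @export
annotation_set <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("tomogram_id", "sheet", "slice_index", "point_u", "point_v")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_fib(sprintf("missing annotation column '%s'", missing[1]),
              "fib_format_error")
  }
  if (nrow(df) == 0) abort_fib("annotation set is empty", "fib_empty_input")
  if (!all(df$sheet %in% c("front", "back"))) {
    abort_fib("sheet must be 'front' or 'back'", "fib_format_error")
  }
  for (col in c("slice_index", "point_u", "point_v")) {
    if (!all(is.finite(df[[col]]))) {
      abort_fib(sprintf("annotation column '%s' must be finite", col),
                "fib_format_error")
    }
  }
  class(df) <- unique(c("annotation_set", class(df)))
  df
}

#' Read / write surface annotations
#'
#' @param path CSV path.
#' @return [annotation_set()] (reader); `path` invisibly (writer).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort_fib(sprintf("file not found: %s", path), "fib_io_error")
  }
  annotation_set(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_annotations
#' @param annotations an [annotation_set()].
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}
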