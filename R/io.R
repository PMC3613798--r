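#' Read and write 4-D BOLD volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving data and affine exactly.
#'
#' @param data Numeric array (3-D map or 4-D time series), or a
#'   volumes x voxels matrix with `dim` supplied.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param dim Volume dimensions when `data` is a time x voxels matrix.
#' @return `path` invisibly for the writer; for the reader, a list with
#'   `data` (array) and `image` (the `niftiImage` carrying the header).
#' @export
write_bold_nifti <- function(data, path, dim = NULL) {
  if (is.matrix(data) && !is.null(dim)) {
    data <- array(t(data), dim = c(dim, nrow(data)))
  }
  RNifti::writeNifti(RNifti::asNifti(data), path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)), image = img)
}

# 4-D array (x, y, z, t) -> volumes x voxels matrix
bold_as_matrix <- function(arr4d) {
  d <- dim(arr4d)
  t(matrix(arr4d, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Read and write BIDS-style event tables
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`,
#' `n_groups` and optionally `response`, `rt`. Onsets survive the round
#' trip at full double precision.
#'
#' @param events Event tibble.
#' @param path File path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
write_events_tsv <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("onset", "duration", "trial_type", "n_groups")
  missing <- setdiff(need, names(ev))
  if (length(missing) > 0) {
    stop("read_events_tsv: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(diff(ev$onset) <= 0)) {
    stop("read_events_tsv: onsets must be strictly increasing",
         call. = FALSE)
  }
  ev$n_groups <- as.integer(ev$n_groups)
  ev
}

#' Read and write nuisance regressor tables
#'
#' Tab-separated, one column per nuisance series, one row per volume.
#'
#' @param nuisance Tibble of nuisance series.
#' @param path File path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
write_nuisance_tsv <- function(nuisance, path) {
  readr::write_tsv(nuisance, path)
  invisible(path)
}

#' @rdname write_nuisance_tsv
#' @export
read_nuisance_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write gaze tables
#'
#' Tab-separated `(t, x, y, valid)` time series, e.g. a 500 Hz eye-position
#' recording.
#'
#' @param gaze Gaze tibble.
#' @param path File path.
#' @return The tibble (reader) or `path` invisibly (writer).
#' @export
write_gaze_tsv <- function(gaze, path) {
  readr::write_tsv(gaze, path)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("t", "x", "y", "valid")
  missing <- setdiff(need, names(g))
  if (length(missing) > 0) {
    stop("read_gaze_tsv: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g
}

#' Write a cluster table as TSV
#'
#' @param result A [cluster_inference()] result.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_cluster_tsv <- function(result, path) {
  readr::write_tsv(result$clusters, path)
  invisible(path)
}
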