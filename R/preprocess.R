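#' Crop window
#'
#' Closed rectangular region of a chromatogram in axis coordinates. Cropping
#' keeps cells whose retention time lies in `[rt_min, rt_max]` and whose drift
#' time lies in `[dt_min, dt_max]` (closed on both ends).
#'
#' @param rt_min,rt_max Retention-time bounds (seconds), `rt_min < rt_max`.
#' @param dt_min,dt_max Drift-time bounds (milliseconds), `dt_min < dt_max`.
#' @return An object of class `crop_window`.
#' @export
crop_window <- function(rt_min, rt_max, dt_min, dt_max) {
  vals <- c(rt_min, rt_max, dt_min, dt_max)
  if (anyNA(vals) || !all(is.finite(vals))) {
    stop_vocims("vocims_invalid_window", "crop window bounds must be finite")
  }
  if (rt_min >= rt_max || dt_min >= dt_max) {
    stop_vocims("vocims_invalid_window", "crop window requires rt_min < rt_max and dt_min < dt_max")
  }
  structure(
    list(rt_min = rt_min, rt_max = rt_max, dt_min = dt_min, dt_max = dt_max),
    class = "crop_window"
  )
}

#' Crop a chromatogram to its information-bearing central section
#'
#' GC-IMS output is mostly empty; the chemical information sits in a central
#' block of the retention-time x drift-time plane. `crop()` extracts the
#' subgrid whose coordinates fall inside `window` (closed intervals on both
#' axes) and subsets the axes to match. Idempotent: cropping twice with the
#' same window is a no-op.
#'
#' @param grid A [chromatogram_grid()].
#' @param window A [crop_window()]; must intersect both axes.
#' @return A `chromatogram_grid` restricted to the window.
#' @export
crop <- function(grid, window) {
  stopifnot(inherits(grid, "chromatogram_grid"), inherits(window, "crop_window"))
  ri <- which(grid$rt_axis >= window$rt_min & grid$rt_axis <= window$rt_max)
  di <- which(grid$dt_axis >= window$dt_min & grid$dt_axis <= window$dt_max)
  if (length(ri) == 0 || length(di) == 0) {
    stop_vocims("vocims_empty_crop", "crop window does not intersect the grid axes")
  }
  chromatogram_grid(
    grid$rt_axis[ri], grid$dt_axis[di],
    grid$intensity[ri, di, drop = FALSE]
  )
}

#' Zero sub-threshold intensities
#'
#' Sets every intensity strictly below `tau` to zero; values equal to or above
#' `tau` pass unchanged. In the intended use `tau` sits just above the
#' instrument noise floor, leaving a sparse vector of chemical signal.
#'
#' @param grid A [chromatogram_grid()].
#' @param tau Threshold in intensity units, >= 0.
#' @return A `chromatogram_grid` with sub-threshold cells zeroed.
#' @export
apply_threshold <- function(grid, tau) {
  stopifnot(inherits(grid, "chromatogram_grid"))
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0) {
    stop_vocims("vocims_invalid_threshold", "tau must be a single non-negative number")
  }
  grid$intensity[grid$intensity < tau] <- 0
  grid
}

#' Flatten a chromatogram to a feature vector
#'
#' Row-major flattening: retention time is the outer index, drift time the
#' inner one, so positions `1..|dt|` are the first retention-time row. The
#' returned `feature_index` recovers the `(rt, dt)` coordinate of every
#' position; reshaping `values` by `|dt_axis|` columns (row-wise) reproduces
#' the grid.
#'
#' @param grid A [chromatogram_grid()].
#' @return A list with `values` (numeric vector, length = cells) and
#'   `feature_index` (data.frame with columns `rt` and `dt`).
#' @export
vectorize <- function(grid) {
  stopifnot(inherits(grid, "chromatogram_grid"))
  list(
    values = as.vector(t(grid$intensity)),
    feature_index = data.frame(
      rt = rep(grid$rt_axis, each = length(grid$dt_axis)),
      dt = rep(grid$dt_axis, times = length(grid$rt_axis))
    )
  )
}

#' Build the samples-by-pixels feature matrix
#'
#' Applies the same crop window and the same threshold to every sample (a
#' requirement of the analysis: one crop, one threshold for all files), then
#' flattens each cropped grid row-major into one row of the matrix. Zeros are
#' kept as observed values, not missingness: downstream rank tests treat them
#' as measurements below the noise floor.
#'
#' @param samples A list of [chromatogram_grid()] objects sharing identical
#'   axes, optionally named by sample id.
#' @param window A [crop_window()].
#' @param tau Threshold in intensity units, or `NULL` to calibrate via
#'   [calibrate_threshold()] against `target_nnz`.
#' @param target_nnz Median non-zero pixel count aimed for when `tau` is
#'   `NULL` (default 10000).
#' @return An object of class `feature_matrix`: list with `matrix`
#'   (samples x pixels), `feature_index`, `sample_ids`, `threshold_used`,
#'   `crop_used`.
#' @export
build_matrix <- function(samples, window, tau = NULL, target_nnz = 10000) {
  if (!is.list(samples) || length(samples) == 0 ||
      !all(vapply(samples, inherits, logical(1), "chromatogram_grid"))) {
    stop_vocims("vocims_invalid_input", "samples must be a non-empty list of chromatogram_grid objects")
  }
  ref <- samples[[1]]
  same_axes <- vapply(
    samples,
    function(g) {
      length(g$rt_axis) == length(ref$rt_axis) &&
        length(g$dt_axis) == length(ref$dt_axis) &&
        all(g$rt_axis == ref$rt_axis) && all(g$dt_axis == ref$dt_axis)
    },
    logical(1)
  )
  if (!all(same_axes)) {
    stop_vocims("vocims_incompatible_grids", "all sample grids must share identical axes")
  }
  stopifnot(inherits(window, "crop_window"))
  ri <- which(ref$rt_axis >= window$rt_min & ref$rt_axis <= window$rt_max)
  di <- which(ref$dt_axis >= window$dt_min & ref$dt_axis <= window$dt_max)
  if (length(ri) == 0 || length(di) == 0) {
    stop_vocims("vocims_empty_crop", "crop window does not intersect the grid axes")
  }
  # single pass: slice + row-major flatten per sample, one shared threshold
  mat <- matrix(0, length(samples), length(ri) * length(di))
  for (s in seq_along(samples)) {
    mat[s, ] <- as.vector(t(samples[[s]]$intensity[ri, di, drop = FALSE]))
  }
  if (is.null(tau)) {
    tau <- calibrate_matrix_threshold(mat, target_nnz)
  } else if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0) {
    stop_vocims("vocims_invalid_threshold", "tau must be a single non-negative number")
  }
  mat[mat < tau] <- 0
  ids <- names(samples)
  if (is.null(ids)) {
    ids <- sprintf("S%03d", seq_along(samples))
  }
  rownames(mat) <- ids
  structure(
    list(
      matrix = mat,
      feature_index = data.frame(
        rt = rep(ref$rt_axis[ri], each = length(di)),
        dt = rep(ref$dt_axis[di], times = length(ri))
      ),
      sample_ids = ids,
      threshold_used = tau,
      crop_used = window
    ),
    class = "feature_matrix"
  )
}

# Shared calibration core on an already-flattened samples x pixels matrix.
calibrate_matrix_threshold <- function(mat, target_nnz,
                                       candidates = seq(0, 10, by = 0.05)) {
  if (!is.numeric(target_nnz) || target_nnz < 1) {
    stop_vocims("vocims_invalid_input", "target_nnz must be >= 1")
  }
  if (length(candidates) == 0 || any(diff(candidates) <= 0) || any(candidates < 0)) {
    stop_vocims("vocims_invalid_input", "candidates must be an increasing non-negative grid")
  }
  nnz <- apply(mat, 1, function(row) {
    v <- row[row > 0]
    bins <- tabulate(findInterval(v, candidates) + 1L, nbins = length(candidates) + 1L)
    rev(cumsum(rev(bins)))[seq_along(candidates) + 1L] + 0
  })
  med <- apply(matrix(nnz, nrow = length(candidates)), 1, median)
  ok <- which(med <= target_nnz)
  if (length(ok) == 0) {
    stop_vocims(
      "vocims_calibration_error",
      sprintf(
        "no candidate threshold reaches median nnz <= %g (best: %g at tau = %g)",
        target_nnz, min(med), candidates[which.min(med)]
      )
    )
  }
  candidates[ok[1]]
}

#' @export
print.feature_matrix <- function(x, ...) {
  nnz <- rowSums(x$matrix > 0)
  cat(
    sprintf(
      "<feature_matrix> %d samples x %d pixels; threshold %.3g; median nnz/sample %d\n",
      nrow(x$matrix), ncol(x$matrix), x$threshold_used, as.integer(median(nnz))
    )
  )
  invisible(x)
}

#' Calibrate the noise threshold to a target sparsity
#'
#' The threshold is meant to sit just above the instrument noise level so that
#' each sample retains on the order of 10,000 non-zero pixels. This picks the
#' smallest candidate `tau` whose median per-sample non-zero count is at or
#' below `target_nnz`.
#'
#' @param samples List of [chromatogram_grid()] objects (typically already
#'   cropped).
#' @param target_nnz Target median non-zero count per sample, >= 1.
#' @param candidates Increasing grid of candidate thresholds searched
#'   exhaustively.
#' @return The selected threshold (scalar).
#' @export
calibrate_threshold <- function(samples, target_nnz = 10000,
                                candidates = seq(0, 10, by = 0.05)) {
  if (!is.list(samples) || length(samples) == 0 ||
      !all(vapply(samples, inherits, logical(1), "chromatogram_grid"))) {
    stop_vocims("vocims_invalid_input", "samples must be a non-empty list of chromatogram_grid objects")
  }
  mat <- do.call(rbind, lapply(samples, function(g) as.vector(g$intensity)))
  calibrate_matrix_threshold(mat, target_nnz, candidates)
}

#' Write / read a feature matrix as CSV plus JSON sidecar
#'
#' The CSV holds one row per sample (first column `sample_id`); the sidecar
#' records the pixel coordinate map, crop window and threshold so any row can
#' be re-derived from its raw chromatogram.
#'
#' @param fm A `feature_matrix`.
#' @param csv_path,sidecar_path Output paths.
#' @return `fm`, invisibly.
#' @export
write_feature_matrix <- function(fm, csv_path, sidecar_path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(sample_id = fm$sample_ids, fm$matrix, check.names = FALSE)
  colnames(df) <- c("sample_id", sprintf("px%06d", seq_len(ncol(fm$matrix))))
  write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(
      feature_index = fm$feature_index,
      crop = unclass(fm$crop_used),
      threshold = fm$threshold_used
    ),
    sidecar_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(fm)
}
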