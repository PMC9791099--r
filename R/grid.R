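#' Chromatogram grid
#'
#' A GC-IMS chromatogram: a matrix of ion-current intensities indexed by
#' retention time (GC axis, seconds) in rows and drift time (IMS axis,
#' milliseconds) in columns. Both axes must be strictly increasing and all
#' intensities finite and non-negative.
#'
#' @param rt_axis Numeric vector of retention-time coordinates (seconds),
#'   strictly increasing.
#' @param dt_axis Numeric vector of drift-time coordinates (milliseconds),
#'   strictly increasing.
#' @param intensity Numeric matrix, `length(rt_axis)` rows by
#'   `length(dt_axis)` columns.
#' @return An object of class `chromatogram_grid`: a list with elements
#'   `rt_axis`, `dt_axis` and `intensity`.
#' @examples
#' g <- make_grid(seq(0, 10, by = 1), seq(5, 6, by = 0.1))
#' dim(g$intensity)
#' @export
chromatogram_grid <- function(rt_axis, dt_axis, intensity) {
  check_axis(rt_axis, "rt_axis")
  check_axis(dt_axis, "dt_axis")
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop_vocims("vocims_invalid_grid", "intensity must be a numeric matrix")
  }
  if (nrow(intensity) != length(rt_axis) || ncol(intensity) != length(dt_axis)) {
    stop_vocims(
      "vocims_invalid_grid",
      sprintf(
        "intensity is %d x %d but axes imply %d x %d",
        nrow(intensity), ncol(intensity), length(rt_axis), length(dt_axis)
      )
    )
  }
  if (!all(is.finite(intensity))) {
    stop_vocims("vocims_invalid_grid", "all intensities must be finite")
  }
  structure(
    list(
      rt_axis = as.numeric(rt_axis),
      dt_axis = as.numeric(dt_axis),
      intensity = intensity
    ),
    class = "chromatogram_grid"
  )
}

check_axis <- function(axis, name) {
  if (length(axis) == 0 || !is.numeric(axis) || anyNA(axis)) {
    stop_vocims("vocims_invalid_axis", sprintf("%s must be a non-empty numeric vector", name))
  }
  if (length(axis) > 1 && any(diff(axis) <= 0)) {
    stop_vocims("vocims_invalid_axis", sprintf("%s must be strictly increasing", name))
  }
  invisible(axis)
}

#' @rdname chromatogram_grid
#' @export
make_grid <- function(rt_axis, dt_axis) {
  check_axis(rt_axis, "rt_axis")
  check_axis(dt_axis, "dt_axis")
  chromatogram_grid(
    rt_axis, dt_axis,
    matrix(0, nrow = length(rt_axis), ncol = length(dt_axis))
  )
}

#' @export
print.chromatogram_grid <- function(x, ...) {
  cat(
    sprintf(
      "<chromatogram_grid> %d rt x %d dt cells; rt [%g, %g] s; dt [%g, %g] ms; max intensity %.3g\n",
      length(x$rt_axis), length(x$dt_axis),
      min(x$rt_axis), max(x$rt_axis), min(x$dt_axis), max(x$dt_axis),
      max(x$intensity)
    )
  )
  invisible(x)
}

#' Analyte peak specification
#'
#' Describes one Gaussian-shaped analyte signal: an axis-separable 2D Gaussian
#' whose mode carries intensity `amplitude`. Peak centers are snapped to the
#' nearest grid cell when added, so the cell nearest
#' `(rt_center, dt_center)` receives exactly `amplitude`.
#'
#' @param rt_center Retention-time center (seconds).
#' @param dt_center Drift-time center (milliseconds).
#' @param rt_sigma Retention-time standard deviation (seconds), > 0.
#' @param dt_sigma Drift-time standard deviation (milliseconds), > 0.
#' @param amplitude Mode intensity (arbitrary ion-current units), >= 0.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(rt_center, dt_center, rt_sigma, dt_sigma, amplitude) {
  vals <- c(rt_center, dt_center, rt_sigma, dt_sigma, amplitude)
  if (length(vals) != 5 || anyNA(vals) || !all(is.finite(vals))) {
    stop_vocims("vocims_invalid_peak", "peak_spec fields must be finite scalars")
  }
  if (rt_sigma <= 0 || dt_sigma <= 0) {
    stop_vocims("vocims_invalid_peak", "peak sigmas must be strictly positive")
  }
  if (amplitude < 0) {
    stop_vocims("vocims_invalid_peak", "peak amplitude must be non-negative")
  }
  structure(
    list(
      rt_center = rt_center, dt_center = dt_center,
      rt_sigma = rt_sigma, dt_sigma = dt_sigma, amplitude = amplitude
    ),
    class = "peak_spec"
  )
}

# Gaussian factor along one axis, evaluated only within +/- 6 sigma of the
# snapped center (exp(-18) ~ 1.5e-8 of the mode lies outside; truncation keeps
# per-peak cost proportional to peak area, not grid area).
gauss_profile <- function(axis, center, sigma) {
  idx0 <- which.min(abs(axis - center))
  c0 <- axis[idx0]
  lo <- findInterval(c0 - 6 * sigma, axis) # last index <= bound (0 if none)
  lo <- max(1L, lo)
  hi <- findInterval(c0 + 6 * sigma, axis)
  hi <- min(length(axis), hi + 1L)
  list(idx = lo:hi, val = exp(-((axis[lo:hi] - c0)^2) / (2 * sigma^2)))
}

#' Add an analyte peak to a chromatogram
#'
#' Adds a separable 2D Gaussian cell-wise. The input grid is not modified.
#' Support is truncated at 6 sigma around the (snapped) center on each axis;
#' the omitted mass is below 2e-8 of the mode.
#'
#' @param grid A [chromatogram_grid()].
#' @param peak A [peak_spec()]. Its center must lie inside both axis ranges.
#' @return A new `chromatogram_grid` with the peak added.
#' @examples
#' g <- make_grid(seq(0, 100, by = 5), seq(6, 10, by = 0.05))
#' g2 <- add_peak(g, peak_spec(50, 8, 5, 0.1, 10))
#' max(g2$intensity)
#' @export
add_peak <- function(grid, peak) {
  stopifnot(inherits(grid, "chromatogram_grid"), inherits(peak, "peak_spec"))
  if (peak$rt_center < min(grid$rt_axis) || peak$rt_center > max(grid$rt_axis) ||
      peak$dt_center < min(grid$dt_axis) || peak$dt_center > max(grid$dt_axis)) {
    stop_vocims(
      "vocims_peak_out_of_range",
      sprintf(
        "peak center (%.3g s, %.3g ms) lies outside the grid axes",
        peak$rt_center, peak$dt_center
      )
    )
  }
  if (peak$amplitude == 0) {
    return(grid)
  }
  pr <- gauss_profile(grid$rt_axis, peak$rt_center, peak$rt_sigma)
  pd <- gauss_profile(grid$dt_axis, peak$dt_center, peak$dt_sigma)
  inc <- peak$amplitude * tcrossprod(pr$val, pd$val)
  grid$intensity[pr$idx, pd$idx] <- grid$intensity[pr$idx, pd$idx] + inc
  grid
}

#' Add the reactant-ion peak (RIP)
#'
#' The ionization source produces a persistent reactant-ion signal: a ridge
#' that is Gaussian in drift time, centered at `rip$dt_center`, and constant
#' across all retention times. `rip$rt_center` and `rip$rt_sigma` are ignored.
#'
#' @inheritParams add_peak
#' @param rip A [peak_spec()]; only its drift-time fields and amplitude are
#'   used.
#' @return A new `chromatogram_grid` with the ridge added.
#' @export
add_rip <- function(grid, rip) {
  stopifnot(inherits(grid, "chromatogram_grid"), inherits(rip, "peak_spec"))
  if (rip$dt_center < min(grid$dt_axis) || rip$dt_center > max(grid$dt_axis)) {
    stop_vocims(
      "vocims_peak_out_of_range",
      sprintf("RIP drift-time center %.3g ms lies outside the dt axis", rip$dt_center)
    )
  }
  if (rip$amplitude == 0) {
    return(grid)
  }
  pd <- gauss_profile(grid$dt_axis, rip$dt_center, rip$dt_sigma)
  ridge <- rip$amplitude * pd$val
  grid$intensity[, pd$idx] <- grid$intensity[, pd$idx] +
    matrix(ridge, nrow = nrow(grid$intensity), ncol = length(ridge), byrow = TRUE)
  grid
}
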