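#' Read and write chromatograms as plain text
#'
#' One file per sample: line 1 is the comma-separated retention-time axis,
#' line 2 the drift-time axis, then one line per retention time holding the
#' comma-separated intensities across drift times. Values are written with 8
#' significant digits.
#'
#' @param grid A [chromatogram_grid()].
#' @param path File path.
#' @return `write_chromatogram()` returns `path` invisibly;
#'   `read_chromatogram()` returns a `chromatogram_grid`.
#' @export
write_chromatogram <- function(grid, path) {
  stopifnot(inherits(grid, "chromatogram_grid"))
  fmt <- function(v) paste(sprintf("%.8g", v), collapse = ",")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(fmt(grid$rt_axis), con)
  writeLines(fmt(grid$dt_axis), con)
  writeLines(apply(grid$intensity, 1, fmt), con)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    stop_vocims("vocims_io_error", sprintf("'%s' is not a chromatogram file (needs >= 3 lines)", path))
  }
  parse_row <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  rt <- parse_row(lines[1])
  dt <- parse_row(lines[2])
  if (length(lines) != 2 + length(rt)) {
    stop_vocims(
      "vocims_io_error",
      sprintf("'%s': expected %d intensity rows, found %d", path, length(rt), length(lines) - 2)
    )
  }
  intensity <- matrix(
    unlist(lapply(lines[-(1:2)], parse_row), use.names = FALSE),
    nrow = length(rt), ncol = length(dt), byrow = TRUE
  )
  chromatogram_grid(rt, dt, intensity)
}

#' Write a cohort to a workspace directory
#'
#' Lays out `<dir>/manifest.csv`, `<dir>/chromatograms/<sample_id>.txt` and
#' `<dir>/ground_truth.json` (planted peak footprints as pixel index lists).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "voc_cohort"))
  dir.create(file.path(dir, "chromatograms"), recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$records, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (sid in names(cohort$grids)) {
    write_chromatogram(cohort$grids[[sid]], file.path(dir, "chromatograms", paste0(sid, ".txt")))
  }
  jsonlite::write_json(
    cohort$ground_truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a sample manifest
#'
#' @param path Path to a `manifest.csv` written by [write_cohort()] (or any
#'   CSV with the same columns).
#' @return A data.frame, one row per sample.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "chromatogram_path")
  missing <- setdiff(required, colnames(m))
  if (length(missing)) {
    stop_vocims(
      "vocims_schema_error",
      paste("manifest is missing columns:", paste(missing, collapse = ", "))
    )
  }
  m
}

# Load the chromatograms referenced by a manifest, as a named list.
read_cohort_grids <- function(manifest, dir) {
  grids <- lapply(manifest$chromatogram_path, function(p) {
    fp <- file.path(dir, p)
    if (!file.exists(fp)) {
      stop_vocims("vocims_io_error", sprintf("chromatogram file not found: %s", fp))
    }
    read_chromatogram(fp)
  })
  names(grids) <- manifest$sample_id
  grids
}
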