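#' Default chromatogram axes
#'
#' The stated world of the synthetic instrument: a 6-minute GC run sampled at
#' 120 retention-time points (0-360 s) and 2,500 drift-time points spanning
#' 6-16 ms, giving a 300,000-cell grid whose thresholded central crop lands
#' near 10,000 non-zero pixels per sample.
#'
#' @return Numeric axis vector.
#' @export
default_rt_axis <- function() seq(0, 360, length.out = 120)

#' @rdname default_rt_axis
#' @export
default_dt_axis <- function() seq(6, 16, length.out = 2500)

#' Default crop window
#'
#' Central section holding the analyte signal: retention time 20-340 s, drift
#' time 7.5-15.5 ms. The reactant-ion ridge (7.0 ms) and the grid margins are
#' excluded.
#'
#' @return A [crop_window()].
#' @export
default_crop_window <- function() crop_window(20, 340, 7.5, 15.5)

#' Default reactant-ion peak
#'
#' A drift-time ridge at 7.0 ms (sigma 0.05 ms) of amplitude 50, constant
#' across retention time, emulating the persistent reactant-ion signal of a
#' tritium source.
#'
#' @return A [peak_spec()].
#' @export
default_rip_spec <- function() peak_spec(0, 7.0, 1, 0.05, 50)

#' Random template peak set
#'
#' Draws `n_peaks` analyte peaks shared by every sample of a cohort. Centers
#' fall inside the default crop window (retention time 30-330 s, drift time
#' 8-15 ms); widths are uniform on 3-8 s and 0.02-0.08 ms; amplitudes are
#' log-normal with median 8 intensity units (sdlog 0.5), i.e. mostly well
#' above a noise floor of 1.
#'
#' @param n_peaks Number of peaks (default 40).
#' @param seed Integer seed making the template reproducible.
#' @return List of [peak_spec()] objects.
#' @export
template_peaks <- function(n_peaks = 40, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n_peaks), function(i) {
      peak_spec(
        rt_center = runif(1, 30, 330),
        dt_center = runif(1, 8, 15),
        rt_sigma = runif(1, 3, 8),
        dt_sigma = runif(1, 0.02, 0.08),
        amplitude = stats::rlnorm(1, meanlog = log(8), sdlog = 0.5)
      )
    })
  })
}

#' Cohort design
#'
#' The full recipe for a synthetic GC-IMS cohort: class sizes, the shared
#' template peaks, per-class amplitude multipliers (the planted effects), the
#' reactant-ion ridge, noise level, baseline drift and one master seed from
#' which every per-sample seed is derived (counter-based, so generation order
#' does not matter).
#'
#' @param n_per_class Named integer vector of class sizes (names are class
#'   labels). Default `c(term = 26, preterm = 52)`, the study's cohort.
#' @param peaks List of [peak_spec()] template peaks; default
#'   `template_peaks(40, seed)`.
#' @param planted_effects Named list mapping each class label to a numeric
#'   vector of per-peak amplitude multipliers (length = number of peaks).
#'   Default: all ones (no class effect).
#' @param rip_spec Reactant-ion ridge, a [peak_spec()].
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (intensity units); the noisy signal is clamped at zero.
#' @param baseline_drift Linear baseline slope in intensity units per second
#'   of retention time.
#' @param rt_axis,dt_axis Grid axes.
#' @param preterm_classes Character vector naming which class labels count as
#'   preterm deliveries when drawing clinical covariates; default: the last
#'   class label.
#' @param seed Master integer seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_class = c(term = 26, preterm = 52),
                          peaks = NULL,
                          planted_effects = NULL,
                          rip_spec = default_rip_spec(),
                          noise_sd = 1,
                          baseline_drift = 0.002,
                          rt_axis = default_rt_axis(),
                          dt_axis = default_dt_axis(),
                          preterm_classes = NULL,
                          seed = 1) {
  if (length(n_per_class) < 1 || any(n_per_class < 0) || is.null(names(n_per_class)) ||
      anyNA(n_per_class) || any(names(n_per_class) == "")) {
    stop_vocims("vocims_invalid_design", "n_per_class must be a named vector of non-negative sizes")
  }
  if (noise_sd < 0) {
    stop_vocims("vocims_invalid_design", "noise_sd must be >= 0")
  }
  if (is.null(peaks)) {
    peaks <- template_peaks(40, seed = seed)
  }
  classes <- names(n_per_class)
  if (is.null(planted_effects)) {
    planted_effects <- setNames(
      rep(list(rep(1, length(peaks))), length(classes)), classes
    )
  }
  if (!all(classes %in% names(planted_effects))) {
    stop_vocims("vocims_invalid_design", "planted_effects must cover every class label")
  }
  for (cl in classes) {
    eff <- planted_effects[[cl]]
    if (length(eff) != length(peaks) || any(eff < 0) || anyNA(eff)) {
      stop_vocims(
        "vocims_invalid_design",
        sprintf("planted_effects[['%s']] must be %d non-negative multipliers", cl, length(peaks))
      )
    }
  }
  if (is.null(preterm_classes)) {
    preterm_classes <- if ("preterm" %in% classes) "preterm" else classes[length(classes)]
  }
  structure(
    list(
      n_per_class = n_per_class, peaks = peaks, planted_effects = planted_effects,
      rip_spec = rip_spec, noise_sd = noise_sd, baseline_drift = baseline_drift,
      rt_axis = rt_axis, dt_axis = dt_axis,
      preterm_classes = preterm_classes, seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' Plant a class effect on the strongest template peaks
#'
#' Marks `n_peaks` template peaks as discriminative by multiplying their
#' amplitude by `multiplier` in `class_label` only. The strongest peaks are
#' chosen so the planted effect is expressed above the noise threshold.
#'
#' @param design A [cohort_design()].
#' @param n_peaks Number of discriminative peaks (default 5).
#' @param multiplier Amplitude multiplier in the affected class (default 1.5).
#' @param class_label Affected class; default: the first preterm class.
#' @return The design with updated `planted_effects` (other classes keep
#'   multiplier 1 at those peaks).
#' @export
plant_effect <- function(design, n_peaks = 5, multiplier = 1.5, class_label = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(class_label)) {
    class_label <- design$preterm_classes[1]
  }
  if (!class_label %in% names(design$n_per_class)) {
    stop_vocims("vocims_unknown_class", sprintf("unknown class label '%s'", class_label))
  }
  amps <- vapply(design$peaks, `[[`, numeric(1), "amplitude")
  idx <- order(amps, decreasing = TRUE)[seq_len(min(n_peaks, length(amps)))]
  design$planted_effects[[class_label]][idx] <- multiplier
  design
}

# Peaks whose multipliers differ across any pair of classes.
planted_peak_ids <- function(design) {
  eff <- do.call(rbind, design$planted_effects[names(design$n_per_class)])
  which(apply(eff, 2, function(col) max(col) != min(col)))
}

#' Generate one synthetic chromatogram
#'
#' Sum of: template peaks with the class's amplitude multipliers, the
#' reactant-ion ridge, a linear baseline rising with retention time, and
#' additive Gaussian noise; the result is clamped at zero (ion current is
#' non-negative). Deterministic given `seed`.
#'
#' @param design A [cohort_design()].
#' @param class_label Class whose multipliers apply; must appear in
#'   `design$planted_effects`.
#' @param seed Integer seed for the noise draw.
#' @return A [chromatogram_grid()].
#' @export
generate_sample <- function(design, class_label, seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (!class_label %in% names(design$planted_effects)) {
    stop_vocims("vocims_unknown_class", sprintf("unknown class label '%s'", class_label))
  }
  rt <- design$rt_axis
  dt <- design$dt_axis
  check_axis(rt, "rt_axis")
  check_axis(dt, "dt_axis")
  mult <- design$planted_effects[[class_label]]
  # Local accumulation (no intermediate grid copies); identical term order to
  # composing add_peak / add_rip / drift, which an invariant test asserts.
  M <- matrix(0, length(rt), length(dt))
  for (i in seq_along(design$peaks)) {
    p <- design$peaks[[i]]
    amp <- p$amplitude * mult[i]
    if (amp == 0) next
    if (p$rt_center < rt[1] || p$rt_center > rt[length(rt)] ||
        p$dt_center < dt[1] || p$dt_center > dt[length(dt)]) {
      stop_vocims(
        "vocims_peak_out_of_range",
        sprintf("template peak %d lies outside the grid axes", i)
      )
    }
    pr <- gauss_profile(rt, p$rt_center, p$rt_sigma)
    pd <- gauss_profile(dt, p$dt_center, p$dt_sigma)
    M[pr$idx, pd$idx] <- M[pr$idx, pd$idx] + amp * tcrossprod(pr$val, pd$val)
  }
  rip <- design$rip_spec
  if (rip$amplitude > 0) {
    pd <- gauss_profile(dt, rip$dt_center, rip$dt_sigma)
    M[, pd$idx] <- M[, pd$idx] +
      matrix(rip$amplitude * pd$val, nrow(M), length(pd$idx), byrow = TRUE)
  }
  if (design$baseline_drift != 0) {
    M <- M + design$baseline_drift * rt
  }
  if (design$noise_sd > 0) {
    M <- M + with_seed(seed, rnorm(length(M), sd = design$noise_sd))
  }
  M[M < 0] <- 0
  chromatogram_grid(rt, dt, M)
}

# WHO gestational-age bands in days (weeks+days notation: 37+0 = 259).
who_bands <- list(
  "1" = c(168L, 195L), "2" = c(196L, 223L), "3" = c(224L, 258L)
)
term_delivery_range <- c(259L, 293L)

# Draw clinical covariates for one sample, conditional on preterm status.
# Marginals follow the study's baseline table: chorioamnionitis 0/26 term and
# 28/52 preterm; UTI 3/26 term and 4/52 preterm; CRP and cervical length
# normal with the per-group mean (SD), clamped to plausible ranges.
draw_record <- function(preterm, sample_id, seed) {
  with_seed(seed, {
    if (preterm) {
      grp <- sample(c("1", "2", "3"), 1, prob = c(30, 17, 5) / 52)
      band <- who_bands[[grp]]
      ga_delivery <- as.integer(round(runif(1, band[1], band[2])))
      ga_inclusion <- as.integer(round(runif(1, band[1], ga_delivery)))
      chorio <- runif(1) < 28 / 52
      uti <- runif(1) < 4 / 52
      crp <- max(0.1, rnorm(1, 21.43, 17.59))
      cl <- min(45, max(1, rnorm(1, 20.54, 11.23)))
    } else {
      grp <- sample(c("4a", "4b", "4c"), 1, prob = c(10, 15, 1) / 26)
      band <- who_bands[[match(substr(grp, 2, 2), c("a", "b", "c"))]]
      ga_inclusion <- as.integer(round(runif(1, band[1], band[2])))
      ga_delivery <- as.integer(round(runif(1, term_delivery_range[1], term_delivery_range[2])))
      chorio <- FALSE
      uti <- runif(1) < 3 / 26
      crp <- max(0.1, rnorm(1, 6.74, 7.09))
      cl <- min(45, max(1, rnorm(1, 21.46, 9.96)))
    }
    data.frame(
      sample_id = sample_id,
      delivery_class = if (preterm) "preterm" else "term",
      ga_inclusion_days = ga_inclusion,
      ga_delivery_days = ga_delivery,
      who_group = grp,
      chorioamnionitis = chorio,
      uti = uti,
      crp = round(crp, 2),
      cervical_length = round(cl, 1),
      chromatogram_path = paste0("chromatograms/", sample_id, ".txt"),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic GC-IMS cohort
#'
#' Produces per-class chromatograms (via [generate_sample()]), a clinical
#' manifest with one row per sample (gestational-age bands, chorioamnionitis
#' and UTI flags, CRP, cervical length) and a ground-truth record of the
#' planted discriminative peaks. Fully deterministic given the design's seed:
#' sample `i` uses a counter-derived seed, so two calls yield identical grids
#' and manifests.
#'
#' @param design A [cohort_design()].
#' @return An object of class `voc_cohort`: list with `records` (data.frame
#'   manifest), `grids` (named list of [chromatogram_grid()]), `ground_truth`
#'   (planted peak centers, sigmas, multipliers, and full-grid pixel
#'   footprints within 3 sigma of each center) and the `design`.
#' @examples
#' d <- cohort_design(c(term = 3, preterm = 4), seed = 7)
#' co <- generate_cohort(d)
#' table(co$records$delivery_class)
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  classes <- names(design$n_per_class)
  records <- list()
  grids <- list()
  counter <- 0L
  for (cl in classes) {
    n <- design$n_per_class[[cl]]
    if (n == 0) next
    preterm <- cl %in% design$preterm_classes
    for (j in seq_len(n)) {
      counter <- counter + 1L
      sid <- sprintf("S%03d_%s", counter, cl)
      rec <- draw_record(preterm, sid, seed_stream(design$seed, 2L * counter))
      rec$class_label <- cl
      records[[counter]] <- rec
      grids[[sid]] <- generate_sample(design, cl, seed_stream(design$seed, 2L * counter + 1L))
    }
  }
  manifest <- if (length(records)) {
    do.call(rbind, records)
  } else {
    draw_record(TRUE, "x", 1)[0, ]
  }
  rownames(manifest) <- NULL
  structure(
    list(
      records = manifest,
      grids = grids,
      ground_truth = ground_truth(design),
      design = design
    ),
    class = "voc_cohort"
  )
}

# Planted-peak footprints: all full-grid pixels within 3 sigma of the snapped
# center on both axes, as row-major flat indices (dt inner).
ground_truth <- function(design) {
  ids <- planted_peak_ids(design)
  ndt <- length(design$dt_axis)
  peaks <- lapply(ids, function(i) {
    p <- design$peaks[[i]]
    c_rt <- design$rt_axis[which.min(abs(design$rt_axis - p$rt_center))]
    c_dt <- design$dt_axis[which.min(abs(design$dt_axis - p$dt_center))]
    ri <- which(abs(design$rt_axis - c_rt) <= 3 * p$rt_sigma)
    di <- which(abs(design$dt_axis - c_dt) <= 3 * p$dt_sigma)
    flat <- as.vector(outer((ri - 1L) * ndt, di, `+`))
    mult <- vapply(design$planted_effects, `[`, numeric(1), i)
    list(
      peak_id = i, rt_center = c_rt, dt_center = c_dt,
      rt_sigma = p$rt_sigma, dt_sigma = p$dt_sigma,
      multipliers = as.list(mult), pixels = sort(flat)
    )
  })
  names(peaks) <- sprintf("peak_%03d", ids)
  list(planted = peaks)
}

#' Map planted-peak footprints to feature-matrix columns
#'
#' Returns the column indices of a [build_matrix()] result whose pixel
#' coordinates fall within 3 sigma of any planted peak center — the set a
#' successful feature-selection run should concentrate on.
#'
#' @param truth A `ground_truth` element of a [generate_cohort()] result.
#' @param fm A `feature_matrix`.
#' @return Integer vector of column indices (possibly empty).
#' @export
footprint_columns <- function(truth, fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  fi <- fm$feature_index
  hit <- rep(FALSE, nrow(fi))
  for (p in truth$planted) {
    hit <- hit |
      (abs(fi$rt - p$rt_center) <= 3 * p$rt_sigma &
         abs(fi$dt - p$dt_center) <= 3 * p$dt_sigma)
  }
  which(hit)
}
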