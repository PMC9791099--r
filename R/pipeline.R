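#' Comparison specification
#'
#' Defines one two-arm contrast as a pair of manifest filters, e.g. WHO group
#' 2 vs. group 4b, chorioamnionitis yes vs. no, CRP > 9 mg/L vs. <= 9.
#' Predicates are R expressions (given as strings) evaluated on the manifest
#' columns; arm A is the reference class (label 0), arm B the case class
#' (label 1).
#'
#' @param name Comparison label used in reports.
#' @param predicate_a,predicate_b Filter expressions as strings, e.g.
#'   `"delivery_class == 'term'"` or `"who_group %in% c('2', '3')"`.
#' @return An object of class `comparison_spec`.
#' @export
comparison_spec <- function(name, predicate_a, predicate_b) {
  if (!is.character(name) || !is.character(predicate_a) || !is.character(predicate_b)) {
    stop_vocims("vocims_invalid_input", "name and predicates must be strings")
  }
  structure(
    list(name = name, predicate_a = predicate_a, predicate_b = predicate_b),
    class = "comparison_spec"
  )
}

#' The study's default comparisons
#'
#' Preterm vs. term delivery, the WHO gestational-age subgroup contrasts
#' (group 2 vs. 4b; merged groups 2+3 vs. 4b+4c; group 1 vs. 4a; group 1 vs.
#' 2+3), and the infection/inflammation contrasts (chorioamnionitis, UTI,
#' CRP > 9 mg/L, cervical length < 25 mm). Group mergers are expressed as
#' predicates, not code.
#'
#' @return List of [comparison_spec()] objects.
#' @export
default_comparisons <- function() {
  list(
    comparison_spec(
      "preterm_vs_term",
      "delivery_class == 'term'", "delivery_class == 'preterm'"
    ),
    comparison_spec(
      "group1_vs_4a",
      "who_group == '4a'", "who_group == '1'"
    ),
    comparison_spec(
      "group2_vs_4b",
      "who_group == '4b'", "who_group == '2'"
    ),
    comparison_spec(
      "group23_vs_4bc",
      "who_group %in% c('4b', '4c')", "who_group %in% c('2', '3')"
    ),
    comparison_spec(
      "chorioamnionitis",
      "!chorioamnionitis", "chorioamnionitis"
    ),
    comparison_spec(
      "uti",
      "!uti", "uti"
    ),
    comparison_spec(
      "crp_gt9",
      "crp <= 9", "crp > 9"
    ),
    comparison_spec(
      "cervical_lt25",
      "cervical_length >= 25", "cervical_length < 25"
    )
  )
}

#' Resolve a comparison on a manifest
#'
#' Evaluates both predicates, checks the arms are disjoint and non-empty,
#' and returns binary labels (arm A = 0, arm B = 1) with row indices.
#'
#' @param manifest Data.frame manifest.
#' @param spec A [comparison_spec()].
#' @return List with `indices` (manifest row positions, arm A first),
#'   `labels01`, `n_a`, `n_b`, `name`.
#' @export
resolve_comparison <- function(manifest, spec) {
  stopifnot(inherits(spec, "comparison_spec"))
  eval_pred <- function(pred) {
    out <- tryCatch(
      eval(str2lang(pred), envir = manifest, enclos = baseenv()),
      error = function(e) {
        stop_vocims(
          "vocims_schema_error",
          sprintf("comparison '%s': predicate failed: %s", spec$name, conditionMessage(e))
        )
      }
    )
    which(!is.na(out) & out)
  }
  ia <- eval_pred(spec$predicate_a)
  ib <- eval_pred(spec$predicate_b)
  if (length(intersect(ia, ib)) > 0) {
    stop_vocims(
      "vocims_invalid_comparison",
      sprintf("comparison '%s': arms overlap (%d shared samples)", spec$name, length(intersect(ia, ib)))
    )
  }
  if (length(ia) == 0 || length(ib) == 0) {
    stop_vocims(
      "vocims_empty_arm",
      sprintf("comparison '%s': empty arm (A = %d, B = %d)", spec$name, length(ia), length(ib))
    )
  }
  list(
    indices = c(ia, ib),
    labels01 = c(rep(0L, length(ia)), rep(1L, length(ib))),
    n_a = length(ia), n_b = length(ib), name = spec$name
  )
}

#' Run configuration
#'
#' Defaults mirror the study's stated parameters: 10 folds, the 100 smallest
#' rank-sum p-values per fold, all three classifiers, one crop and one
#' threshold shared by all samples (threshold calibrated to ~10,000 non-zero
#' pixels unless fixed).
#'
#' @param crop A [crop_window()].
#' @param threshold Fixed intensity threshold, or `NULL` to calibrate.
#' @param target_nnz Calibration target when `threshold` is `NULL`.
#' @param n_folds,k Cross-validation parameters.
#' @param classifiers List of [classifier_spec()] objects.
#' @param comparisons List of [comparison_spec()] objects.
#' @param seed Master seed for fold assignment (per-comparison seeds are
#'   derived from it).
#' @return An object of class `run_config`.
#' @export
run_config <- function(crop = default_crop_window(),
                       threshold = NULL,
                       target_nnz = 10000,
                       n_folds = 10,
                       k = 100,
                       classifiers = default_classifier_specs(),
                       comparisons = default_comparisons(),
                       seed = 1) {
  structure(
    list(
      crop = crop, threshold = threshold, target_nnz = target_nnz,
      n_folds = n_folds, k = k, classifiers = classifiers,
      comparisons = comparisons, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full study pipeline
#'
#' End to end: load (or accept) all chromatograms, build one feature matrix
#' with a shared crop and threshold, compute the baseline-characteristics
#' table, then for every configured comparison run leakage-free k-fold CV
#' with all classifiers, evaluate each, and pick the best by AUC. Comparisons
#' whose arms are empty or too small are reported as skipped, not fatal.
#' Deterministic given the config seed.
#'
#' @param manifest Data.frame manifest ([read_manifest()] or
#'   `cohort$records`).
#' @param chrom_dir Directory that `manifest$chromatogram_path` is relative
#'   to; ignored when `grids` is supplied.
#' @param config A [run_config()].
#' @param grids Optional named list of [chromatogram_grid()] objects (keyed
#'   by `sample_id`) to skip file I/O.
#' @return An object of class `voc_report_bundle`: list with `summary` (one
#'   best-classifier row per comparison), `comparisons` (full per-classifier
#'   reports, arm sizes, per-fold selected features, pooled probabilities),
#'   `baseline`, `threshold_used`, `config`.
#' @export
run_study <- function(manifest, chrom_dir = NULL, config = run_config(),
                      grids = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(grids)) {
    if (is.null(chrom_dir)) {
      stop_vocims("vocims_invalid_input", "either chrom_dir or grids must be given")
    }
    grids <- read_cohort_grids(manifest, chrom_dir)
  }
  missing_ids <- setdiff(manifest$sample_id, names(grids))
  if (length(missing_ids)) {
    stop_vocims(
      "vocims_io_error",
      paste("no chromatogram for sample(s):", paste(missing_ids, collapse = ", "))
    )
  }
  grids <- grids[manifest$sample_id]
  fm <- build_matrix(grids, config$crop, tau = config$threshold,
                     target_nnz = config$target_nnz)
  baseline <- tryCatch(
    baseline_table(manifest),
    vocims_error = function(e) NULL
  )
  comp_results <- list()
  summary_rows <- list()
  for (i in seq_along(config$comparisons)) {
    spec <- config$comparisons[[i]]
    res <- tryCatch(
      resolve_comparison(manifest, spec),
      vocims_error = function(e) e
    )
    if (inherits(res, "condition")) {
      comp_results[[spec$name]] <- list(name = spec$name, skipped = conditionMessage(res))
      next
    }
    if (res$n_a < 2 || res$n_b < 2) {
      comp_results[[spec$name]] <- list(
        name = spec$name,
        skipped = sprintf("arm too small for stratified CV (A = %d, B = %d)", res$n_a, res$n_b)
      )
      next
    }
    cv <- run_cv(
      fm$matrix[res$indices, , drop = FALSE], res$labels01,
      specs = config$classifiers, n_folds = min(config$n_folds, length(res$indices)),
      k = config$k, seed = seed_stream(config$seed, 10000L + i)
    )
    reports <- lapply(colnames(cv$probabilities), function(nm) {
      evaluate_probs(cv$probabilities[, nm], cv$labels01, classifier = nm)
    })
    best <- select_best_classifier(reports)
    comp_results[[spec$name]] <- list(
      name = spec$name, n_a = res$n_a, n_b = res$n_b,
      reports = reports, best = best,
      selected = cv$selected,
      probabilities = cv$probabilities,
      sample_ids = manifest$sample_id[res$indices],
      labels01 = cv$labels01,
      cv_seed = seed_stream(config$seed, 10000L + i)
    )
    row <- as.data.frame(best)
    row <- cbind(
      data.frame(comparison = spec$name, stringsAsFactors = FALSE), row
    )
    summary_rows[[spec$name]] <- row
  }
  structure(
    list(
      summary = if (length(summary_rows)) do.call(rbind, c(summary_rows, make.row.names = FALSE)) else NULL,
      comparisons = comp_results,
      baseline = baseline,
      threshold_used = fm$threshold_used,
      config = config
    ),
    class = "voc_report_bundle"
  )
}

#' @export
print.voc_report_bundle <- function(x, ...) {
  cat("<voc_report_bundle>\n")
  if (!is.null(x$summary)) {
    df <- x$summary
    df$auc <- round(df$auc, 2)
    df$p_value <- signif(df$p_value, 2)
    print(df[, c("comparison", "classifier", "p_value", "auc", "sensitivity",
                 "specificity", "ppv", "npv", "n0", "n1")])
  }
  skipped <- Filter(function(cr) !is.null(cr$skipped), x$comparisons)
  for (cr in skipped) {
    cat(sprintf("  skipped %s: %s\n", cr$name, cr$skipped))
  }
  invisible(x)
}

#' Serialize a report bundle
#'
#' Writes `summary.csv` (one best-classifier row per comparison, rounded to 2
#' decimals as in the published tables), `reports.json` (full per-classifier
#' reports, pooled probabilities, per-fold selected features),
#' `baseline.csv` and `config.json`. Output is deterministic: no timestamps,
#' fixed digit settings — two runs with the same seed produce byte-identical
#' bundles.
#'
#' @param bundle A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "voc_report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$summary)) {
    out <- bundle$summary
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) round(v, 2))
    write.csv(out, file.path(dir, "summary.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$baseline)) {
    write.csv(bundle$baseline, file.path(dir, "baseline.csv"), row.names = FALSE)
  }
  comp_json <- lapply(bundle$comparisons, function(cr) {
    if (!is.null(cr$skipped)) {
      return(list(name = cr$name, skipped = cr$skipped))
    }
    list(
      name = cr$name, n_a = cr$n_a, n_b = cr$n_b,
      cv_seed = cr$cv_seed,
      best = unclass_report(cr$best),
      reports = lapply(cr$reports, unclass_report),
      probabilities = as.data.frame(cr$probabilities),
      sample_ids = cr$sample_ids,
      labels01 = cr$labels01,
      selected = cr$selected
    )
  })
  jsonlite::write_json(
    comp_json, file.path(dir, "reports.json"),
    auto_unbox = TRUE, digits = 10
  )
  jsonlite::write_json(
    list(
      crop = unclass(bundle$config$crop),
      threshold_used = bundle$threshold_used,
      n_folds = bundle$config$n_folds,
      k = bundle$config$k,
      seed = bundle$config$seed,
      classifiers = lapply(bundle$config$classifiers, function(s) s$name),
      comparisons = lapply(bundle$config$comparisons, unclass)
    ),
    file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = 10
  )
  invisible(dir)
}

unclass_report <- function(r) {
  u <- unclass(r)
  u$n_per_class <- as.list(u$n_per_class)
  u
}
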