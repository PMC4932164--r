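#' Pipeline configuration
#'
#' Validated configuration for the end-to-end discovery/validation runs.
#' Exactly one input source must be given: file paths (`matrix_path` +
#' `meta_path`) or a [synthetic_spec()]. Unknown arguments are errors, not
#' warnings, to prevent silent typos.
#'
#' @param matrix_path,meta_path Paths of the discovery expression matrix and
#'   sample metadata (tab-delimited), or `NULL` when `synthetic` is given.
#' @param synthetic A [synthetic_spec()], or `NULL` when paths are given.
#' @param pool_path Optional gene-pool file restricting the feature space.
#' @param probe_map_path Optional probe-to-gene map.
#' @param keep_diagnoses Diagnosis labels retained before analysis.
#' @param correct Apply the robust age/gender correction.
#' @param correct_before_filter Fit the correction before instead of after
#'   the diagnosis filter.
#' @param spec An [svm_spec()].
#' @param methods Selection methods to run, subset of `c("SVMFS",
#'   "SVMTFS")`.
#' @param threshold Selection continuation threshold.
#' @param scheme A [split_scheme()] for the repeated evaluation.
#' @param validation_scheme A [split_scheme()] for within-validation-cohort
#'   evaluation (default 20 + 20 training draws).
#' @param fixed_panels Named list of user-supplied panels (character
#'   vectors of feature ids) evaluated alongside the discovered ones.
#' @param top_k Number of rows of the single-feature ranking to report.
#' @param group_field Optional sample-metadata column for per-group LOOCV.
#' @param out_dir Run directory (created if needed).
#' @param seed Master seed governing generation and resampling.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, meta_path = NULL,
                            synthetic = NULL, pool_path = NULL,
                            probe_map_path = NULL,
                            keep_diagnoses = c("AD", "CONTROL"),
                            correct = TRUE, correct_before_filter = FALSE,
                            spec = svm_spec(), methods = c("SVMFS", "SVMTFS"),
                            threshold = 0, scheme = split_scheme(),
                            validation_scheme = split_scheme(20, 20, scheme$n_repeats,
                                                            scheme$seed),
                            fixed_panels = list(), top_k = 20,
                            group_field = NULL, out_dir = tempfile("panelfs_run_"),
                            seed = 1) {
  has_paths <- !is.null(matrix_path) || !is.null(meta_path)
  has_syn <- !is.null(synthetic)
  if (has_paths && has_syn)
    stopf("give either input paths or a synthetic spec, not both")
  if (!has_paths && !has_syn)
    stopf("one of {matrix_path + meta_path, synthetic} is required")
  if (has_paths && (is.null(matrix_path) || is.null(meta_path)))
    stopf("both matrix_path and meta_path are required")
  if (has_syn && !inherits(synthetic, "synthetic_spec"))
    stopf("`synthetic` must be a synthetic_spec")
  methods <- match.arg(methods, c("SVMFS", "SVMTFS"), several.ok = TRUE)
  structure(list(matrix_path = matrix_path, meta_path = meta_path,
                 synthetic = synthetic, pool_path = pool_path,
                 probe_map_path = probe_map_path,
                 keep_diagnoses = keep_diagnoses, correct = correct,
                 correct_before_filter = correct_before_filter,
                 spec = spec, methods = methods, threshold = threshold,
                 scheme = scheme, validation_scheme = validation_scheme,
                 fixed_panels = fixed_panels, top_k = top_k,
                 group_field = group_field, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

run_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

prepare_dataset <- function(cfg, ds) {
  steps <- function(d) {
    if (cfg$correct && !cfg$correct_before_filter) {
      d <- filter_diagnoses(d, cfg$keep_diagnoses)
      d <- floor_log_transform(d)
      d <- apply_correction(d, fit_robust_correction(d))
    } else if (cfg$correct) {
      d <- floor_log_transform(d)
      d <- apply_correction(d, fit_robust_correction(d))
      d <- filter_diagnoses(d, cfg$keep_diagnoses)
    } else {
      d <- filter_diagnoses(d, cfg$keep_diagnoses)
      d <- floor_log_transform(d)
    }
    d
  }
  d <- steps(ds)
  if (!is.null(cfg$pool_path)) {
    mapping <- if (!is.null(cfg$probe_map_path)) read_probe_map(cfg$probe_map_path)
    d <- restrict_to_pool(d, read_gene_pool(cfg$pool_path), mapping)
  }
  d
}

manifest <- function(cfg, extra = list()) {
  cfg_plain <- lapply(unclass(cfg), function(x)
    if (is.object(x)) unclass(x) else x)
  c(list(package = "panelfs",
         package_version = as.character(utils::packageVersion("panelfs")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = cfg$seed,
         config = cfg_plain,
         config_hash = fnv1a32(paste(deparse(cfg_plain), collapse = ""))),
    extra)
}

#' Run the discovery pipeline
#'
#' Executes load/generate, diagnosis filter, floor+log2 transform, robust
#' age/gender correction, pool restriction, the single-feature ranking
#' table, the configured forward selections, and the repeated-split
#' evaluation of every discovered and fixed panel; writes all tables and a
#' provenance manifest under the run directory. Any stage error aborts with
#' the stage name and leaves a `FAILED` marker beside the partial outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the run directory, the processed dataset,
#'   ranking, traces and metrics.
#' @export
run_discovery <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- cfg$out_dir

  ds <- run_stage("load", od, {
    if (!is.null(cfg$synthetic))
      generate_cohort(cfg$synthetic, seed = cfg$seed)$dataset
    else read_expression(cfg$matrix_path, cfg$meta_path, cfg$probe_map_path)
  })
  prep <- run_stage("preprocess", od, prepare_dataset(cfg, ds))

  ranking <- run_stage("rank", od, rank_single_features(prep, cfg$spec))
  write_tsv_full(utils::head(ranking, cfg$top_k), file.path(od, "ranking_top.tsv"))

  traces <- list()
  for (m in cfg$methods) {
    tr <- run_stage(paste0("select_", m), od,
                    if (m == "SVMFS") svmfs(prep, cfg$spec, cfg$threshold)
                    else svmtfs(prep, cfg$spec, cfg$threshold))
    write_trace(tr, file.path(od, paste0("trace_", tolower(m))), seed = cfg$seed)
    traces[[m]] <- tr
  }

  panels <- c(lapply(traces, function(t) t$selected), cfg$fixed_panels)
  metrics <- run_stage("evaluate", od, {
    rows <- lapply(names(panels), function(nm) {
      cv <- repeated_split_cv(prep, panels[[nm]], cfg$spec,
                              split_scheme(cfg$scheme$n_train_pos,
                                           cfg$scheme$n_train_neg,
                                           cfg$scheme$n_repeats, cfg$seed))
      data.frame(panel = nm, features = paste(cv$panel, collapse = "+"),
                 t(unclass(cv$summary)), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  write_tsv_full(metrics, file.path(od, "panel_metrics.tsv"))
  jsonlite::write_json(manifest(cfg, list(stage = "discovery")),
                       file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = od, dataset = prep, ranking = ranking,
                 traces = traces, metrics = metrics))
}

#' Run the validation pipeline
#'
#' For a panel discovered on (or supplied with) a discovery cohort:
#' cross-cohort validation (train on discovery, test on validation),
#' within-validation-cohort repeated evaluation, optional per-group LOOCV,
#' banded-interval fits and pairwise marker correlations for every panel
#' feature in both cohorts. Writes the corresponding tables and ROC points.
#'
#' @param cfg A [pipeline_config()] (its `validation_scheme` drives the
#'   within-cohort evaluation).
#' @param discovery,validation Processed [expr_dataset()] cohorts (e.g. the
#'   `dataset` element of [run_discovery()]'s result and a validation cohort
#'   prepared the same way).
#' @param panel A `selection_trace` or character vector of feature ids.
#' @return Invisibly, a list with the run directory and all computed
#'   results.
#' @export
run_validation <- function(cfg, discovery, validation, panel) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (inherits(panel, "selection_trace")) panel <- panel$selected
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- cfg$out_dir

  cross <- run_stage("cross_cohort", od,
                     cross_cohort_validate(discovery, validation, panel, cfg$spec))
  write_tsv_full(data.frame(t(unclass(cross$metrics))),
                 file.path(od, "cross_cohort_metrics.tsv"))
  if (!is.null(cross$roc))
    write_tsv_full(cross$roc$points, file.path(od, "cross_cohort_roc.tsv"))

  vs <- cfg$validation_scheme
  within <- run_stage("within_validation_cv", od, {
    vpanel <- cross$matched$test_feature
    repeated_split_cv(validation, vpanel, cfg$spec,
                      split_scheme(vs$n_train_pos, vs$n_train_neg,
                                   vs$n_repeats, cfg$seed))
  })
  write_tsv_full(data.frame(t(unclass(within$summary))),
                 file.path(od, "validation_cv_metrics.tsv"))

  grouped <- NULL
  if (!is.null(cfg$group_field) &&
      any(!is.na(validation$sample_meta[[cfg$group_field]]))) {
    grouped <- run_stage("grouped_loocv", od,
                         grouped_loocv(validation, cross$matched$test_feature,
                                       cfg$spec, cfg$group_field))
    write_tsv_full(grouped, file.path(od, "grouped_loocv.tsv"))
  }

  banded <- run_stage("banded_fits", od, {
    rows <- list()
    for (nm in c("discovery", "validation")) {
      co <- if (nm == "discovery") discovery else validation
      feats <- if (nm == "discovery") panel else cross$matched$test_feature
      for (f in feats) {
        v <- co$values[, match(f, co$feature_meta$feature_id)]
        bf <- tryCatch(fit_banded(v, co$sample_meta$diagnosis, cfg$spec$positive),
                       error = function(e) NULL)
        if (!is.null(bf))
          rows[[paste(nm, f)]] <- data.frame(
            cohort = nm, feature_id = f, lower = bf$lower, upper = bf$upper,
            interval_accuracy = bf$interval_accuracy,
            single_threshold_accuracy = bf$best_single_threshold_accuracy,
            is_banded = bf$is_banded, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  if (!is.null(banded)) {
    rownames(banded) <- NULL
    write_tsv_full(banded, file.path(od, "banded_fits.tsv"))
  }

  correlations <- run_stage("correlations", od,
                            panel_correlations(discovery, panel))
  jsonlite::write_json(manifest(cfg, list(stage = "validation", panel = panel)),
                       file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = od, cross_cohort = cross, within_validation = within,
                 grouped = grouped, banded = banded,
                 correlations = correlations))
}
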