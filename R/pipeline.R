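#' Declarative configuration of the full origin-discrimination pipeline
#'
#' Collects every tunable of the pipeline in one validated object. When
#' `peak_list_dir` is `NULL` the synthetic generator supplies training and
#' test peak lists from `spec`; otherwise per-sample CSVs are read from disk
#' (`origins` taken from an optional `samples.csv` with columns
#' `sample_id, origin`).
#'
#' @param out_dir Output directory for the run's artifacts.
#' @param spec A [synthetic_spec()] used when simulating input.
#' @param test_n_per_class Per-class counts of simulated held-out samples
#'   (default one LN, two HLJ, five JL batches).
#' @param peak_list_dir Optional directory of per-sample peak-list CSVs.
#' @param db_path Ginsenoside reference table CSV (default: packaged copy).
#' @param min_area,charge,min_quality Screening thresholds, see
#'   [screen_peaks()].
#' @param mz_tol_ppm,rt_tol Alignment tolerances, see [align_peaks()].
#' @param max_missing_frac Common-peak rule, see [filter_common_peaks()].
#' @param annotate_mz_tol_ppm,annotate_rt_tol Annotation windows.
#' @param C_grid,gamma_grid,k Grid search and CV settings.
#' @param n_importance Permutation repeats for marker discovery.
#' @param report_mode `"out_of_fold"` (recognized = CV prediction) or
#'   `"resubstitution"` (recognized = refit-on-all prediction).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            spec = synthetic_spec(),
                            test_n_per_class = c(1L, 2L, 5L),
                            peak_list_dir = NULL,
                            db_path = system.file("extdata",
                                                  "ginsenosides_table1.csv",
                                                  package = "ginsengms"),
                            min_area = 1000, charge = 1L, min_quality = 60,
                            mz_tol_ppm = 10, rt_tol = 0.2,
                            max_missing_frac = 0.8,
                            annotate_mz_tol_ppm = 15, annotate_rt_tol = 0.5,
                            C_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            k = 10L,
                            n_importance = 10L,
                            report_mode = c("out_of_fold", "resubstitution"),
                            seed = 1L) {
  report_mode <- match.arg(report_mode)
  if (!file.exists(db_path)) stop_field("db_path", "file does not exist")
  if (!is.null(peak_list_dir) && !dir.exists(peak_list_dir))
    stop_field("peak_list_dir", "directory does not exist")
  stopifnot(inherits(spec, "synthetic_spec"))
  cfg <- list(out_dir = out_dir, spec = spec,
              test_n_per_class = test_n_per_class,
              peak_list_dir = peak_list_dir, db_path = db_path,
              min_area = min_area, charge = charge, min_quality = min_quality,
              mz_tol_ppm = mz_tol_ppm, rt_tol = rt_tol,
              max_missing_frac = max_missing_frac,
              annotate_mz_tol_ppm = annotate_mz_tol_ppm,
              annotate_rt_tol = annotate_rt_tol,
              C_grid = C_grid, gamma_grid = gamma_grid, k = as.integer(k),
              n_importance = as.integer(n_importance),
              report_mode = report_mode, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(stage, t0) {
  message(sprintf("[ginsengms] %-22s %6.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full origin-discrimination pipeline
#'
#' Orchestrates, in order: input acquisition (simulation or CSV ingestion),
#' peak screening, alignment, common-peak filtering, ginsenoside annotation,
#' mean and Z-score normalization, PCA and PLS-DA baselines, SVM grid
#' search, raw-vs-normalized training reports, permutation-importance marker
#' discovery, the marker-panel SVM, and prediction of the held-out samples.
#' Every artifact is written to `config$out_dir` as CSV and listed with its
#' MD5 checksum in `manifest.json`; identical config + seed gives identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run's key objects (`feature_table`,
#'   `grid`, `reports`, `importance`, `markers`, `marker_model`,
#'   `test_report`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  seed <- config$seed
  artifacts <- character(0)
  put <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
    path
  }

  # --- input ---------------------------------------------------------------
  if (is.null(config$peak_list_dir)) {
    pls <- generate_peak_lists(config$spec)
    test_ft <- generate_feature_table(config$spec,
                                      n_per_class = config$test_n_per_class,
                                      sample_seed = derive_seed(seed, 17L),
                                      sample_prefix = "T")
  } else {
    files <- list.files(config$peak_list_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    files <- files[!grepl("samples\\.csv$", files)]
    meta_path <- file.path(config$peak_list_dir, "samples.csv")
    meta <- if (file.exists(meta_path)) read.csv(meta_path) else NULL
    pls <- lapply(files, function(f) {
      sid <- sub("\\.csv$", "", basename(f))
      org <- if (!is.null(meta) && sid %in% meta$sample_id)
        meta$origin[match(sid, meta$sample_id)] else NA_character_
      read_peak_list(f, sample_id = sid, origin = org)
    })
    test_ft <- NULL
  }
  pipeline_log("input", t0)

  # --- preprocess ----------------------------------------------------------
  pls <- lapply(pls, screen_peaks, min_area = config$min_area,
                charge = config$charge, min_quality = config$min_quality)
  ft <- align_peaks(pls, mz_tol_ppm = config$mz_tol_ppm, rt_tol = config$rt_tol)
  ft <- filter_common_peaks(ft, max_missing_frac = config$max_missing_frac)
  put("feature_table.csv", function(p) write_feature_table(ft, p))
  pipeline_log("preprocess", t0)

  # --- annotation ----------------------------------------------------------
  db <- load_ginsenoside_db(config$db_path)
  hits <- annotate_features(ft, db, mz_tol_ppm = config$annotate_mz_tol_ppm,
                            rt_tol = config$annotate_rt_tol)
  put("annotation_hits.csv", function(p) write.csv(hits, p, row.names = FALSE))
  pipeline_log("annotate", t0)

  # --- normalization + baselines ------------------------------------------
  nt_mean <- normalize_mean(ft)
  nt_z <- normalize_zscore(ft)
  put("normalized_mean.csv", function(p)
    write.csv(data.frame(sample_id = ft$sample_ids, nt_mean$values,
                         check.names = FALSE), p, row.names = FALSE))
  put("normalized_zscore.csv", function(p)
    write.csv(data.frame(sample_id = ft$sample_ids, nt_z$values,
                         check.names = FALSE), p, row.names = FALSE))

  pca <- fit_pca(nt_z, n_components = 2L)
  put("pca_summary.csv", function(p)
    write.csv(data.frame(component = seq_along(pca$explained_variance_ratio),
                         explained_variance_ratio = pca$explained_variance_ratio),
              p, row.names = FALSE))
  pls_fit <- fit_plsda(nt_z, cv_seed = derive_seed(seed, 2L))
  put("plsda_summary.csv", function(p)
    write.csv(data.frame(R2Y = pls_fit$R2Y, Q2 = pls_fit$Q2,
                         n_components = pls_fit$n_components),
              p, row.names = FALSE))
  pipeline_log("baselines", t0)

  # --- SVM grid search + training reports ----------------------------------
  gs <- grid_search(nt_z, C_grid = config$C_grid,
                    gamma_grid = config$gamma_grid, k = config$k,
                    seed = derive_seed(seed, 3L))
  put("grid_surface.csv", function(p)
    write.csv(gs$surface, p, row.names = FALSE))

  recognize <- function(x) {
    if (config$report_mode == "out_of_fold")
      cross_validate(x, ft$origins, C = gs$best_C, gamma = gs$best_gamma,
                     k = config$k, seed = derive_seed(seed, 3L))$predicted
    else
      predict(fit_multiclass_svm(as_area_matrix(x), ft$origins, C = gs$best_C,
                                 gamma = gs$best_gamma), as_area_matrix(x))
  }
  raw_rep <- classification_report(ft$sample_ids, ft$origins, recognize(ft))
  norm_rep <- classification_report(ft$sample_ids, ft$origins, recognize(nt_z))
  put("training_report.csv", function(p)
    write.csv(data.frame(sample = raw_rep$pairs$sample,
                         actual = raw_rep$pairs$actual,
                         recognized_raw = raw_rep$pairs$recognized,
                         recognized_normalized = norm_rep$pairs$recognized),
              p, row.names = FALSE))
  pipeline_log("svm", t0)

  # --- markers -------------------------------------------------------------
  imp <- permutation_importance(nt_z, C = gs$best_C, gamma = gs$best_gamma,
                                N = config$n_importance, k = config$k,
                                seed = derive_seed(seed, 4L))
  ann_by_feature <- vapply(ft$feature_meta$feature, function(f) {
    h <- hits$name[hits$feature == f]
    if (length(h)) h[1] else ""
  }, character(1))
  put("importance_report.csv", function(p)
    write.csv(cbind(imp$importance,
                    mz = ft$feature_meta$mz, rt = ft$feature_meta$rt,
                    annotation = ann_by_feature), p, row.names = FALSE))
  markers <- suppressWarnings(select_markers(imp))
  if (length(markers) == 0L) {
    # degenerate run: no feature has IV > 0; keep the top-ranked feature so
    # the marker model stage stays defined
    warning("no feature has importance > 0; using the top-ranked feature")
    markers <- imp$importance$feature[imp$importance$rank == 1L]
  }
  put("markers.csv", function(p)
    write.csv(data.frame(marker = markers), p, row.names = FALSE))
  refit <- refit_on_markers(nt_z, ft$origins, markers, C_grid = config$C_grid,
                            gamma_grid = config$gamma_grid, k = config$k,
                            seed = derive_seed(seed, 5L))
  put("marker_model.json", function(p) write_svm_model(refit$model, p))
  pipeline_log("markers", t0)

  # --- held-out prediction -------------------------------------------------
  test_rep <- NULL
  if (!is.null(test_ft)) {
    test_rep <- predict_external(refit$model, test_ft, norm_stats = nt_z)
    put("test_report.csv", function(p)
      write.csv(test_rep$pairs, p, row.names = FALSE))
  }
  pipeline_log("predict", t0)

  manifest <- list(seed = seed, created = "run",
                   artifacts = data.frame(
                     file = basename(artifacts),
                     md5 = unname(tools::md5sum(artifacts))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA, auto_unbox = TRUE)
  pipeline_log("done", t0)

  invisible(list(feature_table = ft, annotation = hits, pca = pca,
                 plsda = pls_fit, grid = gs,
                 reports = list(raw = raw_rep, normalized = norm_rep),
                 importance = imp, markers = markers,
                 marker_model = refit$model, test_report = test_rep,
                 manifest = manifest))
}

#' Side-by-side training / test origin report
#'
#' Formats raw-data and normalized-data training calls next to each other
#' with their accuracies, plus an optional held-out block -- the layout of
#' an origin-recognition results table.
#'
#' @param raw_pairs,norm_pairs Data frames with `sample`, `actual`,
#'   `recognized` (equal length, same samples).
#' @param test_pairs Optional held-out block in the same shape.
#' @return Character vector of report lines (also printed).
#' @export
make_report <- function(raw_pairs, norm_pairs, test_pairs = NULL) {
  if (inherits(raw_pairs, "classification_report")) raw_pairs <- raw_pairs$pairs
  if (inherits(norm_pairs, "classification_report")) norm_pairs <- norm_pairs$pairs
  if (inherits(test_pairs, "classification_report")) test_pairs <- test_pairs$pairs
  if (nrow(raw_pairs) == 0 || nrow(norm_pairs) == 0)
    stop_field("pairs", "must be nonempty")
  if (nrow(raw_pairs) != nrow(norm_pairs))
    stop_field("pairs", "raw and normalized blocks differ in length")
  acc_raw <- accuracy_from_pairs(raw_pairs$actual, raw_pairs$recognized)
  acc_norm <- accuracy_from_pairs(norm_pairs$actual, norm_pairs$recognized)
  lines <- c(sprintf("Raw Data (Accuracy = %d%%) | Normalized Data (Accuracy = %d%%)",
                     acc_raw, acc_norm),
             sprintf("%-8s %-6s %-11s | %-6s %-11s", "Sample", "Actual",
                     "Recognized", "Actual", "Recognized"),
             sprintf("%-8s %-6s %-11s | %-6s %-11s", raw_pairs$sample,
                     raw_pairs$actual, raw_pairs$recognized,
                     norm_pairs$actual, norm_pairs$recognized))
  if (!is.null(test_pairs) && nrow(test_pairs) > 0) {
    acc_test <- accuracy_from_pairs(test_pairs$actual, test_pairs$recognized)
    lines <- c(lines, "",
               sprintf("Test Samples (Accuracy = %d%%)", acc_test),
               sprintf("%-8s %-6s %-11s", "Sample", "Actual", "Recognized"),
               sprintf("%-8s %-6s %-11s", test_pairs$sample,
                       test_pairs$actual, test_pairs$recognized))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Packaged reference origin calls
#'
#' Published origin assignments for 31 training batches (with the calls of
#' both the raw-data and the Z-score-normalized SVM) and 8 market test
#' batches of ginseng from Jilin (JL), Liaoning (LN) and Heilongjiang (HLJ),
#' shipped as worked-example input for [accuracy_from_pairs()].
#'
#' @param which `"training"` or `"test"`.
#' @return The corresponding `data.frame`.
#' @export
reference_origin_calls <- function(which = c("training", "test")) {
  which <- match.arg(which)
  fn <- if (which == "training") "training_origin_calls.csv" else "test_origin_calls.csv"
  read.csv(system.file("extdata", fn, package = "ginsengms"),
           stringsAsFactors = FALSE)
}
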