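#' @name experiments
#' @title Factorial sweep experiments and reports
#'
#' @description
#' The three sweeps mirror the study design: segment length x feature set x
#' classifier on the full band; frequency band x classifier at the selected
#' length and features; scalp region under the hold-out protocol at the
#' selected band and classifier. Because every protocol reseeds iteration
#' `i` at `seed + i`, fold assignments are identical across classifiers
#' within an iteration, making cells directly comparable (paired).
#'
#' Sweeps are resumable: with a `cache_dir`, each completed cell is stored
#' under a key built from its factor levels, the seed and a cohort
#' fingerprint, and is never recomputed.
NULL

cohort_fingerprint <- function(cohort) {
  grp <- vapply(cohort, function(r) r$meta$group, "")
  s <- sum(vapply(cohort, function(r) sum(r$signal[1, ]), 0))
  sprintf("n%d_d%d_%s", length(cohort), sum(grp == "depressed"),
          fmt_num(s))
}

cell_cached <- function(key, cache_dir, compute) {
  if (is.null(cache_dir)) return(compute())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(gsub("[^A-Za-z0-9_.-]", "-", key), ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

#' The feature-set grid of the segment-length sweep
#'
#' Every feature alone, plus the four combinations examined in the study:
#' Hjorth + entropies, variance + entropies, skewness + kurtosis, and all
#' features except variance (a duplicate of activity).
#'
#' @return Named list of feature-name vectors.
#' @export
default_feature_grid <- function() {
  singles <- c("variance", "activity", "mobility", "complexity",
               "shannon_entropy", "log_energy_entropy", "kurtosis",
               "skewness")
  c(stats::setNames(lapply(singles, identity), singles),
    list(hjorth = feature_set("hjorth"),
         entropy = feature_set("entropy"),
         hjorth_entropy = feature_set("hjorth_entropy"),
         variance_entropy = feature_set("variance_entropy"),
         skew_kurt = feature_set("skew_kurt"),
         all = feature_set("all")))
}

#' Segment length x feature set x classifier sweep (full band)
#'
#' For each segment length the cohort is band-filtered (full band by
#' default), segmented, reduced to each feature set, and scored with
#' iterated stratified k-fold CV under every classifier preset.
#'
#' @param cohort An `"eeg_cohort"`.
#' @param seg_lengths_s Segment lengths in seconds (default 1:5).
#' @param feature_sets Named list of feature vectors (default
#'   [default_feature_grid()]).
#' @param presets Classifier preset names (default all ten).
#' @param band Filter band (default `"FULL"`).
#' @param folds,iterations,seed CV protocol parameters.
#' @param cache_dir Optional cell cache directory.
#' @return Data frame with one row per (segment_s, feature_set, classifier):
#'   `accuracy_mean` / `accuracy_sd` on the percent scale (2 decimals).
#' @export
sweep_segments_features <- function(cohort, seg_lengths_s = 1:5,
                                    feature_sets = default_feature_grid(),
                                    presets = classifier_presets(),
                                    band = "FULL", folds = 5L,
                                    iterations = 5L, seed = 1L,
                                    cache_dir = NULL) {
  fp <- cohort_fingerprint(cohort)
  rows <- list()
  for (len in seg_lengths_s) {
    segs <- preprocess_cohort(cohort, band, len)
    for (fs_name in names(feature_sets)) {
      fm <- build_feature_matrix(segs, feature_sets[[fs_name]])
      for (p in presets) {
        key <- paste("segfeat", band, len, fs_name, p, folds, iterations,
                     seed, fp, sep = "_")
        rep <- cell_cached(key, cache_dir, function() {
          run_cv(fm, p, folds = folds, iterations = iterations, seed = seed)
        })
        acc <- rep$summary[rep$summary$metric == "accuracy", ]
        rows[[length(rows) + 1L]] <- data.frame(
          segment_s = len, feature_set = fs_name, classifier = p,
          accuracy_mean = round(100 * acc$mean, 2),
          accuracy_sd = round(100 * acc$sd, 2))
      }
    }
  }
  do.call(rbind, rows)
}

#' Frequency band x classifier sweep
#'
#' At a fixed segment length and feature set, scores every (band,
#' classifier) cell with iterated CV. Defaults cover the five canonical
#' sub-bands and the five combinations.
#'
#' @inheritParams sweep_segments_features
#' @param bands Band names (default the five sub-bands then the five
#'   combinations).
#' @param seg_len_s Segment length (default 5).
#' @param features Feature set (default `"hjorth_entropy"`).
#' @return Data frame, one row per (band, classifier), accuracy on the
#'   percent scale.
#' @export
sweep_bands <- function(cohort, bands = c("DELTA", "THETA", "ALPHA", "BETA",
                                          "GAMMA", "ABDT", "ABT", "AB",
                                          "ABTG", "ABG"),
                        seg_len_s = 5, features = "hjorth_entropy",
                        presets = classifier_presets(), folds = 5L,
                        iterations = 25L, seed = 1L, cache_dir = NULL) {
  fp <- cohort_fingerprint(cohort)
  rows <- list()
  for (b in bands) {
    fm <- build_feature_matrix(preprocess_cohort(cohort, b, seg_len_s),
                               features)
    for (p in presets) {
      key <- paste("band", b, seg_len_s, p, folds, iterations, seed, fp,
                   sep = "_")
      rep <- cell_cached(key, cache_dir, function() {
        run_cv(fm, p, folds = folds, iterations = iterations, seed = seed)
      })
      acc <- rep$summary[rep$summary$metric == "accuracy", ]
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, classifier = p,
        accuracy_mean = round(100 * acc$mean, 2),
        accuracy_sd = round(100 * acc$sd, 2))
    }
  }
  do.call(rbind, rows)
}

#' Scalp-region sweep under the 70/30 hold-out protocol
#'
#' For each region of [region_map()], restricts the feature matrix to the
#' region's channels and runs [run_split_cv()]; reports the full metric
#' summary per region.
#'
#' @inheritParams sweep_bands
#' @param regions Region names (default the full catalogue).
#' @param preset Classifier preset (default `"fine_knn"`).
#' @param iterations Default 10.
#' @return Data frame, one row per region: mean and SD of training, testing
#'   and overall accuracy (percent) plus the five other testing metrics
#'   (0-1 scale).
#' @export
sweep_regions <- function(cohort, regions = names(region_map()),
                          band = "AB", seg_len_s = 5,
                          features = "hjorth_entropy", preset = "fine_knn",
                          folds = 5L, iterations = 10L, seed = 1L,
                          cache_dir = NULL) {
  fp <- cohort_fingerprint(cohort)
  segs <- preprocess_cohort(cohort, band, seg_len_s)
  rmap <- region_map()
  rows <- list()
  for (rg in regions) {
    fm <- build_feature_matrix(segs, features, channels = rmap[[rg]])
    key <- paste("region", rg, band, seg_len_s, preset, folds, iterations,
                 seed, fp, sep = "_")
    rep <- cell_cached(key, cache_dir, function() {
      run_split_cv(fm, preset, folds = folds, iterations = iterations,
                   seed = seed)
    })
    s <- rep$summary
    g <- function(m, what) s[[what]][s$metric == m]
    rows[[length(rows) + 1L]] <- data.frame(
      region = rg,
      training_accuracy_mean = round(100 * g("training_accuracy", "mean"), 2),
      training_accuracy_sd = round(100 * g("training_accuracy", "sd"), 2),
      testing_accuracy_mean = round(100 * g("testing_accuracy", "mean"), 2),
      testing_accuracy_sd = round(100 * g("testing_accuracy", "sd"), 2),
      overall_accuracy_mean = round(100 * g("overall_accuracy", "mean"), 2),
      overall_accuracy_sd = round(100 * g("overall_accuracy", "sd"), 2),
      precision_mean = g("precision", "mean"), precision_sd = g("precision", "sd"),
      npv_mean = g("npv", "mean"), npv_sd = g("npv", "sd"),
      sensitivity_mean = g("sensitivity", "mean"), sensitivity_sd = g("sensitivity", "sd"),
      specificity_mean = g("specificity", "mean"), specificity_sd = g("specificity", "sd"),
      f1_mean = g("f1", "mean"), f1_sd = g("f1", "sd"))
  }
  do.call(rbind, rows)
}

#' Write sweep tables plus a run-metadata echo
#'
#' @param tables Non-empty named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional list echoed into `run_metadata.json`.
#' @return Character vector of written file paths, invisibly.
#' @export
make_report <- function(tables, out_dir, config = list()) {
  if (length(tables) == 0) stop("empty table list", call. = FALSE)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be named", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_result_table_csv(tables[[nm]], p)
    p
  }, "")
  meta <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(c(config, list(r_version = R.version.string,
                                      package_version =
                                        as.character(utils::packageVersion("depscreen")))),
                       meta, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, meta))
}

#' The end-to-end screening pipeline at the selected settings
#'
#' Runs the selected configuration — 5 s segments, Hjorth + entropy
#' features, the alpha-through-beta (8--30 Hz) band, fine KNN, whole
#' brain — under both protocols: iterated 5-fold CV and the 70/30 hold-out
#' with CV on the training part.
#'
#' @param cohort An `"eeg_cohort"`.
#' @param seed Base seed.
#' @param cv_iterations Iterations for the CV protocol (default 25).
#' @param split_iterations Iterations for the hold-out protocol (default 10).
#' @return List with `feature_matrix`, `cv` and `split` eval reports.
#' @export
run_screening_pipeline <- function(cohort, seed = 1L, cv_iterations = 25L,
                                   split_iterations = 10L) {
  fm <- build_feature_matrix(preprocess_cohort(cohort, "AB", 5),
                             "hjorth_entropy")
  list(feature_matrix = fm,
       cv = run_cv(fm, "fine_knn", folds = 5L, iterations = cv_iterations,
                   seed = seed),
       split = run_split_cv(fm, "fine_knn", folds = 5L,
                            iterations = split_iterations, seed = seed))
}
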