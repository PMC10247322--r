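#' Binary confusion matrix with "depressed" as the positive class
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param positive Positive-class label (default `"depressed"`).
#' @return List of counts `TP`, `TN`, `FP`, `FN`, class
#'   `"confusion_matrix"`.
#' @export
confusion_matrix <- function(truth, pred, positive = "depressed") {
  stopifnot(length(truth) == length(pred))
  structure(list(
    TP = sum(truth == positive & pred == positive),
    TN = sum(truth != positive & pred != positive),
    FP = sum(truth != positive & pred == positive),
    FN = sum(truth == positive & pred != positive)
  ), class = "confusion_matrix")
}

#' The six confusion-matrix performance metrics
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, negative predictive
#' value `TN/(TN+FN)`, sensitivity (recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and F1 `2TP/(2TP+FP+FN)` — the harmonic mean of precision
#' and sensitivity. A metric with zero denominator is reported as `NA`
#' (missing), never coerced to 0; the names of undefined metrics are
#' attached as attribute `"undefined"`.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector
#'   `c(accuracy, precision, npv, sensitivity, specificity, f1)` on the 0-1
#'   scale.
#' @examples
#' m <- compute_metrics(structure(list(TP = 50, TN = 40, FP = 10, FN = 0),
#'                                class = "confusion_matrix"))
#' round(m["f1"], 4)  # 0.9091
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(accuracy = ratio(cm$TP + cm$TN, tot),
           precision = ratio(cm$TP, cm$TP + cm$FP),
           npv = ratio(cm$TN, cm$TN + cm$FN),
           sensitivity = ratio(cm$TP, cm$TP + cm$FN),
           specificity = ratio(cm$TN, cm$TN + cm$FP),
           f1 = ratio(2 * cm$TP, 2 * cm$TP + cm$FP + cm$FN))
  und <- names(out)[is.na(out)]
  if (length(und) > 0) attr(out, "undefined") <- und
  out
}

# Stratified fold assignment at the row level: within each class, rows are
# shuffled and dealt round-robin, so per-fold class counts differ from the
# global ratio by at most one row.
stratified_folds <- function(labels, k) {
  if (min(table(labels)) < k) {
    stop("stratification error: a class has fewer rows (",
         min(table(labels)), ") than folds (", k, ")", call. = FALSE)
  }
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    # random fold numbering per class so the remainder rows do not always
    # land in the lowest-numbered folds
    fold[idx] <- rep_len(sample(k), length(idx))
  }
  fold
}

# Stratified train/test row split preserving the class ratio.
stratified_split <- function(labels, train_fraction) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n_tr <- round(train_fraction * length(idx))
    train[idx[seq_len(n_tr)]] <- TRUE
  }
  train
}

summarize_iterations <- function(per_iter) {
  data.frame(metric = colnames(per_iter),
             mean = colMeans(per_iter, na.rm = TRUE),
             sd = apply(per_iter, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}

#' Iterated stratified k-fold cross-validation
#'
#' For each iteration, rows are shuffled and dealt into `folds` stratified
#' folds at the segment level; out-of-fold predictions are pooled into one
#' confusion matrix per iteration and scored with [compute_metrics()].
#' Iteration `i` reseeds the RNG at `seed + i`, so any single iteration can
#' be reproduced in isolation. Summary is the mean and SD of each metric
#' over iterations.
#'
#' Note that segment-level folding lets segments of one subject span the
#' train/test boundary; see [run_grouped_cv()] for the subject-level
#' diagnostic.
#'
#' @param fm A `"feature_matrix"` containing both classes.
#' @param spec A [classifier_spec()] or preset name.
#' @param folds Number of folds (default 5).
#' @param iterations Number of shuffled repetitions (default 25).
#' @param seed Base seed.
#' @return An `"eval_report"`: list with `per_iteration` (data frame, one
#'   row per iteration), `summary` (metric, mean, sd) and `config`.
#' @export
run_cv <- function(fm, spec, folds = 5L, iterations = 25L, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(fm, "feature_matrix"), folds >= 2, iterations >= 1)
  per <- matrix(NA_real_, nrow = iterations, ncol = 6,
                dimnames = list(NULL, c("accuracy", "precision", "npv",
                                        "sensitivity", "specificity", "f1")))
  for (i in seq_len(iterations)) {
    set.seed(as.integer(seed) + i)
    fold <- stratified_folds(fm$labels, folds)
    pred <- character(length(fm$labels))
    for (f in seq_len(folds)) {
      fit <- fit_classifier(spec, fm_rows(fm, fold != f))
      pred[fold == f] <- predict(fit, fm_rows(fm, fold == f))
    }
    per[i, ] <- compute_metrics(confusion_matrix(fm$labels, pred))
  }
  structure(list(per_iteration = as.data.frame(per),
                 summary = summarize_iterations(per),
                 config = list(protocol = "cv_only", folds = folds,
                               iterations = iterations, seed = seed,
                               preset = spec$preset)),
            class = "eval_report")
}

#' 70/30 hold-out with cross-validated training accuracy
#'
#' Per iteration: a stratified random split keeps `train_fraction` of the
#' rows for training; "training accuracy" is the mean out-of-fold accuracy
#' of a `folds`-fold CV inside the training part; the model is then refitted
#' on the full training part and scored on the held-out rows (testing
#' metrics). The "overall" accuracy is the sample-weighted combination
#' `train_fraction * training + (1 - train_fraction) * testing` — a
#' reporting convention, flagged as such in the report config.
#'
#' @inheritParams run_cv
#' @param train_fraction Training share (default 0.7).
#' @param iterations Default 10.
#' @return An `"eval_report"` whose `per_iteration` has training, testing
#'   and overall accuracy plus the five other testing metrics.
#' @export
run_split_cv <- function(fm, spec, folds = 5L, iterations = 10L,
                         train_fraction = 0.7, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(train_fraction > 0, train_fraction < 1)
  cols <- c("training_accuracy", "testing_accuracy", "overall_accuracy",
            "precision", "npv", "sensitivity", "specificity", "f1")
  per <- matrix(NA_real_, nrow = iterations, ncol = length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_len(iterations)) {
    set.seed(as.integer(seed) + i)
    in_train <- stratified_split(fm$labels, train_fraction)
    tr <- fm_rows(fm, in_train)
    te <- fm_rows(fm, !in_train)
    fold <- stratified_folds(tr$labels, folds)
    fold_acc <- vapply(seq_len(folds), function(f) {
      fit <- fit_classifier(spec, fm_rows(tr, fold != f))
      mean(predict(fit, fm_rows(tr, fold == f)) == tr$labels[fold == f])
    }, 0)
    train_acc <- mean(fold_acc)
    fit <- fit_classifier(spec, tr)
    m <- compute_metrics(confusion_matrix(te$labels, predict(fit, te)))
    per[i, ] <- c(train_acc, m[["accuracy"]],
                  train_fraction * train_acc +
                    (1 - train_fraction) * m[["accuracy"]],
                  m[["precision"]], m[["npv"]], m[["sensitivity"]],
                  m[["specificity"]], m[["f1"]])
  }
  structure(list(per_iteration = as.data.frame(per),
                 summary = summarize_iterations(per),
                 config = list(protocol = "split70_cv", folds = folds,
                               iterations = iterations,
                               train_fraction = train_fraction, seed = seed,
                               preset = spec$preset,
                               overall_accuracy_convention =
                                 "sample-weighted 0.7*training + 0.3*testing")),
            class = "eval_report")
}

#' Subject-grouped cross-validation (leakage diagnostic)
#'
#' Same protocol as [run_cv()] but folds are assigned at the subject level
#' (stratified by group), so no subject's segments span the train/test
#' boundary. Comparing this with segment-level CV on cohorts with subject
#' random effects quantifies the optimistic bias (subject leakage) of
#' segment-level folding.
#'
#' @inheritParams run_cv
#' @param iterations Default 10.
#' @return An `"eval_report"`.
#' @export
run_grouped_cv <- function(fm, spec, folds = 5L, iterations = 10L, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  subj <- unique(fm$subject_ids)
  if (length(subj) < folds) {
    stop("fewer subjects (", length(subj), ") than folds (", folds, ")",
         call. = FALSE)
  }
  subj_grp <- vapply(subj, function(s) fm$labels[match(s, fm$subject_ids)], "")
  per <- matrix(NA_real_, nrow = iterations, ncol = 6,
                dimnames = list(NULL, c("accuracy", "precision", "npv",
                                        "sensitivity", "specificity", "f1")))
  for (i in seq_len(iterations)) {
    set.seed(as.integer(seed) + i)
    subj_fold <- integer(length(subj))
    for (cl in unique(subj_grp)) {
      idx <- sample(which(subj_grp == cl))
      subj_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold <- subj_fold[match(fm$subject_ids, subj)]
    pred <- character(length(fm$labels))
    for (f in seq_len(folds)) {
      fit <- fit_classifier(spec, fm_rows(fm, fold != f))
      pred[fold == f] <- predict(fit, fm_rows(fm, fold == f))
    }
    per[i, ] <- compute_metrics(confusion_matrix(fm$labels, pred))
  }
  structure(list(per_iteration = as.data.frame(per),
                 summary = summarize_iterations(per),
                 config = list(protocol = "grouped_cv", folds = folds,
                               iterations = iterations, seed = seed,
                               preset = spec$preset)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %s, %d iterations x %d folds\n",
              x$config$preset, x$config$protocol, x$config$iterations,
              x$config$folds))
  s <- x$summary
  for (r in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.4f +/- %.4f\n", s$metric[r], s$mean[r], s$sd[r]))
  }
  invisible(x)
}
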