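#' The ten KNN/SVM classifier presets
#'
#' Returns the preset table behind [classifier_spec()]: six KNN variants
#' (fine k=1, medium k=10, coarse k=100, all Euclidean; cosine k=10 with
#' cosine distance; cubic k=10 with Minkowski p=3; weighted k=10 with
#' squared-inverse-distance vote weights) and four SVM kernels (linear,
#' quadratic and cubic polynomials, Gaussian radial basis).
#'
#' @return Character vector of the ten preset names.
#' @export
classifier_presets <- function() {
  c("fine_knn", "medium_knn", "coarse_knn", "cosine_knn", "cubic_knn",
    "weighted_knn", "linear_svm", "quadratic_svm", "cubic_svm", "gaussian_svm")
}

.preset_table <- function() {
  list(
    fine_knn     = list(family = "knn", k = 1L,   distance = "euclidean", weights = "equal"),
    medium_knn   = list(family = "knn", k = 10L,  distance = "euclidean", weights = "equal"),
    coarse_knn   = list(family = "knn", k = 100L, distance = "euclidean", weights = "equal"),
    cosine_knn   = list(family = "knn", k = 10L,  distance = "cosine",    weights = "equal"),
    cubic_knn    = list(family = "knn", k = 10L,  distance = "minkowski3", weights = "equal"),
    weighted_knn = list(family = "knn", k = 10L,  distance = "euclidean", weights = "squared_inverse"),
    linear_svm    = list(family = "svm", kernel = "linear",     degree = NA),
    quadratic_svm = list(family = "svm", kernel = "polynomial", degree = 2L),
    cubic_svm     = list(family = "svm", kernel = "polynomial", degree = 3L),
    gaussian_svm  = list(family = "svm", kernel = "radial",     degree = NA)
  )
}

#' Configure one classifier preset
#'
#' Resolves a preset name to its hyperparameters. SVM presets use
#' regularisation constant (`cost`) 1 and, for the polynomial and radial
#' kernels, kernel coefficient `gamma = 1 / n_features` (equivalently a
#' radial kernel scale of `sqrt(n_features)`); these mirror common toolbox
#' defaults and are overridable. Features are standardised (training mean /
#' SD) by default for every preset, since KNN distances are scale-sensitive.
#'
#' @param preset One of [classifier_presets()].
#' @param standardize Standardise features from training rows (default TRUE).
#' @param ... Hyperparameter overrides (`k`, `cost`, `gamma`, `degree`, ...).
#' @return Object of class `"classifier_spec"`.
#' @examples
#' classifier_spec("fine_knn")$k  # 1
#' @export
classifier_spec <- function(preset, standardize = TRUE, ...) {
  tab <- .preset_table()
  if (!preset %in% names(tab)) {
    stop("unknown classifier preset '", preset, "'; choose one of: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  spec <- tab[[preset]]
  spec$preset <- preset
  spec$standardize <- standardize
  dots <- list(...)
  spec[names(dots)] <- dots
  structure(spec, class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
make_classifier <- classifier_spec

dist_to_train <- function(test, train, distance) {
  # rows of `test` vs rows of `train`; returns n_test x n_train matrix
  switch(distance,
    euclidean = {
      cross <- tcrossprod(test, train)
      d2 <- outer(rowSums(test^2), rowSums(train^2), "+") - 2 * cross
      sqrt(pmax(d2, 0))
    },
    minkowski3 = {
      d <- matrix(0, nrow(test), nrow(train))
      for (j in seq_len(ncol(test))) {
        d <- d + abs(outer(test[, j], train[, j], "-"))^3
      }
      d^(1 / 3)
    },
    cosine = {
      nt <- sqrt(rowSums(test^2)); nr <- sqrt(rowSums(train^2))
      nt[nt == 0] <- 1; nr[nr == 0] <- 1
      1 - tcrossprod(test / nt, train / nr)
    },
    stop("unknown distance '", distance, "'", call. = FALSE)
  )
}

#' Fit a classifier preset on a feature matrix
#'
#' Standardisation parameters (per-feature mean and SD) are computed from
#' the training rows only and stored in the fitted model, so evaluation
#' protocols stay leak-free by construction. For KNN, `k` greater than
#' `n_train - 1` is capped with a warning. SVMs are fitted with
#' `e1071::svm` on the standardised features.
#'
#' @param spec A [classifier_spec()] (or preset name).
#' @param fm A `"feature_matrix"` with at least 2 rows per class.
#' @return Object of class `"fitted_classifier"`.
#' @export
fit_classifier <- function(spec, fm) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"), inherits(fm, "feature_matrix"))
  x <- fm$values
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  classes <- sort(unique(fm$labels))
  if (length(classes) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (min(table(fm$labels)) < 2) {
    stop("need at least 2 training rows per class", call. = FALSE)
  }
  if (spec$standardize) {
    mu <- colMeans(x)
    sdev <- apply(x, 2, stats::sd)
    sdev[sdev == 0] <- 1
  } else {
    mu <- rep(0, ncol(x)); sdev <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  y <- factor(fm$labels, levels = classes)

  state <- if (spec$family == "knn") {
    k <- spec$k
    if (k > nrow(xs) - 1L) {
      warning("k = ", k, " exceeds training size - 1; capped at ",
              nrow(xs) - 1L, call. = FALSE)
      k <- nrow(xs) - 1L
    }
    list(train = xs, y = y, k = k)
  } else {
    gamma <- spec$gamma %||% (1 / ncol(xs))
    e1071::svm(x = xs, y = y, kernel = spec$kernel,
               degree = if (is.na(spec$degree %||% NA)) 3L else spec$degree,
               cost = spec$cost %||% 1, gamma = gamma, coef0 = 1,
               scale = FALSE)
  }
  structure(list(spec = spec, classes = classes, mu = mu, sdev = sdev,
                 feature_names = colnames(x), state = state),
            class = "fitted_classifier")
}

knn_vote <- function(d, y, k, weights, classes) {
  # one prediction per row of distance matrix d (n_test x n_train)
  apply(d, 1, function(di) {
    ord <- order(di)          # stable: earliest training row wins distance ties
    nn <- ord[seq_len(k)]
    w <- if (weights == "squared_inverse") {
      dd <- di[nn]
      ifelse(dd < 1e-12, 1e24, 1 / dd^2)
    } else {
      rep(1, k)
    }
    score <- vapply(classes, function(cl) sum(w[y[nn] == cl]), 0)
    top <- classes[score == max(score)]
    if (length(top) == 1L) return(top)
    # tie: nearest neighbour's class if tied-top, else lowest class index
    nn_cl <- as.character(y[nn[1]])
    if (nn_cl %in% top) nn_cl else top[1]
  })
}

#' Predict class labels
#'
#' Applies the stored training standardisation, then the preset's decision
#' rule. Predictions are row-wise independent and deterministic: KNN
#' distance ties resolve to the earliest training row, vote ties to the
#' nearest neighbour's class and then to the lowest class index.
#'
#' @param object A `"fitted_classifier"`.
#' @param newdata A `"feature_matrix"` or numeric matrix with the training
#'   columns.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.fitted_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  if (!identical(colnames(x), object$feature_names)) {
    stop("feature columns do not match the training matrix", call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, object$mu), 2, object$sdev, "/")
  if (object$spec$family == "knn") {
    st <- object$state
    d <- dist_to_train(xs, st$train, object$spec$distance)
    unname(knn_vote(d, st$y, st$k, object$spec$weights, object$classes))
  } else {
    as.character(stats::predict(object$state, xs))
  }
}
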