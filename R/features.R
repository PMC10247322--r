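#' @name time_domain_features
#' @title Per-channel time-domain EEG features
#'
#' @description
#' The eight scalar features computed per channel and segment. All moments
#' are population (1/N) moments; the discrete derivative is the first
#' difference `x[k+1] - x[k]` without sampling-rate scaling (any constant
#' factor cancels in the mobility and complexity ratios).
#'
#' * `sig_variance(x)` — population variance; identical to Hjorth activity.
#' * `hjorth_activity(x)` — `Var(x)`, the signal power.
#' * `hjorth_mobility(x)` — `sqrt(Var(dx) / Var(x))`, a mean-frequency proxy
#'   in radians per sample; a pure sinusoid of digital frequency `w` gives
#'   `2*sin(w/2)`.
#' * `hjorth_complexity(x)` — `mobility(dx) / mobility(x)`, a bandwidth
#'   proxy: 1 for a pure sinusoid, larger for broadband signals.
#' * `shannon_entropy(x)` — the wavelet-entropy convention
#'   `-sum(x^2 * ln(x^2))` (see Details), with zero samples contributing 0.
#' * `log_energy_entropy(x)` — `sum(ln(x^2))`, zero samples contributing 0.
#' * `sig_kurtosis(x)` — excess kurtosis `m4/m2^2 - 3`.
#' * `sig_skewness(x)` — `m3 / m2^(3/2)`.
#'
#' Degenerate (zero-variance) input makes mobility, complexity, kurtosis and
#' skewness ill-defined; these return 0 carrying attribute
#' `degenerate = TRUE`, and [build_feature_matrix()] drops such rows.
#'
#' @details
#' The Shannon-entropy "probability" of a sample is not pinned down by the
#' usual textbook formula when applied to a real-valued signal. The default
#' here is the wavelet-toolbox convention that treats the squared sample as
#' an unnormalised energy weight, `-sum(x_i^2 ln x_i^2)`. A
#' histogram-probability estimator (`n_bins` equal-width bins over the
#' segment's range, `p` = bin relative frequency) is available via
#' `shannon_entropy(x, method = "histogram")`. Natural logarithms
#' throughout; a different base only rescales the feature and is absorbed by
#' classifier standardisation.
#'
#' @param x Numeric vector, one channel of one segment.
#' @param method For `shannon_entropy`: `"energy"` (default) or
#'   `"histogram"`.
#' @param n_bins Histogram bins when `method = "histogram"` (default 128).
#' @return A scalar feature value.
NULL

pop_moment <- function(x, k) mean((x - mean(x))^k)

#' @rdname time_domain_features
#' @export
sig_variance <- function(x) {
  if (length(x) < 2) stop("variance needs at least 2 samples", call. = FALSE)
  pop_moment(x, 2)
}

#' @rdname time_domain_features
#' @export
hjorth_activity <- function(x) sig_variance(x)

degenerate_zero <- function() structure(0, degenerate = TRUE)

#' @rdname time_domain_features
#' @export
hjorth_mobility <- function(x) {
  if (length(x) < 3) stop("mobility needs at least 3 samples", call. = FALSE)
  v <- pop_moment(x, 2)
  if (v == 0) return(degenerate_zero())
  sqrt(pop_moment(diff(x), 2) / v)
}

#' @rdname time_domain_features
#' @export
hjorth_complexity <- function(x) {
  if (length(x) < 4) stop("complexity needs at least 4 samples", call. = FALSE)
  m <- hjorth_mobility(x)
  if (m == 0) return(degenerate_zero())
  md <- hjorth_mobility(diff(x))
  as.numeric(md / m)
}

#' @rdname time_domain_features
#' @export
shannon_entropy <- function(x, method = c("energy", "histogram"),
                            n_bins = 128L) {
  method <- match.arg(method)
  if (method == "energy") {
    e <- x^2
    nz <- e > 0
    -sum(e[nz] * log(e[nz]))
  } else {
    if (length(unique(x)) == 1L) return(0)
    br <- seq(min(x), max(x), length.out = n_bins + 1L)
    p <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                  nbins = n_bins) / length(x)
    p <- p[p > 0]
    -sum(p * log(p))
  }
}

#' @rdname time_domain_features
#' @export
log_energy_entropy <- function(x) {
  e <- x^2
  nz <- e > 0
  sum(log(e[nz]))
}

#' @rdname time_domain_features
#' @export
sig_kurtosis <- function(x) {
  if (length(x) < 4) stop("kurtosis needs at least 4 samples", call. = FALSE)
  m2 <- pop_moment(x, 2)
  if (m2 == 0) return(degenerate_zero())
  pop_moment(x, 4) / m2^2 - 3
}

#' @rdname time_domain_features
#' @export
sig_skewness <- function(x) {
  if (length(x) < 3) stop("skewness needs at least 3 samples", call. = FALSE)
  m2 <- pop_moment(x, 2)
  if (m2 == 0) return(degenerate_zero())
  pop_moment(x, 3) / m2^1.5
}

.feature_funs <- list(
  variance = function(x) sig_variance(x),
  activity = function(x) hjorth_activity(x),
  mobility = function(x) hjorth_mobility(x),
  complexity = function(x) hjorth_complexity(x),
  shannon_entropy = function(x) shannon_entropy(x),
  log_energy_entropy = function(x) log_energy_entropy(x),
  kurtosis = function(x) sig_kurtosis(x),
  skewness = function(x) sig_skewness(x)
)

#' Named feature sets
#'
#' Resolves a feature-set name to the corresponding feature vector:
#' `"hjorth"` = activity + mobility + complexity; `"entropy"` = Shannon +
#' log-energy entropy; `"hjorth_entropy"` their union (the pipeline's
#' preferred set); `"variance_entropy"`; `"skew_kurt"`; `"all"` = every
#' feature except variance, which duplicates Hjorth activity exactly. A
#' character vector of individual feature names passes through unchanged.
#'
#' @param set A set name or character vector of feature names.
#' @return Character vector of feature names.
#' @export
feature_set <- function(set) {
  sets <- list(
    hjorth = c("activity", "mobility", "complexity"),
    entropy = c("shannon_entropy", "log_energy_entropy"),
    hjorth_entropy = c("activity", "mobility", "complexity",
                       "shannon_entropy", "log_energy_entropy"),
    variance_entropy = c("variance", "shannon_entropy", "log_energy_entropy"),
    skew_kurt = c("skewness", "kurtosis"),
    all = c("activity", "mobility", "complexity", "shannon_entropy",
            "log_energy_entropy", "kurtosis", "skewness")
  )
  if (length(set) == 1L && set %in% names(sets)) return(sets[[set]])
  unknown <- setdiff(set, names(.feature_funs))
  if (length(unknown) > 0) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  set
}

#' Build a segments x (channel, feature) matrix
#'
#' One row per segment; columns ordered channel-major, feature-minor and
#' named `<channel>_<feature>`. Rows whose features came out degenerate
#' (zero-variance channel in the segment) are dropped with a message; this
#' cannot occur on generated cohorts but guards real-world flat channels.
#'
#' @param segments List of `"eeg_segment"` objects.
#' @param features Feature names or a [feature_set()] name (default
#'   `"hjorth_entropy"`).
#' @param channels Channel subset (default: all channels of the first
#'   segment).
#' @return A `"feature_matrix"`: list with numeric matrix `values`, and
#'   per-row `labels` and `subject_ids`.
#' @examples
#' coh <- generate_cohort(1, 1, duration_s = 10, seed = 1)
#' fm <- build_feature_matrix(preprocess_cohort(coh, "AB", 5))
#' dim(fm$values)  # 4 segments x 70 columns
#' @export
build_feature_matrix <- function(segments, features = "hjorth_entropy",
                                 channels = NULL) {
  if (length(segments) == 0) stop("empty segment list", call. = FALSE)
  features <- feature_set(features)
  montage <- segments[[1]]$channel_names
  if (is.null(channels)) channels <- montage
  unknown <- setdiff(channels, montage)
  if (length(unknown) > 0) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cols <- as.vector(t(outer(channels, features, paste, sep = "_")))
  vals <- matrix(NA_real_, nrow = length(segments), ncol = length(cols),
                 dimnames = list(NULL, cols))
  degen <- logical(length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    j <- 0L
    for (ch in channels) {
      x <- seg$data[match(ch, seg$channel_names), ]
      for (f in features) {
        v <- .feature_funs[[f]](x)
        if (isTRUE(attr(v, "degenerate"))) degen[i] <- TRUE
        vals[i, j <- j + 1L] <- as.numeric(v)
      }
    }
  }
  labels <- vapply(segments, function(s) s$label, "")
  ids <- vapply(segments, function(s) s$subject_id, "")
  if (any(degen)) {
    message("dropping ", sum(degen), " degenerate (zero-variance) segment(s)")
    vals <- vals[!degen, , drop = FALSE]
    labels <- labels[!degen]
    ids <- ids[!degen]
  }
  structure(list(values = vals, labels = labels, subject_ids = ids,
                 channels = channels, features = features),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d columns (%d channels x %d features)\n",
              nrow(x$values), ncol(x$values), length(x$channels),
              length(x$features)))
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                 as.integer(table(x$labels))), collapse = ", "), "\n")
  invisible(x)
}

# subset a feature matrix by row index, preserving metadata alignment
fm_rows <- function(fm, idx) {
  structure(list(values = fm$values[idx, , drop = FALSE],
                 labels = fm$labels[idx], subject_ids = fm$subject_ids[idx],
                 channels = fm$channels, features = fm$features),
            class = "feature_matrix")
}
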