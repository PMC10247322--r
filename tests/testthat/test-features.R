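test_that("variance and Hjorth activity use population moments and coincide", {
  expect_identical(sig_variance(c(1, -1, 1, -1)), 1)
  expect_identical(sig_variance(rep(3, 10)), 0)
  expect_error(sig_variance(1), "at least 2")
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(5:200, 1))
    expect_identical(hjorth_activity(x), sig_variance(x))
    expect_equal(sig_variance(x), mean((x - mean(x))^2))  # 1/N, not 1/(N-1)
  }
  # sinusoid power A^2 / 2
  t <- seq(0, 50, by = 1 / 128)
  expect_equal(hjorth_activity(3 * sin(2 * pi * 7 * t)), 9 / 2,
               tolerance = 0.01)
  # scaling x by c multiplies activity by c^2
  x <- rnorm(100)
  expect_equal(hjorth_activity(5 * x), 25 * hjorth_activity(x))
})

test_that("mobility matches the sinusoid closed form and is scale-invariant", {
  t <- seq(0, 100, by = 1 / 128)
  x <- sin(2 * pi * 10 * t)
  expect_equal(hjorth_mobility(x), 2 * sin(pi * 10 / 128), tolerance = 0.01)
  # brute-force oracle on arbitrary data
  set.seed(2)
  y <- rnorm(500)
  n <- length(y); nd <- n - 1
  brute <- sqrt((sum((diff(y) - mean(diff(y)))^2) / nd) /
                  (sum((y - mean(y))^2) / n))
  expect_equal(hjorth_mobility(y), brute)
  expect_equal(hjorth_mobility(17 * y), hjorth_mobility(y))
  flat <- hjorth_mobility(rep(2, 10))
  expect_identical(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "degenerate")))
  expect_error(hjorth_mobility(c(1, 2)), "at least 3")
})

test_that("complexity is ~1 for a sinusoid, >1 for white noise, scale-free", {
  t <- seq(0, 100, by = 1 / 128)
  expect_equal(hjorth_complexity(sin(2 * pi * 10 * t)), 1, tolerance = 0.02)
  # Monte-Carlo: white noise is broadband, so complexity exceeds 1
  set.seed(3)
  cx <- replicate(1000, hjorth_complexity(rnorm(256)))
  expect_true(all(cx > 1))
  set.seed(4)
  y <- rnorm(300)
  expect_equal(hjorth_complexity(5 * y), hjorth_complexity(y))
  expect_identical(as.numeric(hjorth_complexity(rep(1, 10))), 0)
})

test_that("entropies follow the energy conventions with zero-sample terms dropped", {
  expect_identical(shannon_entropy(numeric(5)), 0)
  expect_identical(shannon_entropy(c(1, 1)), 0)
  expect_equal(shannon_entropy(2), -4 * log(4))
  expect_equal(log_energy_entropy(c(1, 1, 1)), 0)
  expect_equal(log_energy_entropy(c(exp(1), exp(1))), 4)
  expect_true(is.finite(log_energy_entropy(c(0, 1, 2))))
  expect_true(is.finite(shannon_entropy(c(0, 1, 2))))
  # entropies are not scale-invariant
  set.seed(5)
  x <- rnorm(100)
  expect_false(isTRUE(all.equal(shannon_entropy(2 * x), shannon_entropy(x))))
  expect_false(isTRUE(all.equal(log_energy_entropy(2 * x),
                                log_energy_entropy(x))))
  # histogram estimator: bounded by log(n_bins), zero for a constant
  h <- shannon_entropy(x, method = "histogram", n_bins = 16)
  expect_gt(h, 0)
  expect_lt(h, log(16) + 1e-12)
  expect_identical(shannon_entropy(rep(1, 10), method = "histogram"), 0)
})

test_that("kurtosis and skewness match hand values, an independent oracle, and invariances", {
  expect_identical(sig_kurtosis(c(1, -1, 1, -1)), -2)
  expect_equal(sig_skewness(c(0, 0, 3)), 2 / 2^1.5)
  expect_identical(sig_skewness(c(-2, -1, 0, 1, 2)), 0)  # symmetric
  set.seed(6)
  z <- rnorm(1e5)
  expect_lt(abs(sig_kurtosis(z)), 0.1)
  expect_lt(abs(sig_skewness(z)), 0.05)
  # cross-check against e1071's population-moment (type 1) estimators
  for (i in 1:10) {
    x <- rexp(200) - rnorm(200)^2
    expect_equal(sig_kurtosis(x), e1071::kurtosis(x, type = 1))
    expect_equal(sig_skewness(x), e1071::skewness(x, type = 1))
  }
  # affine / scale invariance
  set.seed(7)
  y <- rgamma(100, 2)
  expect_equal(sig_kurtosis(3 * y + 5), sig_kurtosis(y))
  expect_equal(sig_skewness(4 * y), sig_skewness(y))
  expect_identical(as.numeric(sig_kurtosis(rep(1, 5))), 0)
  expect_identical(as.numeric(sig_skewness(rep(1, 5))), 0)
})

test_that("feature sets resolve to the documented combinations", {
  expect_identical(feature_set("hjorth"), c("activity", "mobility", "complexity"))
  expect_identical(feature_set("entropy"), c("shannon_entropy", "log_energy_entropy"))
  expect_length(feature_set("hjorth_entropy"), 5)
  expect_false("variance" %in% feature_set("all"))  # duplicate of activity
  expect_length(feature_set("all"), 7)
  expect_identical(feature_set(c("kurtosis", "skewness")),
                   c("kurtosis", "skewness"))
  expect_error(feature_set("fractal"), "unknown feature")
})

test_that("feature matrices have channel-major column order and right shape", {
  segs <- preprocess_cohort(small_cohort(), "AB", 5)  # 6 rec x 6 segments
  fm <- build_feature_matrix(segs, "hjorth_entropy")
  expect_identical(dim(fm$values), c(36L, 70L))
  expect_identical(colnames(fm$values)[1:6],
                   c("AF3_activity", "AF3_mobility", "AF3_complexity",
                     "AF3_shannon_entropy", "AF3_log_energy_entropy",
                     "F3_activity"))
  expect_true(all(is.finite(fm$values)))
  expect_length(fm$labels, 36)
  expect_length(fm$subject_ids, 36)
  # row count = sum over recordings of floor(T/S)
  expect_identical(nrow(fm$values),
                   length(small_cohort()) *
                     segmentation_plan(30 * 128, 5 * 128)$n_segments)

  # region subset halves the columns
  left <- build_feature_matrix(segs, "hjorth_entropy",
                               channels = region_map()$left_hemisphere)
  expect_identical(ncol(left$values), 35L)

  # base case: 1 segment x 1 channel x 1 feature equals the scalar
  one <- build_feature_matrix(segs[1], "activity", channels = "T7")
  expect_identical(dim(one$values), c(1L, 1L))
  expect_identical(unname(one$values[1, 1]),
                   hjorth_activity(segs[[1]]$data[match("T7", montage_channels()), ]))
})

test_that("degenerate segments are dropped and bad inputs rejected", {
  segs <- preprocess_cohort(small_cohort()[1], NULL, 5)
  segs[[2]]$data[] <- 7  # flat multichannel window
  expect_message(fm <- build_feature_matrix(segs, "hjorth"), "degenerate")
  expect_identical(nrow(fm$values), length(segs) - 1L)
  expect_error(build_feature_matrix(list(), "hjorth"), "empty")
  expect_error(build_feature_matrix(segs, "hjorth", channels = "CZ"),
               "unknown channel")
})
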