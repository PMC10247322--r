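# Shared fixtures, memoised so heavy cohorts are generated once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small effect cohort: 3+3 subjects, 30 s, default group contrast
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(3, 3, duration_s = 30, seed = 42)
  })
}

# exchangeable null: no group effect, no subject clustering
null_cohort <- function() {
  fixture("null_cohort", function() {
    generate_cohort(10, 10, duration_s = 60, seed = 11,
                    effect = null_effect(subject_sd = 0))
  })
}

# clustered cohort with a group effect, for the leakage diagnostic
clustered_cohort <- function() {
  fixture("clustered_cohort", function() {
    eff <- effect_spec(subject_sd = 0.6)
    generate_cohort(8, 8, duration_s = 60, seed = 23, effect = eff)
  })
}

# a feature matrix with the study's 5-s row counts but synthetic values,
# for protocol arithmetic that does not need real signals
fake_feature_matrix <- function(n_dep = 1140, n_con = 780, n_cols = 10,
                                seed = 5, informative = FALSE) {
  set.seed(seed)
  n <- n_dep + n_con
  labels <- c(rep("depressed", n_dep), rep("control", n_con))
  vals <- matrix(rnorm(n * n_cols), n, n_cols,
                 dimnames = list(NULL, paste0("ch_f", seq_len(n_cols))))
  if (informative) vals[labels == "depressed", 1] <- vals[labels == "depressed", 1] + 5
  structure(list(values = vals, labels = labels,
                 subject_ids = paste0("S", rep_len(1:32, n)),
                 channels = "ch", features = paste0("f", seq_len(n_cols))),
            class = "feature_matrix")
}

# row-subset a feature matrix (test-side twin of the package-internal helper)
fm_rows_for_test <- function(fm, idx) {
  structure(list(values = fm$values[idx, , drop = FALSE],
                 labels = fm$labels[idx], subject_ids = fm$subject_ids[idx],
                 channels = fm$channels, features = fm$features),
            class = "feature_matrix")
}

# 99% binomial band around 0.5 for an accuracy estimated on n rows
binomial_band_99 <- function(n) {
  half <- stats::qnorm(0.995) * sqrt(0.25 / n)
  c(0.5 - half, 0.5 + half)
}
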