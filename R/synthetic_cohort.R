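#' Group-contrast specification for the synthetic cohort generator
#'
#' Describes how the depressed group's signal differs from controls, plus the
#' nuisance structure shared by both groups. Band multipliers scale the RMS
#' amplitude of the named band-limited component in depressed subjects;
#' `asymmetry_delta` adds a fractional alpha-amplitude increase on
#' left-hemisphere channels of depressed subjects only; `subject_sd` is the
#' SD of per-subject log-normal amplitude multipliers (drawn once per
#' subject and band, so segments within a subject cluster); `noise_sd` is the
#' white measurement-noise SD in microvolts.
#'
#' An effect with all multipliers 1 and `asymmetry_delta = 0` is the null:
#' both groups then share the same signal distribution (see [null_effect()]).
#'
#' @param band_amplitude_multipliers Named numeric vector over
#'   `c("delta","theta","alpha","beta","gamma")`, all positive.
#' @param asymmetry_delta Fractional left-hemisphere alpha offset for the
#'   depressed group (0 = none).
#' @param subject_sd Between-subject log-amplitude SD (>= 0).
#' @param noise_sd White-noise SD, microvolts (> 0).
#' @param dc_offset_uv Constant offset added to every sample (hardware-style
#'   baseline, e.g. ~4200 uV on consumer headsets); default 0 (off).
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(band_amplitude_multipliers = c(delta = 1, theta = 1.15,
                                                       alpha = 1.4, beta = 1.25,
                                                       gamma = 1.1),
                        asymmetry_delta = 0.25,
                        subject_sd = 0.2,
                        noise_sd = 2,
                        dc_offset_uv = 0) {
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  m <- band_amplitude_multipliers
  if (is.null(names(m)) || !all(bands %in% names(m))) {
    stop("band_amplitude_multipliers must be named over: ",
         paste(bands, collapse = ", "), call. = FALSE)
  }
  m <- m[bands]
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("all band amplitude multipliers must be positive and finite",
         call. = FALSE)
  }
  if (subject_sd < 0) stop("subject_sd must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(band_amplitude_multipliers = m,
                 asymmetry_delta = asymmetry_delta,
                 subject_sd = subject_sd,
                 noise_sd = noise_sd,
                 dc_offset_uv = dc_offset_uv),
            class = "effect_spec")
}

#' The null effect: no group difference
#'
#' All band multipliers 1 and no asymmetry, so depressed and control signals
#' are drawn from the same distribution. `subject_sd` still defaults to the
#' generator's usual subject clustering; set it to 0 for a fully exchangeable
#' (segment-iid) null, e.g. for classifier calibration checks.
#'
#' @inheritParams effect_spec
#' @return An `"effect_spec"` with unit multipliers and zero asymmetry.
#' @export
null_effect <- function(subject_sd = 0.2, noise_sd = 2, dc_offset_uv = 0) {
  effect_spec(band_amplitude_multipliers = c(delta = 1, theta = 1, alpha = 1,
                                             beta = 1, gamma = 1),
              asymmetry_delta = 0, subject_sd = subject_sd,
              noise_sd = noise_sd, dc_offset_uv = dc_offset_uv)
}

# Base RMS amplitude (uV) of each band-limited component in an eyes-closed
# resting-state adult recording; alpha dominant, gamma weakest.
.base_band_rms <- c(delta = 20, theta = 10, alpha = 15, beta = 8, gamma = 4)
.pink_rms <- 10  # 1/f background RMS, uV

#' Draw a PHQ9 score for a group
#'
#' Depressed subjects score uniformly in the severe range 20--27; controls
#' uniformly in the no-depression range, 0 up to `control_max` (default 4).
#' Uses the current RNG stream.
#'
#' @param group `"depressed"` or `"control"`.
#' @param control_max Upper PHQ9 bound for controls (default 4).
#' @return Integer score.
#' @export
assign_phq9 <- function(group, control_max = 4) {
  group <- match.arg(group, c("depressed", "control"))
  if (group == "depressed") sample(20:27, 1L) else sample(0:control_max, 1L)
}

# Components are scaled by their *expected* (theoretical) RMS, not the
# realisation's sample SD: normalising each recording by its own sample SD
# would pin total component power per recording and so anti-correlate the
# band power of windows within a recording, biasing null cross-validation
# below chance.

# 1/f (pink) noise, unit expected RMS, via spectral shaping of white noise.
pink_noise <- function(n) {
  x <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k)        # symmetric frequency index, keeps conjugacy
  sc <- ifelse(f == 0, 0, 1 / sqrt(f))
  y <- Re(stats::fft(x * sc, inverse = TRUE)) / n
  y / sqrt(mean(sc^2))       # theoretical SD of the shaped process
}

.gain_cache <- new.env(parent = emptyenv())

# RMS gain of the zero-phase band filter on unit white noise, from the
# energy of its overall impulse response (cached per band x rate).
band_filter_gain <- function(flt, fs_hz) {
  key <- sprintf("%g_%g_%g_%d", flt$low_hz, flt$high_hz, fs_hz, flt$order)
  if (!is.null(.gain_cache[[key]])) return(.gain_cache[[key]])
  imp <- c(1, numeric(as.integer(16 * fs_hz) - 1L))
  h <- signal::filtfilt(signal::as.Arma(flt$filt), imp)
  g <- sqrt(sum(h^2))
  .gain_cache[[key]] <- g
  g
}

# Band-limited noise with unit expected RMS: white noise through the band's
# Butterworth filter (order 4, zero phase), scaled by the filter gain.
bandlimited_noise <- function(n, low_hz, high_hz, fs_hz) {
  flt <- design_filter(list(name = "gen", low_hz = low_hz, high_hz = high_hz),
                       fs_hz = fs_hz, order = 4L)
  y <- signal::filtfilt(signal::as.Arma(flt$filt), stats::rnorm(n))
  y / band_filter_gain(flt, fs_hz)
}

#' Simulate a two-group multichannel EEG cohort
#'
#' Each channel is a sum of five band-limited oscillatory components
#' (band-filtered white noise, not sinusoids), a 1/f pink-noise background,
#' and white measurement noise. Depressed subjects' band amplitudes are
#' scaled by the effect's multipliers; their left-hemisphere alpha is further
#' raised by `asymmetry_delta`. Per-subject log-normal amplitude multipliers
#' (one draw per subject and band) make segments within a subject more alike
#' than segments across subjects. Metadata (PHQ9, sex, age) follow the study
#' marginals: depressed PHQ9 20--27 and ~74% female, controls PHQ9 0--4,
#' ages 18--25; metadata carry no signal effect.
#'
#' @param n_depressed,n_control Subject counts (non-negative, not both 0).
#' @param duration_s Recording duration in seconds (default 300).
#' @param fs_hz Sampling rate in Hz (default 128).
#' @param effect An [effect_spec()]; defaults to the standard group contrast.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param control_phq9_max Upper PHQ9 bound for controls (default 4).
#' @return A list of `"eeg_recording"` objects (class `"eeg_cohort"`), each
#'   with `meta` (subject_id, group, phq9_score, sex, age_years), `fs_hz`,
#'   `channel_names`, `duration_s` and a channels x samples `signal` matrix
#'   in microvolts.
#' @examples
#' coh <- generate_cohort(2, 2, duration_s = 10, seed = 1)
#' dim(coh[[1]]$signal)  # 14 x 1280
#' @export
generate_cohort <- function(n_depressed, n_control,
                            duration_s = 300, fs_hz = 128,
                            effect = effect_spec(), seed = 1L,
                            control_phq9_max = 4L) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive", call. = FALSE)
  if (n_depressed < 0 || n_control < 0) stop("counts must be >= 0", call. = FALSE)
  if (n_depressed + n_control == 0) {
    stop("cohort must contain at least one subject", call. = FALSE)
  }
  stopifnot(inherits(effect, "effect_spec"))

  n_samp <- round(fs_hz * duration_s)
  chans <- montage_channels()
  left <- region_map()$left_hemisphere
  bands <- names(.base_band_rms)
  edges <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                beta = c(12, 30), gamma = c(30, 64))

  groups <- c(rep("depressed", n_depressed), rep("control", n_control))
  set.seed(as.integer(seed))
  cohort <- vector("list", length(groups))

  for (s in seq_along(groups)) {
    grp <- groups[s]
    meta <- list(
      subject_id = sprintf("S%03d", s),
      group = grp,
      phq9_score = assign_phq9(grp, control_max = control_phq9_max),
      sex = if (grp == "depressed") {
        sample(c("F", "M"), 1L, prob = c(0.74, 0.26))
      } else {
        sample(c("F", "M"), 1L, prob = c(0.15, 0.85))
      },
      age_years = sample(18:25, 1L)
    )
    # one multiplier per band per subject: the subject random effect
    subj_mult <- exp(stats::rnorm(length(bands), 0, effect$subject_sd))
    names(subj_mult) <- bands

    sig <- matrix(0, nrow = length(chans), ncol = n_samp,
                  dimnames = list(chans, NULL))
    for (ci in seq_along(chans)) {
      x <- numeric(n_samp)
      for (b in bands) {
        amp <- .base_band_rms[[b]] * subj_mult[[b]]
        if (grp == "depressed") {
          amp <- amp * effect$band_amplitude_multipliers[[b]]
          if (b == "alpha" && chans[ci] %in% left) {
            amp <- amp * (1 + effect$asymmetry_delta)
          }
        }
        x <- x + amp * bandlimited_noise(n_samp, edges[[b]][1], edges[[b]][2],
                                         fs_hz)
      }
      x <- x + .pink_rms * pink_noise(n_samp)
      x <- x + stats::rnorm(n_samp, 0, effect$noise_sd)
      sig[ci, ] <- x + effect$dc_offset_uv
    }
    cohort[[s]] <- structure(
      list(meta = meta, fs_hz = fs_hz, channel_names = chans,
           duration_s = duration_s, signal = sig),
      class = "eeg_recording")
  }
  structure(cohort, class = c("eeg_cohort", "list"))
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s, PHQ9 %d): %d ch x %d samples @ %g Hz\n",
              x$meta$subject_id, x$meta$group, x$meta$phq9_score,
              nrow(x$signal), ncol(x$signal), x$fs_hz))
  invisible(x)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  grp <- vapply(x, function(r) r$meta$group, "")
  cat(sprintf("<eeg_cohort> %d recordings (%d depressed, %d control)\n",
              length(x), sum(grp == "depressed"), sum(grp == "control")))
  invisible(x)
}
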