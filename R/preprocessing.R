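#' Design a band-pass Butterworth filter for one catalogue band
#'
#' IIR Butterworth band-pass design at the recording's sampling rate. A band
#' upper edge at or above the Nyquist frequency is capped at
#' `0.99 * fs_hz / 2` (a digital band-pass edge exactly at Nyquist is
#' undefined); a band lying entirely at or above Nyquist is an error.
#' Stability is verified at design time: all poles strictly inside the unit
#' circle.
#'
#' @param band A [band_spec()], a band name, or any list with `low_hz` and
#'   `high_hz`.
#' @param fs_hz Sampling rate, Hz.
#' @param order Butterworth prototype order (default 4).
#' @return A list of class `"band_filter"` with the `signal::butter` design
#'   (`filt`), the resolved edges, `fs_hz` and `order`.
#' @examples
#' design_filter("AB", fs_hz = 128)
#' @export
design_filter <- function(band, fs_hz, order = 4L) {
  if (is.character(band)) band <- band_spec(band)
  stopifnot(order >= 1, fs_hz > 0)
  nyq <- fs_hz / 2
  lo <- band$low_hz
  hi <- min(band$high_hz, 0.99 * nyq)
  if (lo >= nyq || lo >= hi) {
    stop("band ", band$name %||% "", " [", band$low_hz, ", ", band$high_hz,
         "] Hz is empty below the Nyquist frequency ", nyq, " Hz",
         call. = FALSE)
  }
  flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  poles <- polyroot(rev(flt$a))
  if (max(Mod(poles)) >= 1) {
    stop("unstable filter design for band [", lo, ", ", hi, "] Hz at order ",
         order, call. = FALSE)
  }
  structure(list(filt = flt, name = band$name %||% "custom",
                 low_hz = lo, high_hz = hi, fs_hz = fs_hz, order = order),
            class = "band_filter")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Band-filter every channel of a recording
#'
#' Applies the band's Butterworth filter to each channel. Zero-phase mode
#' (the default) runs the filter forward and backward so amplitude features
#' are not skewed by phase distortion; causal mode is a single forward pass.
#' The output recording has identical shape and metadata.
#'
#' @param rec An `"eeg_recording"`.
#' @param band Band name or [band_spec()].
#' @param order Butterworth order (default 4).
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @return The filtered `"eeg_recording"`.
#' @export
apply_filter <- function(rec, band, order = 4L, zero_phase = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad <- which(!is.finite(rec$signal), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite sample in channel ", rec$channel_names[bad[1, 1]],
         " at index ", bad[1, 2], call. = FALSE)
  }
  des <- design_filter(band, rec$fs_hz, order)
  arma <- signal::as.Arma(des$filt)
  out <- rec
  for (i in seq_len(nrow(rec$signal))) {
    out$signal[i, ] <- if (zero_phase) {
      zero_phase_filter(arma, rec$signal[i, ], rec$fs_hz)
    } else {
      as.numeric(signal::filter(arma, rec$signal[i, ]))
    }
  }
  out$band <- des$name
  out
}

# Forward-backward filtering with odd-reflection end padding (up to 3 s),
# so start-up transients decay inside the padding and are trimmed off.
zero_phase_filter <- function(arma, x, fs_hz) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(3 * fs_hz)))
  if (pad < 1L) return(signal::filtfilt(arma, x))
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(arma, c(front, x, back))
  y[(pad + 1L):(pad + n)]
}

#' Segment-count bookkeeping for one recording
#'
#' For a recording of `n_total` samples per channel cut into windows of
#' `seg_len` samples, the number of full windows is `floor(n_total /
#' seg_len)`; the trailing partial window is discarded. `samples_per_subject`
#' is the total sample count across channels (`n_total * n_channels`).
#'
#' @param n_total Samples per channel.
#' @param seg_len Segment length, samples.
#' @param n_channels Channel count (default 14).
#' @return List with `n_total`, `seg_len`, `n_channels`, `n_segments`,
#'   `samples_per_subject`.
#' @examples
#' segmentation_plan(38400, 640)$n_segments  # 60 five-second windows
#' @export
segmentation_plan <- function(n_total, seg_len, n_channels = 14L) {
  stopifnot(n_total > 0, seg_len > 0, n_channels > 0)
  list(n_total = n_total, seg_len = seg_len, n_channels = n_channels,
       n_segments = as.integer(floor(n_total / seg_len)),
       samples_per_subject = n_total * n_channels)
}

#' Cut a recording into non-overlapping multichannel segments
#'
#' Window `k` (0-based) covers samples `[k*S, (k+1)*S)` of every channel;
#' windows are contiguous and non-overlapping, and the trailing partial
#' window is dropped. Each segment keeps the subject id, group label and
#' window index so feature rows remain traceable.
#'
#' @param rec An `"eeg_recording"`.
#' @param seg_len_s Segment length in seconds; `seg_len_s * fs_hz` must be a
#'   positive integer.
#' @return List of `"eeg_segment"` objects, length `floor(T / S)`.
#' @examples
#' rec <- generate_cohort(1, 0, duration_s = 10, seed = 1)[[1]]
#' length(segment_recording(rec, 2))  # 5
#' @export
segment_recording <- function(rec, seg_len_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  s_len <- seg_len_s * rec$fs_hz
  if (s_len <= 0 || abs(s_len - round(s_len)) > 1e-9) {
    stop("seg_len_s * fs_hz must be a positive integer, got ", s_len,
         call. = FALSE)
  }
  s_len <- as.integer(round(s_len))
  n_total <- ncol(rec$signal)
  n_seg <- floor(n_total / s_len)
  if (n_seg == 0) {
    stop("no full window fits: segment length ", s_len,
         " samples exceeds recording length ", n_total, call. = FALSE)
  }
  lapply(seq_len(n_seg) - 1L, function(k) {
    structure(list(subject_id = rec$meta$subject_id,
                   label = rec$meta$group,
                   window_index = k,
                   data = rec$signal[, (k * s_len + 1):((k + 1) * s_len),
                                     drop = FALSE],
                   fs_hz = rec$fs_hz,
                   channel_names = rec$channel_names),
              class = "eeg_segment")
  })
}

#' Filter and segment a whole cohort
#'
#' Convenience wrapper fixing the pipeline order as filter-then-segment:
#' each recording is band-filtered in full (so window edges see no extra
#' filter transients beyond the recording ends) and then windowed.
#'
#' @param cohort An `"eeg_cohort"` (list of recordings).
#' @param band Band name or spec; `NULL` skips filtering.
#' @param seg_len_s Segment length, seconds.
#' @param order,zero_phase Passed to [apply_filter()].
#' @return Flat list of `"eeg_segment"` objects across all recordings.
#' @export
preprocess_cohort <- function(cohort, band, seg_len_s, order = 4L,
                              zero_phase = TRUE) {
  segs <- lapply(cohort, function(rec) {
    if (!is.null(band)) rec <- apply_filter(rec, band, order, zero_phase)
    segment_recording(rec, seg_len_s)
  })
  unlist(segs, recursive = FALSE)
}
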