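#' Canonical EEG frequency bands and their combinations
#'
#' The filter-bank catalogue: the five canonical sub-bands (delta, theta,
#' alpha, beta, gamma), the full band, and the five adjacent-band
#' combinations used in the band-combination sweep. `AB`, for example, spans
#' alpha through beta (8--30 Hz); `ABTG` spans theta through gamma
#' (4--64 Hz). Upper edges at the Nyquist frequency are capped at design
#' time, not here (see [design_filter()]).
#'
#' @format A data frame with columns `name`, `low_hz`, `high_hz`.
#' @seealso [band_spec()], [design_filter()]
#' @export
band_catalogue <- function() {
  data.frame(
    name    = c("FULL", "DELTA", "THETA", "ALPHA", "BETA", "GAMMA",
                "ABDT", "ABT", "AB", "ABTG", "ABG"),
    low_hz  = c(0.5, 0.5, 4, 8, 12, 30, 0.5, 4, 8, 4, 8),
    high_hz = c(64, 4, 8, 12, 30, 64, 30, 30, 30, 64, 64),
    stringsAsFactors = FALSE
  )
}

#' Look up one band of the filter-bank catalogue
#'
#' @param name Band name (case-insensitive), one of
#'   `FULL, DELTA, THETA, ALPHA, BETA, GAMMA, ABDT, ABT, AB, ABTG, ABG`.
#' @return A list with `name`, `low_hz`, `high_hz` of class `"band_spec"`.
#' @examples
#' band_spec("AB")  # 8-30 Hz, alpha through beta
#' @export
band_spec <- function(name) {
  cat_ <- band_catalogue()
  i <- match(toupper(name), cat_$name)
  if (is.na(i)) {
    stop("unknown band '", name, "'; known bands: ",
         paste(cat_$name, collapse = ", "), call. = FALSE)
  }
  structure(list(name = cat_$name[i], low_hz = cat_$low_hz[i],
                 high_hz = cat_$high_hz[i]),
            class = "band_spec")
}

#' The 14-channel wireless headset montage
#'
#' Channel names, in acquisition order, of the 14-channel consumer EEG
#' headset montage (10--20 positions) the pipeline assumes.
#'
#' @return Character vector of 14 channel names.
#' @export
montage_channels <- function() {
  c("AF3", "F3", "F7", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F8", "F4", "AF4")
}

#' Scalp-region channel subsets
#'
#' Region catalogue used by the region sweep: whole brain, the two
#' hemispheres (which partition the montage), and the four lobes (frontal,
#' temporal, parietal, occipital, which also partition it).
#'
#' @return Named list of character vectors of channel names.
#' @export
region_map <- function() {
  list(
    whole_brain      = montage_channels(),
    left_hemisphere  = c("AF3", "F3", "F7", "FC5", "T7", "P7", "O1"),
    right_hemisphere = c("AF4", "F4", "F8", "FC6", "T8", "P8", "O2"),
    frontal          = c("AF3", "F3", "F7", "FC5", "AF4", "F4", "F8", "FC6"),
    temporal         = c("T7", "T8"),
    parietal         = c("P7", "P8"),
    occipital        = c("O1", "O2")
  )
}
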