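#' @name signal_io
#' @title Reading and writing recordings, manifests and feature matrices
#'
#' @description
#' On-disk formats are plain text and byte-deterministic: comma-separated,
#' `.` decimal, LF line endings, mandatory header, numeric cells in fixed
#' decimal notation with 9 decimal places (round-trips exact to 1e-9). A recording CSV has a leading `sample` index
#' column then one column per montage channel; a cohort is a directory of
#' recording CSVs plus a JSON manifest holding the per-subject metadata; a
#' feature-matrix CSV has `subject_id`, `label`, then one
#' `<channel>_<feature>` column per cell.
NULL

fmt_num <- function(x) sprintf("%.9f", x)

write_csv_text <- function(header, body_lines, path) {
  con <- file(path, open = "wb")  # binary: LF on every platform
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), body_lines), con, sep = "\n")
}

#' Write one recording as CSV
#'
#' @param rec An `"eeg_recording"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  cols <- apply(rec$signal, 1, fmt_num)      # samples x channels
  body <- paste(seq_len(ncol(rec$signal)) - 1L,
                apply(cols, 1, paste, collapse = ","), sep = ",")
  write_csv_text(c("sample", rec$channel_names), body, path)
  invisible(path)
}

#' Read one recording from CSV
#'
#' The header must name the `sample` column and exactly the 14 montage
#' channels (any order; channels are kept in header order). Metadata not
#' stored in the CSV (subject, group, sampling rate) comes from the
#' arguments, normally filled in by [read_cohort()] from the manifest.
#'
#' @param path CSV file path.
#' @param fs_hz Sampling rate (default 128).
#' @param meta Optional list with `subject_id`, `group`, `phq9_score`,
#'   `sex`, `age_years`.
#' @return An `"eeg_recording"`.
#' @export
read_recording_csv <- function(path, fs_hz = 128, meta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  chan_cols <- setdiff(names(df), "sample")
  if (anyDuplicated(chan_cols)) {
    stop("duplicate channel column(s): ",
         paste(unique(chan_cols[duplicated(chan_cols)]), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(chan_cols, montage_channels())) {
    stop("header must name the 14 montage channels; got ",
         length(chan_cols), " channel column(s)", call. = FALSE)
  }
  sig <- matrix(NA_real_, nrow = length(chan_cols), ncol = nrow(df),
                dimnames = list(chan_cols, NULL))
  for (ch in chan_cols) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    if (anyNA(v)) {
      stop("non-numeric cell in channel ", ch, " at row ",
           which(is.na(v))[1], call. = FALSE)
    }
    sig[ch, ] <- v
  }
  meta <- utils::modifyList(
    list(subject_id = sub("\\.csv$", "", basename(path)), group = "control",
         phq9_score = NA_integer_, sex = NA_character_,
         age_years = NA_integer_),
    meta %||% list())
  structure(list(meta = meta, fs_hz = fs_hz, channel_names = chan_cols,
                 duration_s = ncol(sig) / fs_hz, signal = sig),
            class = "eeg_recording")
}

#' Write a cohort as per-recording CSVs plus a JSON manifest
#'
#' @param cohort An `"eeg_cohort"`.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort, function(rec) {
    fname <- paste0(rec$meta$subject_id, ".csv")
    write_recording_csv(rec, file.path(dir, fname))
    c(rec$meta[c("subject_id", "group", "phq9_score", "sex", "age_years")],
      list(fs_hz = rec$fs_hz, file = fname))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(channel_names = cohort[[1]]$channel_names,
                            entries = entries),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort back from its manifest
#'
#' @param manifest_path Path to `manifest.json` written by [write_cohort()].
#' @return An `"eeg_cohort"`.
#' @export
read_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  recs <- lapply(man$entries, function(e) {
    p <- file.path(dir, e$file)
    if (!file.exists(p)) stop("manifest references missing file: ", p,
                              call. = FALSE)
    rec <- read_recording_csv(p, fs_hz = e$fs_hz,
                              meta = e[c("subject_id", "group", "phq9_score",
                                         "sex", "age_years")])
    # restore canonical channel order from the manifest
    ord <- match(unlist(man$channel_names), rec$channel_names)
    rec$signal <- rec$signal[ord, , drop = FALSE]
    rec$channel_names <- rec$channel_names[ord]
    rec
  })
  structure(recs, class = c("eeg_cohort", "list"))
}

#' Write a feature matrix as CSV
#'
#' Header: `subject_id`, `label`, then the `<channel>_<feature>` columns in
#' matrix order; one row per segment.
#'
#' @param fm A non-empty `"feature_matrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) == 0) stop("empty feature matrix", call. = FALSE)
  body <- vapply(seq_len(nrow(fm$values)), function(i) {
    paste(c(fm$subject_ids[i], fm$labels[i], fmt_num(fm$values[i, ])),
          collapse = ",")
  }, "")
  write_csv_text(c("subject_id", "label", colnames(fm$values)), body, path)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by [write_feature_matrix_csv()].
#' @return A `"feature_matrix"`.
#' @export
read_feature_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  cols <- colnames(vals)
  feats <- unique(sub("^[^_]+_", "", cols))
  chans <- unique(sub("_.*$", "", cols))
  structure(list(values = vals, labels = df$label,
                 subject_ids = df$subject_id, channels = chans,
                 features = feats),
            class = "feature_matrix")
}

#' Write a result table as CSV
#'
#' Numeric cells in fixed 9-decimal notation, byte-deterministic.
#'
#' @param tab A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table_csv <- function(tab, path) {
  stopifnot(is.data.frame(tab), nrow(tab) > 0)
  cells <- vapply(seq_len(nrow(tab)), function(i) {
    paste(vapply(seq_along(tab), function(j) {
      v <- tab[i, j]
      if (is.numeric(v)) fmt_num(v) else as.character(v)
    }, ""), collapse = ",")
  }, "")
  write_csv_text(names(tab), cells, path)
  invisible(path)
}
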