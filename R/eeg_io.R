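# Recording container, montage, and file formats (wide CSV + sidecar
# metadata, minimal EDF, TSV annotations).

#' Standard 12-channel workload montage
#'
#' The channel set used throughout the package: twelve 10-20 system
#' positions, with FPz serving as the blink-reference channel (excluded from
#' spectral features), five frontal channels carrying the theta workload
#' signature and six parietal channels carrying the alpha signature.
#'
#' @return A list with elements `channels` (all 12 labels), `reference`
#'   (`"FPz"`), `frontal`, `parietal`, and `analysis` (all channels except
#'   the reference).
#' @export
#' @examples
#' wl_montage()$frontal
wl_montage <- function() {
  channels <- c("FPz", "AF3", "AF4", "F3", "Fz", "F4",
                "P3", "P7", "Pz", "P4", "P8", "POz")
  list(
    channels  = channels,
    reference = "FPz",
    frontal   = c("AF3", "AF4", "F3", "Fz", "F4"),
    parietal  = c("P3", "P7", "Pz", "P4", "P8", "POz"),
    analysis  = setdiff(channels, "FPz")
  )
}

#' Construct a raw multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_labels Character vector of unique 10-20 labels, one per row
#'   of `data`.
#' @param sampling_rate Sampling frequency in Hz.
#' @param annotations Optional data frame with columns `onset_s`,
#'   `duration_s`, `label` (see [read_annotations()]); validated against the
#'   recording span and returned sorted by onset.
#' @param subject_id Subject identifier string.
#' @return An object of class `wl_recording`.
#' @export
raw_recording <- function(data, channel_labels, sampling_rate,
                          annotations = NULL, subject_id = "unknown") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) != length(channel_labels)) {
    stop("`data` must have one row per channel label (", nrow(data),
         " rows vs ", length(channel_labels), " labels)", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number", call. = FALSE)
  }
  rec <- structure(
    list(data = data,
         channel_labels = as.character(channel_labels),
         sampling_rate = sampling_rate,
         annotations = NULL,
         subject_id = subject_id),
    class = "wl_recording"
  )
  if (!is.null(annotations)) {
    rec$annotations <- validate_annotations(annotations,
                                            span = recording_duration(rec))
  }
  rec
}

#' Duration of a recording in seconds
#' @param rec A `wl_recording`.
#' @return Length of the recording in seconds.
#' @export
recording_duration <- function(rec) {
  ncol(rec$data) / rec$sampling_rate
}

#' @export
print.wl_recording <- function(x, ...) {
  cat("<wl_recording> subject:", x$subject_id, "\n")
  cat(sprintf("  %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              recording_duration(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$annotations)) {
    cat("  annotations:", nrow(x$annotations), "\n")
  }
  invisible(x)
}

#' Validate a recording against montage and filter requirements
#'
#' Checks the `wl_recording` invariants: unique labels, presence of required
#' channels (named explicitly in the error if absent), and that the sampling
#' rate exceeds twice the configured low-pass cutoff.
#'
#' @param rec A `wl_recording`.
#' @param required_channels Channel labels that must be present.
#' @param lowpass_cutoff Optional low-pass cutoff in Hz the recording must
#'   support (`sampling_rate > 2 * lowpass_cutoff`).
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec, required_channels = NULL,
                               lowpass_cutoff = NULL) {
  stopifnot(inherits(rec, "wl_recording"))
  if (!is.null(required_channels)) {
    missing <- setdiff(required_channels, rec$channel_labels)
    if (length(missing)) {
      stop("recording is missing required channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(lowpass_cutoff) && rec$sampling_rate <= 2 * lowpass_cutoff) {
    stop("sampling rate (", rec$sampling_rate,
         " Hz) must exceed twice the low-pass cutoff (", lowpass_cutoff,
         " Hz)", call. = FALSE)
  }
  invisible(rec)
}

# Annotation grammar ------------------------------------------------------

.hours  <- c("Normal", "Rush")
.roads  <- c("Easy", "Hard")
.laps   <- 1:3
.events <- c("Pedestrian", "Car")

parse_annotation_label <- function(label) {
  if (identical(label, "eyes_closed")) {
    return(list(type = "baseline", hour = NA_character_, road = NA_character_,
                lap = NA_integer_, event = NA_character_,
                position = NA_character_))
  }
  parts <- strsplit(label, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop("malformed annotation label: '", label, "'", call. = FALSE)
  }
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  if (anyDuplicated(keys)) {
    stop("duplicate keys in annotation label: '", label, "'", call. = FALSE)
  }
  names(vals) <- keys
  if ("event" %in% keys) {
    bad <- setdiff(keys, c("event", "position"))
    if (length(bad)) {
      stop("unknown key(s) ", paste(bad, collapse = ", "),
           " in event label: '", label, "'", call. = FALSE)
    }
    if (!vals[["event"]] %in% .events) {
      stop("unknown event type '", vals[["event"]], "' (expected ",
           paste(.events, collapse = " or "), ")", call. = FALSE)
    }
    return(list(type = "event", hour = NA_character_, road = NA_character_,
                lap = NA_integer_, event = vals[["event"]],
                position = if ("position" %in% keys) vals[["position"]]
                           else NA_character_))
  }
  need <- c("hour", "road", "lap")
  if (!setequal(intersect(keys, need), need) ||
      length(setdiff(keys, need))) {
    stop("condition label must carry exactly hour, road and lap: '",
         label, "'", call. = FALSE)
  }
  if (!vals[["hour"]] %in% .hours) {
    stop("unknown hour '", vals[["hour"]], "' in '", label, "'",
         call. = FALSE)
  }
  if (!vals[["road"]] %in% .roads) {
    stop("unknown road '", vals[["road"]], "' in '", label, "'",
         call. = FALSE)
  }
  lap <- suppressWarnings(as.integer(vals[["lap"]]))
  if (is.na(lap) || !lap %in% .laps) {
    stop("lap must be one of ", paste(.laps, collapse = ", "), " in '",
         label, "'", call. = FALSE)
  }
  list(type = "condition", hour = vals[["hour"]], road = vals[["road"]],
       lap = lap, event = NA_character_, position = NA_character_)
}

validate_annotations <- function(ann, span = NULL) {
  ann <- as.data.frame(ann)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(ann))) {
    stop("annotations need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ann$onset_s <- as.numeric(ann$onset_s)
  ann$duration_s <- as.numeric(ann$duration_s)
  if (anyNA(ann$onset_s) || anyNA(ann$duration_s)) {
    stop("non-numeric onset or duration in annotations", call. = FALSE)
  }
  if (any(ann$onset_s < 0) || any(ann$duration_s < 0)) {
    stop("annotation onsets and durations must be non-negative",
         call. = FALSE)
  }
  for (lab in ann$label) parse_annotation_label(lab)
  if (!is.null(span) &&
      any(ann$onset_s + ann$duration_s > span + 1e-9)) {
    stop("annotation extends beyond the recording span (", span, " s)",
         call. = FALSE)
  }
  ann <- ann[order(ann$onset_s), c("onset_s", "duration_s", "label")]
  rownames(ann) <- NULL
  ann
}

#' Parse annotation labels into typed attributes
#'
#' Expands the label grammar into columns: `type` (baseline / condition /
#' event), `hour`, `road`, `lap`, `event`, `position`.
#'
#' @param ann Annotation data frame with columns `onset_s`, `duration_s`,
#'   `label`.
#' @return The annotation data frame with attribute columns appended.
#' @export
parse_annotations <- function(ann) {
  ann <- validate_annotations(ann)
  parsed <- lapply(ann$label, parse_annotation_label)
  ann$type     <- vapply(parsed, `[[`, "", "type")
  ann$hour     <- vapply(parsed, `[[`, "", "hour")
  ann$road     <- vapply(parsed, `[[`, "", "road")
  ann$lap      <- vapply(parsed, function(p) as.integer(p$lap), 1L)
  ann$event    <- vapply(parsed, `[[`, "", "event")
  ann$position <- vapply(parsed, `[[`, "", "position")
  ann
}

#' Read a TSV annotation track
#'
#' @param path Path to a tab-separated file with header
#'   `onset_s  duration_s  label`.
#' @return Annotations sorted by onset, validated against the label grammar.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty annotation file: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("onset_s", "duration_s", "label"))) {
    stop("annotation header must be 'onset_s\\tduration_s\\tlabel'",
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != 3) {
      stop("malformed annotation row at line ", i + 1L, call. = FALSE)
    }
    on <- suppressWarnings(as.numeric(rows[[i]][1]))
    du <- suppressWarnings(as.numeric(rows[[i]][2]))
    if (is.na(on) || is.na(du)) {
      stop("non-numeric onset/duration at line ", i + 1L, call. = FALSE)
    }
  }
  ann <- data.frame(
    onset_s    = vapply(rows, function(r) as.numeric(r[1]), 0),
    duration_s = vapply(rows, function(r) as.numeric(r[2]), 0),
    label      = vapply(rows, `[[`, "", 3L)
  )
  validate_annotations(ann)
}

#' Write a TSV annotation track
#' @param ann Annotation data frame (columns `onset_s`, `duration_s`,
#'   `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  utils::write.table(ann[, c("onset_s", "duration_s", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Wide CSV + sidecar metadata ---------------------------------------------

csv_sidecar_path <- function(path) sub("\\.csv$", ".meta.json", path)

read_recording_csv <- function(path) {
  meta_path <- csv_sidecar_path(path)
  if (!file.exists(meta_path)) {
    stop("missing sidecar metadata file: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) {
    stop("sidecar metadata must declare 'sampling_rate'", call. = FALSE)
  }
  dt <- data.table::fread(path, header = TRUE)
  data <- t(as.matrix(dt))
  units <- if (is.null(meta$units)) "uV" else meta$units
  scale <- switch(units, uV = 1, mV = 1000, V = 1e6,
                  stop("unknown units '", units, "' in sidecar metadata",
                       call. = FALSE))
  raw_recording(data * scale, rownames(data), meta$sampling_rate,
                subject_id = if (is.null(meta$subject_id)) "unknown"
                             else meta$subject_id)
}

write_recording_csv <- function(rec, path) {
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$channel_labels)
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate, subject_id = rec$subject_id,
         units = "uV"),
    csv_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimal EDF reader/writer -----------------------------------------------
# European Data Format: 256-byte fixed header, 256 bytes per signal of
# field-major signal headers, then 16-bit little-endian samples grouped in
# 1-second data records. Physical units honored: mV and V sources are
# rescaled to uV on read.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

write_recording_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  if (n %% fs != 0) {
    stop("EDF writer requires a whole number of seconds (",
         n / fs, " s given)", call. = FALSE)
  }
  n_rec <- n %/% fs
  ns <- nrow(rec$data)
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("eegworkload", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (ch in rec$channel_labels) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(signif(pmin_[i], 7), 8)
  for (i in seq_len(ns)) wr(signif(pmax_[i], 7), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  # re-read the written physical limits so the stored scaling is exact
  pmin_w <- as.numeric(edf_pad(signif(pmin_, 7), 8))
  pmax_w <- as.numeric(edf_pad(signif(pmax_, 7), 8))
  scale <- (pmax_w - pmin_w) / (dmax - dmin)
  dig <- matrix(0L, ns, n)
  for (i in seq_len(ns)) {
    d <- round((rec$data[i, ] - pmin_w[i]) / scale[i]) + dmin
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      writeBin(dig[i, idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin  <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax  <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 1L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr / rec_dur)) != 1) {
    stop("EDF signals have inconsistent sampling rates", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      data[i, idx] <- (d - dmin[i]) * scale[i] + pmin_[i]
    }
  }
  unit_scale <- vapply(units, function(u) {
    switch(tolower(u), uv = 1, mv = 1000, v = 1e6, 1)
  }, 0)
  data <- data * unit_scale
  raw_recording(data, labels, fs, subject_id = subject_id)
}

#' Read an EEG recording
#'
#' Supports EDF (16-bit European Data Format; physical dimension honored,
#' mV/V sources rescaled to microvolts) and wide CSV (header = channel
#' labels, one row per sample) with a `.meta.json` sidecar declaring
#' `sampling_rate`, `subject_id` and `units`.
#'
#' @param path Path to a `.edf` or `.csv` file.
#' @param format `"auto"` (by extension), `"edf"`, or `"csv"`.
#' @param required_channels Optional channel labels that must be present;
#'   absent labels are named in the error.
#' @param annotations Optional path to a TSV annotation track attached to
#'   the returned recording.
#' @return A `wl_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           required_channels = NULL, annotations = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv",
                     stop("unknown recording format '.", ext,
                          "' (expected .edf or .csv)", call. = FALSE))
  }
  rec <- switch(format,
                edf = read_recording_edf(path),
                csv = read_recording_csv(path))
  validate_recording(rec, required_channels = required_channels)
  if (!is.null(annotations)) {
    rec$annotations <- validate_annotations(read_annotations(annotations),
                                            span = recording_duration(rec))
  }
  rec
}

#' Write an EEG recording
#'
#' @param rec A `wl_recording`.
#' @param path Output path (`.edf` or `.csv`; CSV gains a `.meta.json`
#'   sidecar).
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv",
                     stop("unknown recording format '.", ext, "'",
                          call. = FALSE))
  }
  switch(format,
         edf = write_recording_edf(rec, path),
         csv = write_recording_csv(rec, path))
  invisible(path)
}
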