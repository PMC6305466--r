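# Filtering, blink removal, sliding-epoch segmentation and artifact
# rejection.

#' Preprocessing configuration
#'
#' Defaults follow the standard workload pipeline: 1-30 Hz fourth-order
#' Butterworth band-pass, 2-s epochs shifted by 0.125 s, and the three
#' artifact criteria (amplitude above 100 uV, least-squares trend slope
#' above 10 uV/s, sample-to-sample step above 25 uV).
#'
#' @param highpass_cutoff High-pass cutoff, Hz.
#' @param lowpass_cutoff Low-pass cutoff, Hz.
#' @param filter_order Butterworth order of each (high-pass and low-pass)
#'   section.
#' @param epoch_length Epoch length, s.
#' @param epoch_shift Shift between successive epoch starts, s.
#' @param amplitude_threshold Absolute amplitude rejection threshold, uV.
#' @param trend_slope_threshold Least-squares slope rejection threshold,
#'   uV/s.
#' @param step_threshold Sample-to-sample difference rejection threshold,
#'   uV.
#' @return A validated `wl_preprocess_config` list.
#' @export
preprocess_config <- function(highpass_cutoff = 1, lowpass_cutoff = 30,
                              filter_order = 4, epoch_length = 2,
                              epoch_shift = 0.125,
                              amplitude_threshold = 100,
                              trend_slope_threshold = 10,
                              step_threshold = 25) {
  cfg <- list(highpass_cutoff = highpass_cutoff,
              lowpass_cutoff = lowpass_cutoff,
              filter_order = as.integer(filter_order),
              epoch_length = epoch_length, epoch_shift = epoch_shift,
              amplitude_threshold = amplitude_threshold,
              trend_slope_threshold = trend_slope_threshold,
              step_threshold = step_threshold)
  if (!(cfg$highpass_cutoff > 0 &&
        cfg$highpass_cutoff < cfg$lowpass_cutoff)) {
    stop("need 0 < highpass_cutoff < lowpass_cutoff", call. = FALSE)
  }
  if (cfg$filter_order < 1) stop("filter_order must be >= 1", call. = FALSE)
  if (!(cfg$epoch_shift > 0 && cfg$epoch_length > 0 &&
        cfg$epoch_shift <= cfg$epoch_length)) {
    stop("need 0 < epoch_shift <= epoch_length", call. = FALSE)
  }
  thr <- c(cfg$amplitude_threshold, cfg$trend_slope_threshold,
           cfg$step_threshold)
  if (any(thr <= 0)) stop("thresholds must be strictly positive",
                          call. = FALSE)
  structure(cfg, class = "wl_preprocess_config")
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass as a cascade of a high-pass and a
#' low-pass section of the configured order, each run forward-backward
#' (`signal::filtfilt`) so the passband is phase-neutral relative to the
#' annotation timeline.
#'
#' @param rec A `wl_recording`.
#' @param cfg A [preprocess_config()].
#' @return The filtered recording (identical shape).
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "wl_recording"))
  ny <- rec$sampling_rate / 2
  if (cfg$lowpass_cutoff >= ny) {
    stop("low-pass cutoff (", cfg$lowpass_cutoff,
         " Hz) must be below the Nyquist frequency (", ny, " Hz)",
         call. = FALSE)
  }
  hp <- signal::butter(cfg$filter_order, cfg$highpass_cutoff / ny,
                       type = "high")
  lp <- signal::butter(cfg$filter_order, cfg$lowpass_cutoff / ny,
                       type = "low")
  for (i in seq_len(nrow(rec$data))) {
    x <- signal::filtfilt(hp, rec$data[i, ])
    rec$data[i, ] <- signal::filtfilt(lp, x)
  }
  rec
}

#' Remove eye-blink contributions using the forehead channel
#'
#' Blink intervals are detected on the reference channel (default FPz) from
#' a low-passed envelope using an amplitude criterion or a derivative
#' criterion; detected runs are merged and padded by `margin` seconds.
#' Within each interval the reference-correlated component is regressed out
#' of every other channel; outside the intervals the signal is untouched,
#' so no data are lost to the correction.
#'
#' @param rec A `wl_recording` (already band-pass filtered).
#' @param reference_label Blink reference channel label.
#' @param amplitude_threshold Envelope amplitude criterion, uV.
#' @param derivative_threshold Envelope derivative criterion, uV/s.
#' @param envelope_cutoff Low-pass cutoff of the detection envelope, Hz.
#' @param margin Padding added to each side of a detected interval, s.
#' @param merge_gap Intervals closer than this are merged, s.
#' @return A list with `recording` (corrected) and `blink_intervals`
#'   (data frame of `start_s`, `end_s`).
#' @export
remove_blinks <- function(rec, reference_label = "FPz",
                          amplitude_threshold = 50,
                          derivative_threshold = 1000,
                          envelope_cutoff = 6, margin = 0.15,
                          merge_gap = 0.1) {
  stopifnot(inherits(rec, "wl_recording"))
  ridx <- match(reference_label, rec$channel_labels)
  if (is.na(ridx)) {
    stop("blink reference channel '", reference_label,
         "' not present in the recording", call. = FALSE)
  }
  fs <- rec$sampling_rate
  ref <- rec$data[ridx, ]
  lp <- signal::butter(2, envelope_cutoff / (fs / 2), type = "low")
  env <- signal::filtfilt(lp, ref)
  deriv <- c(0, diff(env)) * fs
  mask <- abs(env) > amplitude_threshold |
          abs(deriv) > derivative_threshold
  intervals <- mask_to_intervals(mask, fs, margin = margin,
                                 merge_gap = merge_gap,
                                 n = length(ref))
  if (nrow(intervals)) {
    # the reference baseline is its recording-wide mean (~0 after the
    # high-pass): subtracting beta * (ref - baseline) removes the blink
    # deflection without stepping the channel mean inside the interval
    baseline <- mean(ref)
    for (k in seq_len(nrow(intervals))) {
      idx <- intervals$start_idx[k]:intervals$end_idx[k]
      seg_ref <- ref[idx] - mean(ref[idx])
      denom <- sum(seg_ref^2)
      if (denom <= 0) next
      for (i in seq_len(nrow(rec$data))) {
        if (i == ridx) next
        seg <- rec$data[i, idx]
        beta <- sum((seg - mean(seg)) * seg_ref) / denom
        rec$data[i, idx] <- seg - beta * (ref[idx] - baseline)
      }
    }
  }
  list(recording = rec,
       blink_intervals = intervals[, c("start_s", "end_s")])
}

mask_to_intervals <- function(mask, fs, margin = 0, merge_gap = 0, n) {
  if (!any(mask)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      start_s = numeric(0), end_s = numeric(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  s <- pmax(1L, starts[keep] - as.integer(round(margin * fs)))
  e <- pmin(n, ends[keep] + as.integer(round(margin * fs)))
  # merge overlapping or near-adjacent intervals
  gap <- as.integer(round(merge_gap * fs))
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(s)[-1]) {
    if (s[k] <= me + gap) {
      me <- max(me, e[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[k]; me <- e[k]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start_idx = out_s, end_idx = out_e,
             start_s = (out_s - 1L) / fs, end_s = (out_e - 1L) / fs)
}

#' Segment a recording into sliding epochs
#'
#' Epochs start at 0, `epoch_shift`, 2 x `epoch_shift`, ... while the full
#' epoch fits inside the recording. All artifact flags start empty.
#'
#' @param rec A `wl_recording`.
#' @param cfg A [preprocess_config()].
#' @return A `wl_epochs` object: `channels` (named list of epoch x sample
#'   matrices, uV), `start_times`, `artifact_flags` (list of reason-code
#'   vectors), `retained` (logical).
#' @export
segment_epochs <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "wl_recording"))
  fs <- rec$sampling_rate
  spe <- cfg$epoch_length * fs
  shift <- cfg$epoch_shift * fs
  if (abs(spe - round(spe)) > 1e-9 || abs(shift - round(shift)) > 1e-9) {
    stop("epoch_length and epoch_shift must be multiples of the sample ",
         "period (1/", fs, " s)", call. = FALSE)
  }
  spe <- as.integer(round(spe)); shift <- as.integer(round(shift))
  n <- ncol(rec$data)
  if (n < spe) {
    stop("recording (", n / fs, " s) is shorter than one epoch (",
         cfg$epoch_length, " s)", call. = FALSE)
  }
  starts0 <- seq(0L, n - spe, by = shift)          # 0-based sample starts
  ne <- length(starts0)
  nc <- nrow(rec$data)
  idx <- outer(starts0, seq_len(spe), "+")          # ne x spe sample index
  chans <- vector("list", nc)
  names(chans) <- rec$channel_labels
  for (c in seq_len(nc)) {
    chans[[c]] <- matrix(rec$data[c, ][idx], ne, spe)
  }
  structure(
    list(channels = chans, channel_labels = rec$channel_labels,
         sampling_rate = fs, start_times = starts0 / fs,
         epoch_length = cfg$epoch_length, epoch_shift = cfg$epoch_shift,
         artifact_flags = replicate(ne, character(0), simplify = FALSE),
         retained = rep(TRUE, ne), subject_id = rec$subject_id),
    class = "wl_epochs")
}

#' @export
print.wl_epochs <- function(x, ...) {
  cat(sprintf(
    "<wl_epochs> %d epochs (%g s, shift %g s) x %d channels; %d retained\n",
    nrow(x$channels[[1]]), x$epoch_length, x$epoch_shift,
    length(x$channels), sum(x$retained)))
  invisible(x)
}

row_abs_max <- function(M) {
  A <- abs(M)
  A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
}

#' Flag artifact epochs by amplitude, trend and step criteria
#'
#' Every non-reference channel of every epoch is tested against three
#' criteria: (a) maximum absolute amplitude above `amplitude_threshold`
#' ("amplitude"); (b) absolute slope of the ordinary least-squares linear
#' fit against time above `trend_slope_threshold` ("trend"); (c) maximum
#' absolute sample-to-sample difference above `step_threshold` ("step").
#' Any channel failing a criterion flags the whole epoch with that reason
#' code; flags accumulate and the retained mask is recomputed. The
#' operation is idempotent.
#'
#' @param ep A `wl_epochs` object.
#' @param cfg A [preprocess_config()].
#' @param reference_label Channel excluded from testing (the blink
#'   reference).
#' @return The `wl_epochs` object with `artifact_flags` and `retained`
#'   filled in.
#' @export
reject_artifacts <- function(ep, cfg = preprocess_config(),
                             reference_label = "FPz") {
  stopifnot(inherits(ep, "wl_epochs"))
  test_ch <- which(ep$channel_labels != reference_label)
  ne <- nrow(ep$channels[[1]])
  spe <- ncol(ep$channels[[1]])
  fs <- ep$sampling_rate
  tc <- (seq_len(spe) - 1) / fs
  tc <- tc - mean(tc)
  stc <- sum(tc^2)
  amp_f <- trend_f <- step_f <- rep(FALSE, ne)
  for (c in test_ch) {
    M <- ep$channels[[c]]
    amp_f <- amp_f | (row_abs_max(M) > cfg$amplitude_threshold)
    slope <- as.vector(M %*% tc) / stc
    trend_f <- trend_f | (abs(slope) > cfg$trend_slope_threshold)
    D <- M[, -1, drop = FALSE] - M[, -spe, drop = FALSE]
    step_f <- step_f | (row_abs_max(D) > cfg$step_threshold)
  }
  flags <- vector("list", ne)
  flags[] <- list(character(0))
  codes <- c("amplitude", "trend", "step")
  for (i in which(amp_f | trend_f | step_f)) {
    flags[[i]] <- codes[c(amp_f[i], trend_f[i], step_f[i])]
  }
  ep$artifact_flags <- flags
  ep$retained <- lengths(flags) == 0
  ep
}

#' Export an epoch set summary to CSV
#'
#' @param ep A `wl_epochs` object after [reject_artifacts()].
#' @param path Output CSV path.
#' @return The summary data frame (epoch, start_s, retained, flags),
#'   invisibly written to `path` when given.
#' @export
epochs_summary <- function(ep, path = NULL) {
  df <- data.frame(
    epoch = seq_along(ep$start_times),
    start_s = ep$start_times,
    retained = ep$retained,
    flags = vapply(ep$artifact_flags, paste, "", collapse = "|"))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
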