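# Per-epoch PSD, individual alpha frequency, IAF-anchored band/ROI
# features and the frontal-theta / parietal-alpha ratio.

#' Region-of-interest and band definition
#'
#' Bands are anchored to the Individual Alpha Frequency (IAF): theta spans
#' `[IAF - 6, IAF - 2]` Hz over the frontal channels and alpha spans
#' `[IAF - 2, IAF + 2]` Hz over the parietal channels, endpoints inclusive
#' on both sides (theta and alpha share the `IAF - 2` bin). At 0.5 Hz
#' resolution each band holds 9 bins and the full range
#' `[IAF - 6, IAF + 2]` holds 17.
#'
#' @param frontal_channels Frontal channel labels.
#' @param parietal_channels Parietal channel labels.
#' @param theta_offsets Theta band limits relative to IAF, Hz.
#' @param alpha_offsets Alpha band limits relative to IAF, Hz.
#' @return A `wl_roi` list.
#' @export
roi_definition <- function(frontal_channels = wl_montage()$frontal,
                           parietal_channels = wl_montage()$parietal,
                           theta_offsets = c(-6, -2),
                           alpha_offsets = c(-2, 2)) {
  structure(list(frontal = frontal_channels, parietal = parietal_channels,
                 theta_offsets = theta_offsets,
                 alpha_offsets = alpha_offsets),
            class = "wl_roi")
}

#' Per-epoch Hanning-windowed power spectral density
#'
#' One periodogram per epoch per channel, using a Hanning window spanning
#' the whole epoch (no sub-segmentation), so the bin spacing equals
#' `1 / epoch_length` (0.5 Hz for 2-s epochs). The window is
#' power-normalized (`2 / (fs * sum(w^2))`, one-sided) so the integrated
#' power of a stationary sinusoid of amplitude A recovers A^2/2.
#'
#' @param ep A `wl_epochs` object.
#' @param retained_only Keep only epochs that survived artifact rejection.
#' @param max_freq Optional upper frequency bound of the stored bins, Hz
#'   (`NULL` keeps the full range up to Nyquist). The periodogram itself is
#'   unchanged; this only trims the stored matrix.
#' @return A `wl_spectra` object: `psd` (epoch x channel x bin, uV^2/Hz),
#'   `freqs` (Hz), `start_times` (s).
#' @export
compute_psd <- function(ep, retained_only = TRUE, max_freq = NULL) {
  stopifnot(inherits(ep, "wl_epochs"))
  keep <- if (retained_only) which(ep$retained)
          else seq_along(ep$retained)
  if (!length(keep)) stop("no epochs to analyze (all rejected?)",
                          call. = FALSE)
  spe <- ncol(ep$channels[[1]])
  nc <- length(ep$channels)
  fs <- ep$sampling_rate
  k <- seq_len(spe) - 1
  w <- 0.5 * (1 - cos(2 * pi * k / (spe - 1)))   # symmetric Hanning
  U <- sum(w^2)
  nyq_nb <- spe %/% 2 + 1
  freqs <- (0:(spe %/% 2)) * fs / spe
  nb <- if (is.null(max_freq)) nyq_nb
        else max(which(freqs <= max_freq + 1e-9))
  freqs <- freqs[seq_len(nb)]
  psd <- array(0, dim = c(length(keep), nc, nb))
  for (c in seq_len(nc)) {
    Xw <- t(ep$channels[[c]][keep, , drop = FALSE]) * w  # spe x n_keep
    F <- stats::mvfft(Xw)
    P <- (Mod(F[seq_len(nb), , drop = FALSE])^2) * (2 / (fs * U))
    P[1, ] <- P[1, ] / 2
    if (nb == nyq_nb) P[nb, ] <- P[nb, ] / 2
    psd[, c, ] <- t(P)
  }
  structure(
    list(psd = psd, freqs = freqs, bin_hz = fs / spe,
         start_times = ep$start_times[keep],
         channel_labels = ep$channel_labels,
         epoch_length = ep$epoch_length, epoch_shift = ep$epoch_shift,
         sampling_rate = fs, subject_id = ep$subject_id),
    class = "wl_spectra")
}

#' @export
print.wl_spectra <- function(x, ...) {
  cat(sprintf(
    "<wl_spectra> %d epochs x %d channels x %d bins (%g Hz spacing)\n",
    dim(x$psd)[1], dim(x$psd)[2], dim(x$psd)[3], x$bin_hz))
  invisible(x)
}

#' Restrict a spectral frame to epochs inside a time interval
#'
#' Keeps epochs whose full `[start, start + epoch_length]` span lies inside
#' `[onset, onset + duration]` — used to isolate the eyes-closed baseline
#' for IAF estimation.
#'
#' @param frame A `wl_spectra` object.
#' @param onset_s,duration_s Interval bounds in seconds.
#' @return The restricted `wl_spectra`.
#' @export
spectra_in_interval <- function(frame, onset_s, duration_s) {
  keep <- frame$start_times >= onset_s - 1e-9 &
          frame$start_times + frame$epoch_length <=
            onset_s + duration_s + 1e-9
  if (!any(keep)) stop("no epochs inside [", onset_s, ", ",
                       onset_s + duration_s, "] s", call. = FALSE)
  frame$psd <- frame$psd[keep, , , drop = FALSE]
  frame$start_times <- frame$start_times[keep]
  frame
}

#' Estimate the Individual Alpha Frequency
#'
#' The IAF is the frequency of the maximum of the epoch-averaged,
#' parietal-averaged PSD inside `search_range`, computed from eyes-closed
#' data. If the in-range spectrum is flat or its maximum sits on the range
#' boundary (no local maximum strictly inside), the population-typical
#' fallback of 10 Hz is returned with a warning.
#'
#' @param frame A `wl_spectra` restricted to the eyes-closed interval (see
#'   [spectra_in_interval()]).
#' @param roi A [roi_definition()] (parietal channel set).
#' @param search_range Alpha-peak search window in Hz.
#' @param fallback IAF used when no peak exists, Hz.
#' @param source Label of the annotation the frame was restricted to.
#' @return A `wl_iaf` list: `iaf`, `search_range`, `peak_power`, `source`.
#' @export
estimate_iaf <- function(frame, roi = roi_definition(),
                         search_range = c(7, 13), fallback = 10,
                         source = "eyes_closed") {
  stopifnot(inherits(frame, "wl_spectra"))
  pidx <- match(roi$parietal, frame$channel_labels)
  if (anyNA(pidx)) {
    stop("parietal channel(s) missing: ",
         paste(roi$parietal[is.na(pidx)], collapse = ", "), call. = FALSE)
  }
  spec <- apply(frame$psd[, pidx, , drop = FALSE], 3, mean)
  inr <- which(frame$freqs >= search_range[1] - 1e-9 &
               frame$freqs <= search_range[2] + 1e-9)
  if (length(inr) < 3) stop("search range too narrow for the bin spacing",
                            call. = FALSE)
  s <- spec[inr]
  pk <- which.max(s)
  flat <- diff(range(s)) <= 1e-12 * max(abs(s), 1e-300)
  if (flat || pk == 1L || pk == length(s)) {
    warning("no alpha peak strictly inside [", search_range[1], ", ",
            search_range[2], "] Hz; falling back to IAF = ", fallback,
            " Hz", call. = FALSE)
    return(structure(list(iaf = fallback, search_range = search_range,
                          peak_power = NA_real_, source = source,
                          fallback = TRUE), class = "wl_iaf"))
  }
  structure(list(iaf = frame$freqs[inr[pk]], search_range = search_range,
                 peak_power = s[pk], source = source, fallback = FALSE),
            class = "wl_iaf")
}

#' @export
print.wl_iaf <- function(x, ...) {
  cat(sprintf("<wl_iaf> %g Hz (search %g-%g Hz, source: %s%s)\n", x$iaf,
              x$search_range[1], x$search_range[2], x$source,
              if (isTRUE(x$fallback)) ", fallback" else ""))
  invisible(x)
}

#' Enumerate the feature domain for a montage and band configuration
#'
#' @param iaf IAF in Hz (a `wl_iaf` or a number).
#' @param roi A [roi_definition()].
#' @param bin_hz Frequency-bin spacing, Hz.
#' @param analysis_channels Channels of the full (unrestricted) domain.
#' @return A list with `full` (all analysis channels x all bins of
#'   `[IAF - 6, IAF + 2]`) and `roi` (frontal-theta plus parietal-alpha
#'   pairs), each a data frame of `channel`, `freq_hz`, `band`.
#' @export
feature_domain <- function(iaf, roi = roi_definition(), bin_hz = 0.5,
                           analysis_channels = wl_montage()$analysis) {
  if (inherits(iaf, "wl_iaf")) iaf <- iaf$iaf
  lo <- iaf + min(roi$theta_offsets)
  hi <- iaf + max(roi$alpha_offsets)
  all_bins <- seq(lo, hi, by = bin_hz)
  full <- expand.grid(freq_hz = all_bins, channel = analysis_channels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- full[, c("channel", "freq_hz")]
  full$band <- "full"
  theta_bins <- seq(iaf + roi$theta_offsets[1], iaf + roi$theta_offsets[2],
                    by = bin_hz)
  alpha_bins <- seq(iaf + roi$alpha_offsets[1], iaf + roi$alpha_offsets[2],
                    by = bin_hz)
  th <- expand.grid(freq_hz = theta_bins, channel = roi$frontal,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  th$band <- "theta"
  al <- expand.grid(freq_hz = alpha_bins, channel = roi$parietal,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  al$band <- "alpha"
  roi_df <- rbind(th[, c("channel", "freq_hz", "band")],
                  al[, c("channel", "freq_hz", "band")])
  rownames(full) <- rownames(roi_df) <- NULL
  list(full = full, roi = roi_df)
}

#' Extract ROI-restricted workload features
#'
#' Features are the (log10-transformed by default) PSD values at every
#' (frontal channel, theta bin) and (parietal channel, alpha bin) pair,
#' ordered channel-major then frequency-ascending. For the default montage
#' and 0.5 Hz bins this gives 99 features (45 frontal-theta + 54
#' parietal-alpha) out of a full domain of 187 (11 channels x 17 bins).
#'
#' @param frame A `wl_spectra` object.
#' @param iaf A `wl_iaf` (or IAF in Hz).
#' @param roi A [roi_definition()].
#' @param transform `"log10"` (default; stabilizes the right skew of band
#'   power) or `"linear"`.
#' @param highpass_cutoff Lower frequency limit; bands extending below it
#'   raise an error listing the truncated bins.
#' @return A `wl_features` object: `features` (epoch x feature matrix),
#'   `ids` (channel, freq_hz, band), `start_times`, optional `labels`.
#' @export
extract_roi_features <- function(frame, iaf, roi = roi_definition(),
                                 transform = c("log10", "linear"),
                                 highpass_cutoff = 1) {
  stopifnot(inherits(frame, "wl_spectra"))
  transform <- match.arg(transform)
  iaf_hz <- if (inherits(iaf, "wl_iaf")) iaf$iaf else iaf
  dom <- feature_domain(iaf_hz, roi, bin_hz = frame$bin_hz,
                        analysis_channels =
                          setdiff(frame$channel_labels, character(0)))
  ids <- dom$roi
  below <- unique(ids$freq_hz[ids$freq_hz < highpass_cutoff - 1e-9])
  if (length(below)) {
    stop("band extends below the high-pass cutoff (", highpass_cutoff,
         " Hz); truncated bins: ", paste(below, collapse = ", "), " Hz",
         call. = FALSE)
  }
  cidx <- match(ids$channel, frame$channel_labels)
  fidx <- vapply(ids$freq_hz, function(f) {
    j <- which(abs(frame$freqs - f) < frame$bin_hz / 4)
    if (!length(j)) NA_integer_ else j[1]
  }, 1L)
  if (anyNA(cidx) || anyNA(fidx)) {
    stop("feature domain does not align with the spectral frame ",
         "(missing channels or bins)", call. = FALSE)
  }
  ne <- dim(frame$psd)[1]
  X <- matrix(0, ne, nrow(ids))
  for (j in seq_len(nrow(ids))) {
    X[, j] <- frame$psd[, cidx[j], fidx[j]]
  }
  if (transform == "log10") X <- log10(pmax(X, 1e-15))
  colnames(X) <- paste0(ids$channel, "@", ids$freq_hz)
  structure(
    list(features = X, ids = ids, start_times = frame$start_times,
         labels = NULL, iaf = iaf_hz, transform = transform,
         epoch_length = frame$epoch_length,
         epoch_shift = frame$epoch_shift, subject_id = frame$subject_id),
    class = "wl_features")
}

#' @export
print.wl_features <- function(x, ...) {
  cat(sprintf("<wl_features> %d epochs x %d features (%s PSD, IAF %g Hz)\n",
              nrow(x$features), ncol(x$features), x$transform, x$iaf))
  invisible(x)
}

#' Frontal-theta / parietal-alpha workload ratio
#'
#' The classical workload indicator: per epoch, the mean PSD over frontal
#' channels and theta bins divided by the mean PSD over parietal channels
#' and alpha bins. The ratio increases with mental workload and is
#' invariant to global amplitude rescaling of the recording.
#'
#' @param frame A `wl_spectra` object.
#' @param iaf A `wl_iaf` (or IAF in Hz).
#' @param roi A [roi_definition()].
#' @return Numeric vector, one ratio per epoch (NA with a warning when the
#'   parietal-alpha denominator is zero).
#' @export
theta_alpha_ratio <- function(frame, iaf, roi = roi_definition()) {
  stopifnot(inherits(frame, "wl_spectra"))
  iaf_hz <- if (inherits(iaf, "wl_iaf")) iaf$iaf else iaf
  fidx <- match(roi$frontal, frame$channel_labels)
  pidx <- match(roi$parietal, frame$channel_labels)
  if (anyNA(fidx) || anyNA(pidx)) {
    stop("ROI channels missing from the spectral frame", call. = FALSE)
  }
  tbin <- which(frame$freqs >= iaf_hz + roi$theta_offsets[1] - 1e-9 &
                frame$freqs <= iaf_hz + roi$theta_offsets[2] + 1e-9)
  abin <- which(frame$freqs >= iaf_hz + roi$alpha_offsets[1] - 1e-9 &
                frame$freqs <= iaf_hz + roi$alpha_offsets[2] + 1e-9)
  if (!length(tbin) || !length(abin)) {
    stop("empty theta or alpha band for IAF = ", iaf_hz, " Hz",
         call. = FALSE)
  }
  num <- apply(frame$psd[, fidx, tbin, drop = FALSE], 1, mean)
  den <- apply(frame$psd[, pidx, abin, drop = FALSE], 1, mean)
  out <- num / den
  if (any(den == 0)) {
    warning("zero parietal-alpha power in ", sum(den == 0),
            " epoch(s); ratio set to NA", call. = FALSE)
    out[den == 0] <- NA_real_
  }
  out
}
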