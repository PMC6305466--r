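# Shared fixtures, all generated in code.

FS <- 256

# A 12-channel recording whose channels are all `x` unless overridden by
# name in `override` (a named list of vectors of the same length).
make_recording <- function(x, override = list(), fs = FS,
                           annotations = NULL, subject_id = "test") {
  mon <- wl_montage()
  data <- matrix(rep(x, each = length(mon$channels)),
                 nrow = length(mon$channels))
  rownames(data) <- mon$channels
  for (ch in names(override)) data[ch, ] <- override[[ch]]
  raw_recording(data, mon$channels, fs, annotations = annotations,
                subject_id = subject_id)
}

sine_wave <- function(freq, duration, amplitude = 1, fs = FS) {
  amplitude * sin(2 * pi * freq * (0:(duration * fs - 1)) / fs)
}

# One crafted 2-s epoch set (12 channels; the crafted signal on Fz).
single_epoch_set <- function(signal, fs = FS) {
  cfg <- preprocess_config(epoch_length = 2, epoch_shift = 2)
  rec <- make_recording(rep(0, length(signal)),
                        override = list(Fz = signal), fs = fs)
  segment_epochs(rec, cfg)
}

# A hand-built workload series on a regular 8-s grid.
make_series <- function(timestamps, wl, window = 8, coverage = 1) {
  df <- data.frame(timestamp_s = timestamps, y_mean = wl, wl = wl,
                   coverage = coverage, n_epochs = 64L)
  attr(df, "window") <- window
  attr(df, "min_coverage") <- 0.25
  class(df) <- c("wl_series", "data.frame")
  df
}

# Compact simulated session for plumbing tests (events need >= 30 s Hard
# segments, so the short protocol drops them unless asked for).
short_protocol <- function(segment_s = 24, eyes_closed_s = 16,
                           events = FALSE) {
  default_protocol(eyes_closed_s = eyes_closed_s, segment_s = segment_s,
                   events = events)
}

# Band-limited 1/f noise via frequency-domain shaping (test-local
# implementation, independent of the package generator).
one_over_f <- function(n, fs = FS, exponent = 1, f_lo = 1, f_hi = 30) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- ifelse(f >= f_lo & f <= f_hi, f^(-exponent / 2), 0)
  ph <- runif(nf, 0, 2 * pi)
  X <- complex(n)
  X[2:(nf + 1)] <- amp * exp(1i * ph)
  X[n:(n - nf + 2)] <- Conj(X[2:nf])
  x <- Re(fft(X, inverse = TRUE))
  x / sd(x)
}

# A hand-built spectral frame (epoch x channel x bin PSD).
make_frame <- function(psd, freqs, channels = wl_montage()$channels,
                       fs = FS) {
  structure(
    list(psd = psd, freqs = freqs, bin_hz = freqs[2] - freqs[1],
         start_times = (seq_len(dim(psd)[1]) - 1) * 0.125,
         channel_labels = channels, epoch_length = 2, epoch_shift = 0.125,
         sampling_rate = fs, subject_id = "test"),
    class = "wl_spectra")
}

uniform_frame <- function(value = 1, n_epochs = 4,
                          freqs = seq(0, 30, 0.5)) {
  make_frame(array(value, c(n_epochs, 12, length(freqs))), freqs)
}

# Brute-force AUC by pair counting (independent oracle).
auc_bruteforce <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns
# (independent oracle; no ties in abs(d) assumed).
wilcoxon_exact_bruteforce <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  center <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - center) >= abs(v_obs - center) - 1e-9)
}

# Friedman chi-squared from the textbook rank formula (independent
# oracle; assumes no ties within rows).
friedman_bruteforce <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- colSums(t(apply(m, 1, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}
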