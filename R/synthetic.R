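# Synthetic multichannel EEG sessions with full ground truth: 1/f
# background, parietal alpha at a subject-specific peak frequency,
# condition-dependent frontal theta, FPz-dominant blinks and sporadic
# high-amplitude artifacts.

#' Simulation specification
#'
#' Defines the statistical structure of a simulated driving session. The
#' oscillatory sources are band-limited filtered noise (not pure
#' sinusoids) so the periodogram bins across each band are populated, as
#' in real EEG. Condition effects act multiplicatively on source
#' amplitude, hence squared on band power: Hard road multiplies theta
#' amplitude by `hard_theta_gain` (1.5) and alpha by `hard_alpha_gain`
#' (0.7); Rush hour pushes both effects further by `rush_gain` (theta
#' x 1.2, alpha / 1.2). The alpha source is boosted during the
#' eyes-closed baseline, as in resting EEG.
#'
#' @param subject_id Subject identifier.
#' @param iaf True individual alpha frequency, Hz.
#' @param sampling_rate Hz.
#' @param bg_exponent 1/f background spectral exponent.
#' @param bg_rms Background RMS amplitude per channel, uV.
#' @param alpha_rms Named RMS amplitudes of the parietal alpha source, uV.
#' @param theta_rms Named RMS amplitudes of the frontal theta source, uV.
#' @param alpha_bw,theta_bw Source bandwidths, Hz.
#' @param theta_offset Center of the theta source relative to IAF, Hz.
#' @param hard_theta_gain,hard_alpha_gain Amplitude gains of the Hard road
#'   relative to Easy.
#' @param rush_gain Additional effect multiplier of the Rush hour.
#' @param eyes_closed_alpha_boost Alpha amplitude gain during the
#'   eyes-closed baseline.
#' @param blink_rate Blinks per minute.
#' @param blink_amplitude Blink peak amplitude at FPz, uV.
#' @param blink_duration Blink duration, s.
#' @param blink_coeffs Named per-channel blink propagation coefficients
#'   (FPz 1.0, decaying toward parietal sites).
#' @param artifact_rate Sporadic artifacts per minute.
#' @param artifact_amplitude Artifact peak amplitude, uV.
#' @param artifact_duration Artifact duration, s.
#' @param event_theta_gain Extra frontal-theta amplitude gain inside event
#'   windows (the workload-relevant event response).
#' @param seed Integer seed; identical specs give identical sessions.
#' @return A `wl_simspec` list.
#' @export
simulation_spec <- function(subject_id = "sim01", iaf = 10,
                            sampling_rate = 256,
                            bg_exponent = 1, bg_rms = 10,
                            alpha_rms = c(P3 = 4, P7 = 3.5, Pz = 5,
                                          P4 = 4, P8 = 3.5, POz = 5),
                            theta_rms = c(AF3 = 2.5, AF4 = 2.5, F3 = 3,
                                          Fz = 3.5, F4 = 3),
                            alpha_bw = 2, theta_bw = 2, theta_offset = -4,
                            hard_theta_gain = 1.5, hard_alpha_gain = 0.7,
                            rush_gain = 1.2,
                            eyes_closed_alpha_boost = 2,
                            blink_rate = 10, blink_amplitude = 200,
                            blink_duration = 0.3,
                            blink_coeffs = c(FPz = 1, AF3 = 0.5,
                                             AF4 = 0.5, F3 = 0.3,
                                             Fz = 0.3, F4 = 0.3,
                                             P3 = 0.08, P7 = 0.08,
                                             Pz = 0.08, P4 = 0.08,
                                             P8 = 0.08, POz = 0.05),
                            artifact_rate = 1, artifact_amplitude = 200,
                            artifact_duration = 0.1,
                            event_theta_gain = 1.4, seed = 1) {
  spec <- as.list(environment())
  gains <- c(hard_theta_gain, hard_alpha_gain, rush_gain,
             eyes_closed_alpha_boost, event_theta_gain)
  if (any(gains <= 0)) stop("all gains must be > 0", call. = FALSE)
  if (blink_rate < 0 || artifact_rate < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  structure(spec, class = "wl_simspec")
}

#' Default experimental protocol annotation plan
#'
#' One-minute eyes-closed baseline, then for each traffic hour (Normal,
#' Rush) three laps of a circuit made of an Easy and a Hard road segment.
#' During the third lap of each hour a Pedestrian event (10-s window) is
#' acted in the Easy segment and a Car event (20-s window) in the Hard
#' segment, each tagged with a circuit-position key so the matched
#' no-event window of lap 2 can be located.
#'
#' @param eyes_closed_s Baseline duration, s.
#' @param segment_s Duration of each road segment, s.
#' @param hours Traffic conditions.
#' @param n_laps Laps per hour.
#' @param events Include lap-3 events.
#' @return Annotation data frame (onset_s, duration_s, label).
#' @export
default_protocol <- function(eyes_closed_s = 60, segment_s = 40,
                             hours = c("Normal", "Rush"), n_laps = 3,
                             events = TRUE) {
  rows <- list(data.frame(onset_s = 0, duration_s = eyes_closed_s,
                          label = "eyes_closed"))
  t <- eyes_closed_s
  for (hour in hours) {
    for (lap in seq_len(n_laps)) {
      for (road in c("Easy", "Hard")) {
        rows[[length(rows) + 1L]] <- data.frame(
          onset_s = t, duration_s = segment_s,
          label = sprintf("hour=%s;road=%s;lap=%d", hour, road, lap))
        if (events && lap == n_laps) {
          if (road == "Easy") {
            rows[[length(rows) + 1L]] <- data.frame(
              onset_s = t + 15, duration_s = 10,
              label = "event=Pedestrian;position=ped1")
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              onset_s = t + 10, duration_s = 20,
              label = "event=Car;position=car1")
          }
        }
        t <- t + segment_s
      }
    }
  }
  do.call(rbind, rows)
}

# Band-limited unit-RMS noise sources -------------------------------------

colored_noise <- function(n, fs, exponent, f_lo, f_hi) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- ifelse(f >= f_lo & f <= f_hi, f^(-exponent / 2), 0)
  ph <- stats::runif(nf, 0, 2 * pi)
  half <- amp * exp(1i * ph)
  X <- complex(n)
  X[2:(nf + 1)] <- half
  if (n %% 2 == 0) {
    X[nf + 1] <- complex(real = amp[nf], imaginary = 0)
    X[(nf + 2):n] <- Conj(half[(nf - 1):1])
  } else {
    X[(nf + 2):n] <- Conj(half[nf:1])
  }
  x <- Re(stats::fft(X, inverse = TRUE))
  x / stats::sd(x)
}

band_noise <- function(n, fs, center, bw) {
  ny <- fs / 2
  lo <- max(center - bw / 2, 0.25) / ny
  hi <- min(center + bw / 2, ny - 0.25) / ny
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

blink_wave <- function(fs, duration, amplitude) {
  m <- round(duration * fs)
  amplitude * sin(pi * (seq_len(m) - 0.5) / m)^2
}

# Per-sample amplitude envelopes from the protocol -------------------------

condition_envelopes <- function(spec, ann, n, fs) {
  theta <- rep(1, n); alpha <- rep(1, n)
  parsed <- parse_annotations(ann)
  idx_of <- function(onset, dur) {
    lo <- max(1L, as.integer(round(onset * fs)) + 1L)
    hi <- min(n, as.integer(round((onset + dur) * fs)))
    if (lo > hi) integer(0) else lo:hi
  }
  for (k in seq_len(nrow(parsed))) {
    idx <- idx_of(parsed$onset_s[k], parsed$duration_s[k])
    if (!length(idx)) next
    if (parsed$type[k] == "baseline") {
      alpha[idx] <- alpha[idx] * spec$eyes_closed_alpha_boost
    } else if (parsed$type[k] == "condition") {
      tg <- 1; ag <- 1
      if (parsed$road[k] == "Hard") {
        tg <- tg * spec$hard_theta_gain
        ag <- ag * spec$hard_alpha_gain
      }
      if (parsed$hour[k] == "Rush") {
        tg <- tg * spec$rush_gain
        ag <- ag / spec$rush_gain
      }
      theta[idx] <- theta[idx] * tg
      alpha[idx] <- alpha[idx] * ag
    } else if (parsed$type[k] == "event") {
      theta[idx] <- theta[idx] * spec$event_theta_gain
    }
  }
  list(theta = theta, alpha = alpha)
}

expected_condition_gains <- function(spec) {
  g <- expand.grid(hour = .hours, road = .roads,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$theta_gain <- ifelse(g$road == "Hard", spec$hard_theta_gain, 1) *
    ifelse(g$hour == "Rush", spec$rush_gain, 1)
  g$alpha_gain <- ifelse(g$road == "Hard", spec$hard_alpha_gain, 1) /
    ifelse(g$hour == "Rush", spec$rush_gain, 1)
  g
}

#' Simulate a full recording session with ground truth
#'
#' Generates a 12-channel recording following the annotation plan:
#' band-limited 1/f background on every channel, an alpha source at the
#' subject's IAF on the parietal channels (boosted while eyes are
#' closed), a theta source centered at `IAF + theta_offset` on the frontal
#' channels, condition gains applied over the annotated segments, blink
#' transients propagated from FPz, and sporadic high-amplitude artifacts
#' on random non-reference channels.
#'
#' @param spec A [simulation_spec()].
#' @param protocol Annotation plan (see [default_protocol()]); baseline
#'   and condition segments must tile the session without gaps or
#'   overlaps.
#' @return A list with `recording` (a `wl_recording` with the annotations
#'   attached) and `ground_truth`: `iaf`, `blink_intervals`,
#'   `artifact_intervals`, `condition_gains` (expected amplitude gain per
#'   hour x road cell), `spec`.
#' @export
simulate_session <- function(spec = simulation_spec(),
                             protocol = default_protocol()) {
  stopifnot(inherits(spec, "wl_simspec"))
  ann <- validate_annotations(protocol)
  parsed <- parse_annotations(ann)
  seg <- parsed[parsed$type %in% c("baseline", "condition"), , drop = FALSE]
  seg <- seg[order(seg$onset_s), ]
  ends <- seg$onset_s + seg$duration_s
  if (any(abs(seg$onset_s[-1] - ends[-nrow(seg)]) > 1e-9)) {
    stop("protocol has gaps or overlaps between segments", call. = FALSE)
  }
  if (abs(seg$onset_s[1]) > 1e-9) {
    stop("protocol must start at 0 s", call. = FALSE)
  }
  fs <- spec$sampling_rate
  dur <- max(ends)
  n <- as.integer(round(dur * fs))
  montage <- wl_montage()
  nc <- length(montage$channels)
  env <- condition_envelopes(spec, ann, n, fs)

  data <- with_local_seed(spec$seed, {
    out <- matrix(0, nc, n,
                  dimnames = list(montage$channels, NULL))
    set.seed(spec$seed + 1L)
    for (i in seq_len(nc)) {
      out[i, ] <- spec$bg_rms *
        colored_noise(n, fs, spec$bg_exponent, 1, 30)
    }
    set.seed(spec$seed + 2L)
    for (ch in names(spec$alpha_rms)) {
      src <- band_noise(n, fs, spec$iaf, spec$alpha_bw)
      out[ch, ] <- out[ch, ] + spec$alpha_rms[[ch]] * env$alpha * src
    }
    set.seed(spec$seed + 3L)
    for (ch in names(spec$theta_rms)) {
      src <- band_noise(n, fs, spec$iaf + spec$theta_offset, spec$theta_bw)
      out[ch, ] <- out[ch, ] + spec$theta_rms[[ch]] * env$theta * src
    }
    out
  })

  # blinks: a jittered point process with a refractory gap
  blink_intervals <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (spec$blink_rate > 0) {
    times <- with_local_seed(spec$seed + 4L, {
      n_blinks <- stats::rpois(1, spec$blink_rate * dur / 60)
      if (n_blinks > 0) {
        t <- sort(stats::runif(n_blinks, 1, dur - 1 - spec$blink_duration))
        t[c(TRUE, diff(t) > max(1, 3 * spec$blink_duration))]
      } else numeric(0)
    })
    if (length(times)) {
      wv <- blink_wave(fs, spec$blink_duration, spec$blink_amplitude)
      for (t in times) {
        i0 <- as.integer(round(t * fs)) + 1L
        idx <- i0:(i0 + length(wv) - 1L)
        for (ch in names(spec$blink_coeffs)) {
          data[ch, idx] <- data[ch, idx] + spec$blink_coeffs[[ch]] * wv
        }
      }
      blink_intervals <- data.frame(
        start_s = times, end_s = times + spec$blink_duration)
    }
  }

  # sporadic artifacts on random non-reference channels
  artifact_intervals <- data.frame(start_s = numeric(0),
                                   end_s = numeric(0),
                                   channel = character(0))
  if (spec$artifact_rate > 0) {
    art <- with_local_seed(spec$seed + 5L, {
      n_art <- stats::rpois(1, spec$artifact_rate * dur / 60)
      if (n_art > 0) {
        data.frame(
          t = stats::runif(n_art, 1, dur - 1 - spec$artifact_duration),
          ch = sample(montage$analysis, n_art, replace = TRUE))
      } else NULL
    })
    if (!is.null(art)) {
      m <- round(spec$artifact_duration * fs)
      wv <- spec$artifact_amplitude * sin(pi * (seq_len(m) - 0.5) / m)
      for (k in seq_len(nrow(art))) {
        i0 <- as.integer(round(art$t[k] * fs)) + 1L
        idx <- i0:(i0 + length(wv) - 1L)
        data[art$ch[k], idx] <- data[art$ch[k], idx] + wv
      }
      artifact_intervals <- data.frame(
        start_s = art$t, end_s = art$t + spec$artifact_duration,
        channel = art$ch)
    }
  }

  rec <- raw_recording(data, montage$channels, fs, annotations = ann,
                       subject_id = spec$subject_id)
  list(recording = rec,
       ground_truth = list(
         iaf = spec$iaf,
         blink_intervals = blink_intervals,
         artifact_intervals = artifact_intervals,
         condition_gains = expected_condition_gains(spec),
         spec = spec))
}

#' Epochs containing a ground-truth artifact peak
#'
#' An epoch is attributed to an injected artifact when it contains the
#' artifact's midpoint (epochs that clip only the first or last samples of
#' a transient need not exceed any rejection threshold).
#'
#' @param ground_truth Ground truth from [simulate_session()].
#' @param start_times Epoch start times, s.
#' @param epoch_length Epoch length, s.
#' @return Integer indices of epochs containing an injected artifact peak.
#' @export
artifact_epoch_indices <- function(ground_truth, start_times,
                                   epoch_length = 2) {
  iv <- ground_truth$artifact_intervals
  if (!nrow(iv)) return(integer(0))
  mid <- (iv$start_s + iv$end_s) / 2
  hit <- rep(FALSE, length(start_times))
  for (m in mid) {
    hit <- hit | (start_times < m & start_times + epoch_length > m)
  }
  which(hit)
}

#' Simulate a labeled Gaussian feature set
#'
#' Unit-variance Gaussian features for exercising the stepwise fit in
#' isolation: informative features are mean-shifted between the classes
#' by the stated effect sizes (Cohen's d), all others are independent
#' noise. For a single informative feature of effect d the Bayes-optimal
#' AUC is `pnorm(d / sqrt(2))`.
#'
#' @param n_per_class Epochs per class.
#' @param n_features Total feature count.
#' @param informative Indices of informative features.
#' @param effects Effect sizes, one per informative feature.
#' @param seed RNG seed.
#' @return A `wl_features` object with `labels` filled (0 then 1).
#' @export
simulate_feature_set <- function(n_per_class, n_features,
                                 informative = integer(0),
                                 effects = numeric(0), seed = 1) {
  if (length(informative) != length(effects)) {
    stop("`effects` must have one entry per informative feature",
         call. = FALSE)
  }
  if (length(informative) && max(informative) > n_features) {
    stop("informative indices exceed the feature range", call. = FALSE)
  }
  n <- 2L * n_per_class
  X <- with_local_seed(seed,
                       matrix(stats::rnorm(n * n_features), n, n_features))
  labels <- rep(c(0, 1), each = n_per_class)
  for (k in seq_along(informative)) {
    X[labels == 1, informative[k]] <-
      X[labels == 1, informative[k]] + effects[k]
  }
  ids <- data.frame(channel = sprintf("S%03d", seq_len(n_features)),
                    freq_hz = seq_len(n_features),
                    band = NA_character_)
  colnames(X) <- paste0(ids$channel, "@", ids$freq_hz)
  structure(
    list(features = X, ids = ids,
         start_times = (seq_len(n) - 1) * 0.125, labels = labels,
         iaf = NA_real_, transform = "linear",
         epoch_length = 2, epoch_shift = 0.125, subject_id = "sim"),
    class = "wl_features")
}
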