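test_that("band-pass filter passes 10 Hz, attenuates 50 Hz, keeps zeros", {
  cfg <- preprocess_config()
  zero <- make_recording(rep(0, 20 * FS))
  expect_equal(bandpass_filter(zero, cfg)$data, zero$data)

  trim <- function(x) x[(2 * FS):(18 * FS)]   # drop edge transients
  amp <- function(x) sqrt(2) * sqrt(mean(trim(x)^2))

  pass <- bandpass_filter(make_recording(sine_wave(10, 20)), cfg)
  expect_lt(abs(amp(pass$data["Fz", ]) - 1), 0.05)

  stopb <- bandpass_filter(make_recording(sine_wave(50, 20)), cfg)
  expect_lt(amp(stopb$data["Fz", ]), 0.15)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- make_recording(rep(0, 4 * FS))
  expect_error(bandpass_filter(rec, preprocess_config(lowpass_cutoff = 128)),
               "Nyquist")
  expect_error(preprocess_config(highpass_cutoff = 40, lowpass_cutoff = 30),
               "highpass_cutoff")
  expect_error(preprocess_config(step_threshold = 0), "positive")
  expect_error(preprocess_config(epoch_shift = 3), "epoch_shift")
})

test_that("blink removal is the identity when nothing crosses the criterion", {
  set.seed(21)
  rec <- make_recording(rnorm(6 * FS, sd = 5))
  out <- remove_blinks(rec)
  expect_equal(out$recording$data, rec$data)
  expect_equal(nrow(out$blink_intervals), 0)
})

test_that("injected blinks are detected and regressed out", {
  set.seed(22)
  n <- 30 * FS
  mon <- wl_montage()
  clean <- matrix(rnorm(12 * n, sd = 5), 12,
                  dimnames = list(mon$channels, NULL))
  blink_times <- c(5, 14, 23)
  wv <- 200 * sin(pi * (seq_len(round(0.3 * FS)) - 0.5) /
                    round(0.3 * FS))^2
  coef <- c(FPz = 1, F3 = 0.5, Pz = 0.1)
  data <- clean
  for (t in blink_times) {
    idx <- (round(t * FS) + 1):(round(t * FS) + length(wv))
    for (ch in names(coef)) {
      data[ch, idx] <- data[ch, idx] + coef[[ch]] * wv
    }
  }
  rec <- raw_recording(data, mon$channels, FS)
  out <- remove_blinks(rec)

  expect_equal(nrow(out$blink_intervals), 3)
  for (t in blink_times) {
    expect_true(any(out$blink_intervals$start_s <= t &
                    out$blink_intervals$end_s >= t + 0.25))
  }
  # residual blink component (vs the blink-free signal) reduced >= 90%
  for (ch in c("F3", "Pz")) {
    injected_rms <- sqrt(mean((data[ch, ] - clean[ch, ])^2))
    residual_rms <- sqrt(mean((out$recording$data[ch, ] - clean[ch, ])^2))
    expect_lt(residual_rms, 0.1 * injected_rms)
  }
})

test_that("blink removal requires the reference channel", {
  rec <- make_recording(rep(0, 2 * FS))
  expect_error(remove_blinks(rec, reference_label = "Oz"), "Oz")
})

test_that("sliding segmentation yields floor((T - L)/S) + 1 epochs", {
  cfg <- preprocess_config()
  ep <- segment_epochs(make_recording(rep(0, 10 * FS)), cfg)
  expect_equal(nrow(ep$channels[[1]]), 65)          # floor((10-2)/.125)+1
  expect_equal(ncol(ep$channels[[1]]), 512)         # 2 s x 256 Hz exactly
  expect_equal(diff(ep$start_times), rep(0.125, 64))
  expect_true(all(lengths(ep$artifact_flags) == 0))

  one <- segment_epochs(make_recording(rep(0, 2 * FS)), cfg)
  expect_equal(nrow(one$channels[[1]]), 1)

  expect_error(segment_epochs(make_recording(rep(0, round(1.9 * FS))), cfg),
               "shorter than one epoch")
})

test_that("the three artifact criteria flag crafted epochs as the thresholds dictate", {
  cfg <- preprocess_config()

  spike <- rep(0, 2 * FS); spike[300] <- 150
  ep <- reject_artifacts(single_epoch_set(spike), cfg)
  # a 150-uV one-sample spike exceeds both the 100-uV amplitude bound and
  # the 25-uV sample-to-sample bound
  expect_setequal(ep$artifact_flags[[1]], c("amplitude", "step"))
  expect_false(ep$retained[1])

  ramp <- seq(0, 25, length.out = 2 * FS)           # 12.5 uV/s slope
  ep <- reject_artifacts(single_epoch_set(ramp), cfg)
  expect_identical(ep$artifact_flags[[1]], "trend")

  jump <- c(rep(0, FS), rep(30, FS))                # 30-uV step mid-epoch
  ep <- reject_artifacts(single_epoch_set(jump), cfg)
  # the 30-uV jump also tilts the least-squares fit above 10 uV/s
  expect_setequal(ep$artifact_flags[[1]], c("step", "trend"))

  clean <- sine_wave(10, 2, amplitude = 20)
  expect_lt(max(abs(diff(clean))), 25)              # ~ 4.9 uV per sample
  ep <- reject_artifacts(single_epoch_set(clean), cfg)
  expect_identical(ep$artifact_flags[[1]], character(0))
  expect_true(ep$retained[1])
})

test_that("artifacts on the blink-reference channel do not flag epochs", {
  spike <- rep(0, 2 * FS); spike[100] <- 150
  cfg <- preprocess_config(epoch_length = 2, epoch_shift = 2)
  rec <- make_recording(rep(0, 2 * FS), override = list(FPz = spike))
  ep <- reject_artifacts(segment_epochs(rec, cfg), cfg)
  expect_true(ep$retained[1])
})

test_that("flagging is monotone in the thresholds and idempotent", {
  set.seed(23)
  n_ep <- 40
  cfg <- preprocess_config(epoch_length = 2, epoch_shift = 2)
  x <- rnorm(n_ep * 2 * FS, sd = 30)
  rec <- make_recording(rep(0, n_ep * 2 * FS), override = list(Pz = x))
  ep <- segment_epochs(rec, cfg)

  strict <- preprocess_config(epoch_length = 2, epoch_shift = 2,
                              amplitude_threshold = 50,
                              trend_slope_threshold = 5,
                              step_threshold = 12)
  loose <- reject_artifacts(ep, cfg)
  tight <- reject_artifacts(ep, strict)
  expect_true(all(which(!loose$retained) %in% which(!tight$retained)))

  twice <- reject_artifacts(loose, cfg)
  expect_identical(twice$artifact_flags, loose$artifact_flags)
  expect_identical(twice$retained, loose$retained)
})

test_that("amplitude artifacts of twice the threshold are always caught; clean background rarely is", {
  set.seed(24)
  n_ep <- 200
  cfg <- preprocess_config(epoch_length = 2, epoch_shift = 2)
  # clean band-limited 1/f background, scaled to at most 50 uV peak
  x <- one_over_f(n_ep * 2 * FS)
  x <- x / max(abs(x)) * 50
  rec <- make_recording(rep(0, n_ep * 2 * FS), override = list(P3 = x))
  ep <- segment_epochs(rec, cfg)

  clean <- reject_artifacts(ep, cfg)
  expect_lt(mean(!clean$retained), 0.05)

  bad <- sort(sample(n_ep, 25))
  for (b in bad) ep$channels[["P3"]][b, 17] <- 200   # 2x the threshold
  flagged <- reject_artifacts(ep, cfg)
  expect_true(all(!flagged$retained[bad]))
  expect_true(all(vapply(flagged$artifact_flags[bad],
                         function(f) "amplitude" %in% f, TRUE)))
})
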