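test_that("identical spec and seed give bit-identical sessions", {
  spec <- simulation_spec(seed = 61)
  proto <- short_protocol()
  a <- simulate_session(spec, proto)
  b <- simulate_session(spec, proto)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth$blink_intervals,
                   b$ground_truth$blink_intervals)
  c <- simulate_session(simulation_spec(seed = 62), proto)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("protocol gaps and overlaps are refused", {
  bad <- data.frame(onset_s = c(0, 70), duration_s = c(60, 30),
                    label = c("eyes_closed",
                              "hour=Normal;road=Easy;lap=1"))
  expect_error(simulate_session(simulation_spec(), bad),
               "gaps or overlaps")
  expect_error(simulation_spec(hard_theta_gain = -1), "> 0")
})

test_that("the eyes-closed parietal spectrum peaks at the specified IAF", {
  for (iaf in c(9.5, 10.5)) {
    spec <- simulation_spec(iaf = iaf, seed = 63, blink_rate = 0,
                            artifact_rate = 0)
    sim <- simulate_session(spec, short_protocol())
    rec <- bandpass_filter(sim$recording)
    ep <- reject_artifacts(segment_epochs(rec, preprocess_config()))
    frame <- spectra_in_interval(compute_psd(ep), 0, 16)
    est <- estimate_iaf(frame)
    expect_lte(abs(est$iaf - iaf), 0.5)
  }
})

test_that("condition band-power ratios track the squared amplitude gains", {
  # background off so the source band power is measured directly
  spec <- simulation_spec(seed = 64, bg_rms = 0.01, blink_rate = 0,
                          artifact_rate = 0)
  proto <- data.frame(
    onset_s = c(0, 10, 70), duration_s = c(10, 60, 60),
    label = c("eyes_closed", "hour=Normal;road=Easy;lap=1",
              "hour=Normal;road=Hard;lap=1"))
  sim <- simulate_session(spec, proto)
  ep <- segment_epochs(sim$recording, preprocess_config())
  frame <- compute_psd(ep)
  src_bins <- which(frame$freqs >= spec$iaf - 5 &
                    frame$freqs <= spec$iaf - 3)
  fidx <- match(wl_montage()$frontal, frame$channel_labels)
  band_power <- function(lo, hi) {
    keep <- frame$start_times >= lo & frame$start_times + 2 <= hi
    mean(frame$psd[keep, fidx, src_bins])
  }
  ratio <- band_power(70, 130) / band_power(10, 70)
  expect_lt(abs(ratio - spec$hard_theta_gain^2) / spec$hard_theta_gain^2,
            0.10)

  # alpha decreases in the Hard segment (parietal, squared gain)
  a_bins <- which(frame$freqs >= spec$iaf - 1 & frame$freqs <= spec$iaf + 1)
  pidx <- match(wl_montage()$parietal, frame$channel_labels)
  alpha_power <- function(lo, hi) {
    keep <- frame$start_times >= lo & frame$start_times + 2 <= hi
    mean(frame$psd[keep, pidx, a_bins])
  }
  aratio <- alpha_power(70, 130) / alpha_power(10, 70)
  expect_lt(abs(aratio - spec$hard_alpha_gain^2) / spec$hard_alpha_gain^2,
            0.10)
})

test_that("band-power ratios tighten as segments lengthen", {
  err_at <- function(len, seed) {
    spec <- simulation_spec(seed = seed, bg_rms = 0.01, blink_rate = 0,
                            artifact_rate = 0)
    proto <- data.frame(
      onset_s = c(0, 10, 10 + len), duration_s = c(10, len, len),
      label = c("eyes_closed", "hour=Normal;road=Easy;lap=1",
                "hour=Normal;road=Hard;lap=1"))
    sim <- simulate_session(spec, proto)
    frame <- compute_psd(segment_epochs(sim$recording,
                                        preprocess_config()))
    bins <- which(frame$freqs >= spec$iaf - 5 &
                  frame$freqs <= spec$iaf - 3)
    fidx <- match(wl_montage()$frontal, frame$channel_labels)
    bp <- function(lo, hi) {
      keep <- frame$start_times >= lo & frame$start_times + 2 <= hi
      mean(frame$psd[keep, fidx, bins])
    }
    abs(bp(10 + len, 10 + 2 * len) / bp(10, 10 + len) -
          spec$hard_theta_gain^2)
  }
  seeds <- 71:75
  expect_lt(mean(vapply(seeds, function(s) err_at(120, s), 0)),
            mean(vapply(seeds, function(s) err_at(15, s), 0)))
})

test_that("every injected blink appears in the ground truth and is detected", {
  spec <- simulation_spec(seed = 66)
  sim <- simulate_session(spec, short_protocol())
  gt <- sim$ground_truth$blink_intervals
  expect_gt(nrow(gt), 10)
  det <- remove_blinks(bandpass_filter(sim$recording))$blink_intervals
  expect_equal(nrow(det), nrow(gt))
  covered <- vapply(seq_len(nrow(gt)), function(k) {
    any(det$start_s <= gt$start_s[k] + 0.05 &
        det$end_s >= gt$end_s[k] - 0.05)
  }, TRUE)
  expect_true(all(covered))
})

test_that("injected artifact epochs are flagged by the rejection rules", {
  spec <- simulation_spec(seed = 67, artifact_rate = 4)
  sim <- simulate_session(spec, short_protocol())
  cfg <- preprocess_config()
  ep <- reject_artifacts(
    segment_epochs(remove_blinks(bandpass_filter(sim$recording))$recording,
                   cfg), cfg)
  idx <- artifact_epoch_indices(sim$ground_truth, ep$start_times)
  expect_gt(length(idx), 0)
  expect_gt(mean(!ep$retained[idx]), 0.95)
})

test_that("simulated feature sets reach the closed-form Gaussian AUC", {
  # one informative feature, d = 3 -> Bayes AUC pnorm(3 / sqrt(2)) = 0.983
  train <- simulate_feature_set(200, 20, informative = 5, effects = 3,
                                seed = 68)
  test <- simulate_feature_set(200, 20, informative = 5, effects = 3,
                               seed = 69)
  m <- asswlda_fit(train)
  auc <- roc_auc(asswlda_score(m, test)$y, test$labels)
  expect_lt(abs(auc - pnorm(3 / sqrt(2))), 0.03)

  # zero effects: scores of an uninformative model stay at chance
  null_train <- simulate_feature_set(150, 20, seed = 70)
  null_test <- simulate_feature_set(150, 20, seed = 71)
  m0 <- asswlda_fit(null_train)
  auc0 <- roc_auc(asswlda_score(m0, null_test)$y, null_test$labels)
  expect_gt(auc0, 0.4); expect_lt(auc0, 0.6)

  expect_error(simulate_feature_set(10, 5, informative = 1,
                                    effects = c(1, 2)), "one entry per")
  expect_error(simulate_feature_set(10, 5, informative = 9, effects = 1),
               "exceed")
  expect_identical(simulate_feature_set(20, 5, seed = 3)$features,
                   simulate_feature_set(20, 5, seed = 3)$features)
})
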