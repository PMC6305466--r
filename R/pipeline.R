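# End-to-end workflow: configuration, calibration (training), scoring,
# and simulated-cohort validation.

#' Default pipeline configuration
#'
#' Bundles the module configurations with their standard defaults: 1-30 Hz
#' band-pass of order 4, 2-s epochs shifted by 0.125 s, 100 uV / 10 uV/s /
#' 25 uV artifact thresholds, 7-13 Hz IAF search with a 10 Hz fallback,
#' log10 PSD features, the stepwise settings of [stepwise_config()], an
#' 8-s workload window with minimum coverage 0.25, and 20 s / 10 s event
#' windows for Car / Pedestrian. The calibration classes are the Easy
#' segment of lap 2 in the Normal hour (class 0) and the Hard segment of
#' lap 2 in the Rush hour (class 1).
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    preprocess = preprocess_config(),
    spectral = list(iaf_search = c(7, 13), iaf_fallback = 10,
                    transform = "log10"),
    stepwise = stepwise_config(),
    evaluation = list(wl_window = 8, min_coverage = 0.25,
                      event_windows = c(Car = 20, Pedestrian = 10),
                      test_lap = 3),
    classes = list(class0 = list(hour = "Normal", road = "Easy", lap = 2),
                   class1 = list(hour = "Rush", road = "Hard", lap = 2))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror the module field names; unset keys keep
#' their defaults. Unknown keys raise an error naming the key.
#'
#' @param path YAML configuration path (NULL for pure defaults).
#' @return A validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  known <- names(cfg)
  bad <- setdiff(names(user), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  raw <- merge_config(lapply(cfg, function(x)
    if (inherits(x, c("wl_preprocess_config", "wl_stepwise_config")))
      unclass(x) else x), user)
  raw$preprocess <- do.call(preprocess_config, raw$preprocess)
  raw$stepwise <- do.call(stepwise_config, raw$stepwise)
  if (!is.null(user$evaluation$event_windows)) {
    raw$evaluation$event_windows <- unlist(user$evaluation$event_windows)
  }
  raw
}

#' Assign condition attributes to epochs
#'
#' An epoch belongs to a segment when its full `[start, start +
#' epoch_length]` span lies inside it.
#'
#' @param start_times Epoch start times, s.
#' @param epoch_length Epoch length, s.
#' @param annotations Annotation data frame.
#' @return Data frame with `hour`, `road`, `lap`, `baseline` per epoch
#'   (NA where unannotated).
#' @export
label_epochs <- function(start_times, epoch_length, annotations) {
  ann <- parse_annotations(annotations)
  hour <- road <- rep(NA_character_, length(start_times))
  lap <- rep(NA_integer_, length(start_times))
  baseline <- rep(FALSE, length(start_times))
  lo <- start_times; hi <- start_times + epoch_length
  for (k in seq_len(nrow(ann))) {
    if (!ann$type[k] %in% c("baseline", "condition")) next
    inside <- lo >= ann$onset_s[k] - 1e-9 &
              hi <= ann$onset_s[k] + ann$duration_s[k] + 1e-9
    if (ann$type[k] == "baseline") {
      baseline[inside] <- TRUE
    } else {
      hour[inside] <- ann$hour[k]
      road[inside] <- ann$road[k]
      lap[inside] <- ann$lap[k]
    }
  }
  data.frame(hour = hour, road = road, lap = lap, baseline = baseline)
}

#' Run the preprocessing and spectral chain once
#'
#' Filter, blink removal, epoching, artifact rejection and per-epoch PSD.
#' The result can be passed to both [wl_train()] and [wl_score()] so the
#' chain is not recomputed when a session is used for calibration and
#' testing.
#'
#' @param rec A `wl_recording` with annotations.
#' @param config Pipeline configuration.
#' @return A `wl_processed` list: `frame` (a `wl_spectra`), `epochs`,
#'   `blink_intervals`, `annotations`, `subject_id`.
#' @export
wl_process <- function(rec, config = default_config()) {
  if (inherits(rec, "wl_processed")) return(rec)
  validate_recording(rec, required_channels = wl_montage()$channels,
                     lowpass_cutoff = config$preprocess$lowpass_cutoff)
  if (is.null(rec$annotations)) {
    stop("the recording carries no annotations", call. = FALSE)
  }
  filt <- bandpass_filter(rec, config$preprocess)
  br <- remove_blinks(filt)
  ep <- segment_epochs(br$recording, config$preprocess)
  ep <- reject_artifacts(ep, config$preprocess)
  frame <- compute_psd(ep, max_freq = config$preprocess$lowpass_cutoff)
  structure(list(frame = frame, epochs = ep,
                 blink_intervals = br$blink_intervals,
                 annotations = rec$annotations,
                 subject_id = rec$subject_id),
            class = "wl_processed")
}

session_iaf <- function(frame, annotations, config) {
  ann <- parse_annotations(annotations)
  ec <- ann[ann$type == "baseline", , drop = FALSE]
  if (!nrow(ec)) {
    stop("no eyes-closed annotation: cannot estimate the IAF",
         call. = FALSE)
  }
  ec_frame <- spectra_in_interval(frame, ec$onset_s[1], ec$duration_s[1])
  estimate_iaf(ec_frame, search_range = config$spectral$iaf_search,
               fallback = config$spectral$iaf_fallback)
}

#' Train a workload model from an annotated recording
#'
#' Runs the full calibration chain: band-pass filter, blink removal,
#' epoching, artifact rejection, per-epoch PSD, IAF estimation from the
#' eyes-closed baseline, ROI feature extraction, and the stepwise
#' discriminant fit on the two calibration segments (by default Easy /
#' Normal lap 2 as class 0 and Hard / Rush lap 2 as class 1).
#'
#' @param rec A `wl_recording` with annotations attached, or a
#'   `wl_processed` object from [wl_process()].
#' @param config Pipeline configuration (see [default_config()]).
#' @return A `wl_model` with the session IAF embedded.
#' @export
wl_train <- function(rec, config = default_config()) {
  pp <- wl_process(rec, config)
  iaf <- session_iaf(pp$frame, pp$annotations, config)
  feats <- extract_roi_features(
    pp$frame, iaf, transform = config$spectral$transform,
    highpass_cutoff = config$preprocess$highpass_cutoff)
  lab <- label_epochs(feats$start_times, feats$epoch_length,
                      pp$annotations)
  cls <- function(spec) {
    !is.na(lab$hour) & lab$hour == spec$hour & lab$road == spec$road &
      lab$lap == spec$lap
  }
  is0 <- cls(config$classes$class0)
  is1 <- cls(config$classes$class1)
  if (!any(is0) || !any(is1)) {
    need <- c(
      if (!any(is0)) sprintf("hour=%s;road=%s;lap=%d",
                             config$classes$class0$hour,
                             config$classes$class0$road,
                             config$classes$class0$lap),
      if (!any(is1)) sprintf("hour=%s;road=%s;lap=%d",
                             config$classes$class1$hour,
                             config$classes$class1$road,
                             config$classes$class1$lap))
    stop("missing calibration segment(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  keep <- is0 | is1
  sub <- feats
  sub$features <- feats$features[keep, , drop = FALSE]
  sub$start_times <- feats$start_times[keep]
  sub$labels <- as.numeric(is1[keep])
  model <- asswlda_fit(sub, config = config$stepwise,
                       subject_id = pp$subject_id)
  model$blink_intervals <- pp$blink_intervals
  model
}

#' Score a recording with a trained model
#'
#' Applies the preprocessing chain, extracts features at the model's IAF,
#' evaluates the discriminant per retained epoch, and reduces it to the
#' workload index at the configured (8-s) time resolution. When the
#' annotations label the test lap, per-window condition labels and an
#' Easy-vs-Hard AUC report are attached.
#'
#' @param rec A `wl_recording` with annotations.
#' @param model A `wl_model` from [wl_train()].
#' @param config Pipeline configuration.
#' @return A list: `scores` (epoch-level `wl_scores`), `wl` (a
#'   `wl_series`), `auc` (pooled Easy-vs-Hard AUC on the test lap, NA if
#'   unavailable), `auc_by_hour`, `condition_means`.
#' @export
wl_score <- function(rec, model, config = default_config()) {
  pp <- wl_process(rec, config)
  transform <- if (!is.null(model$transform) && !is.na(model$transform)) {
    model$transform
  } else {
    config$spectral$transform
  }
  feats <- extract_roi_features(
    pp$frame, model$iaf, transform = transform,
    highpass_cutoff = config$preprocess$highpass_cutoff)
  scores <- asswlda_score(model, feats)
  wl <- workload_index(scores, window = config$evaluation$wl_window,
                       min_coverage = config$evaluation$min_coverage)
  lab <- label_series_windows(wl, pp$annotations,
                              lap = config$evaluation$test_lap)
  usable <- !is.na(wl$wl) & !is.na(lab$road)
  auc <- NA_real_
  auc_by_hour <- c(Normal = NA_real_, Rush = NA_real_)
  if (any(usable & lab$road == "Easy") &&
      any(usable & lab$road == "Hard")) {
    auc <- roc_auc(wl$wl[usable], as.numeric(lab$road[usable] == "Hard"))
    for (h in .hours) {
      uh <- usable & lab$hour == h
      if (any(uh & lab$road == "Easy") && any(uh & lab$road == "Hard")) {
        auc_by_hour[h] <- roc_auc(wl$wl[uh],
                                  as.numeric(lab$road[uh] == "Hard"))
      }
    }
  }
  cm <- suppressWarnings(
    aggregate_conditions(wl, pp$annotations,
                         lap = config$evaluation$test_lap,
                         event_windows = config$evaluation$event_windows))
  list(scores = scores, wl = wl, window_labels = lab, auc = auc,
       auc_by_hour = auc_by_hour, condition_means = cm)
}

#' Train, score and evaluate a simulated cohort
#'
#' Simulates `n_subjects` independent sessions (subject IAFs drawn on the
#' 0.5 Hz grid inside `iaf_range`), trains each subject's model on the
#' calibration segments, scores the test lap, and collects per-subject
#' validation metrics: test AUC (pooled and per hour), shuffled-label
#' baseline AUC, condition-ordering signs (Hard > Easy, Rush > Normal)
#' and the selected-feature count.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param n_shuffles Label shuffles per subject for the baseline.
#' @param config Pipeline configuration.
#' @param iaf_range IAF sampling range, Hz.
#' @param protocol Annotation plan for every subject.
#' @return Data frame with one row per subject.
#' @export
cohort_validation <- function(n_subjects = 16, seed = 1,
                              n_shuffles = 100,
                              config = default_config(),
                              iaf_range = c(9, 11),
                              protocol = default_protocol()) {
  iaf_grid <- seq(iaf_range[1], iaf_range[2], by = 0.5)
  iafs <- with_local_seed(seed,
                          sample(iaf_grid, n_subjects, replace = TRUE))
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    spec <- simulation_spec(subject_id = sprintf("sim%02d", s),
                            iaf = iafs[s],
                            seed = seed * 1000L + s)
    sim <- simulate_session(spec, protocol)
    model <- wl_train(sim$recording, config)
    res <- wl_score(sim$recording, model, config)
    lab <- res$window_labels
    usable <- !is.na(res$wl$wl) & !is.na(lab$road)
    shuf <- if (sum(usable) >= 4 &&
                length(unique(lab$road[usable])) == 2) {
      shuffled_baseline(res$wl$wl[usable],
                        as.numeric(lab$road[usable] == "Hard"),
                        n_shuffles = n_shuffles,
                        seed = seed * 1000L + s)$mean
    } else NA_real_
    cm <- res$condition_means
    mean_cell <- function(hour, road) {
      cm$mean_wl[cm$hour == hour & cm$road == road]
    }
    hard_mean <- mean(c(mean_cell("Normal", "Hard"),
                        mean_cell("Rush", "Hard")), na.rm = TRUE)
    easy_mean <- mean(c(mean_cell("Normal", "Easy"),
                        mean_cell("Rush", "Easy")), na.rm = TRUE)
    rush_mean <- mean(c(mean_cell("Rush", "Easy"),
                        mean_cell("Rush", "Hard")), na.rm = TRUE)
    normal_mean <- mean(c(mean_cell("Normal", "Easy"),
                          mean_cell("Normal", "Hard")), na.rm = TRUE)
    rows[[s]] <- data.frame(
      subject = spec$subject_id,
      iaf_true = iafs[s], iaf_est = model$iaf,
      n_features = nrow(model$selected_features),
      auc = res$auc,
      auc_normal = unname(res$auc_by_hour["Normal"]),
      auc_rush = unname(res$auc_by_hour["Rush"]),
      shuffled_mean_auc = shuf,
      hard_gt_easy = hard_mean > easy_mean,
      rush_gt_normal = rush_mean > normal_mean)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
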