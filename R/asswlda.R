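# Stepwise linear discriminant with automatic stopping (asSWLDA), epoch
# scoring and the 8-s moving-average workload index.

#' Stepwise training configuration
#'
#' Controls the forward-inclusion / backward-elimination stepwise
#' regression of the 0/1 class label on the spectral features and its
#' automatic stopping rule: training halts when no candidate reaches
#' `p_enter`, when the selection reaches `max_features`, or when the
#' held-out validation error has not improved for `val_patience`
#' consecutive steps (at which point the selection reverts to the best
#' validated step). Defaults favor the parsimonious models (a handful of
#' features per subject) this neurometric is known for.
#'
#' @param p_enter Partial-F p-value below which a candidate may enter.
#' @param p_remove Partial-F p-value above which a selected feature is
#'   removed.
#' @param max_features Hard cap on the number of selected features.
#' @param val_fraction Fraction of training epochs held out (stratified)
#'   for the validation stopping rule; 0 disables it.
#' @param val_patience Consecutive non-improving steps tolerated before
#'   stopping.
#' @param split_seed Seed of the validation split (fixed so that identical
#'   inputs give identical models).
#' @param min_epochs_per_class Minimum training epochs required per class.
#' @return A `wl_stepwise_config` list.
#' @export
stepwise_config <- function(p_enter = 0.05, p_remove = 0.10,
                            max_features = 10, val_fraction = 0.25,
                            val_patience = 2, split_seed = 101,
                            min_epochs_per_class = 10) {
  stopifnot(p_enter > 0, p_enter < 1, p_remove >= p_enter, p_remove <= 1,
            max_features >= 1, val_fraction >= 0, val_fraction < 1,
            val_patience >= 1, min_epochs_per_class >= 2)
  structure(list(p_enter = p_enter, p_remove = p_remove,
                 max_features = as.integer(max_features),
                 val_fraction = val_fraction,
                 val_patience = as.integer(val_patience),
                 split_seed = as.integer(split_seed),
                 min_epochs_per_class = as.integer(min_epochs_per_class)),
            class = "wl_stepwise_config")
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

ols_fit <- function(X, y, sel) {
  D <- cbind(`(bias)` = 1, X[, sel, drop = FALSE])
  fit <- stats::lm.fit(D, y)
  list(bias = unname(fit$coefficients[1]),
       weights = unname(fit$coefficients[-1]),
       residuals = fit$residuals)
}

#' Fit the stepwise linear discriminant with automatic stopping
#'
#' The discriminant is fitted as least-squares regression of the 0/1 class
#' label on the selected features (equivalent to the two-class LDA
#' direction up to affine scale), so the trained output takes the value 0
#' in the easiest condition and 1 in the hardest. Forward steps enter the
#' candidate with the smallest partial-F p-value (ties broken by the
#' canonical channel-major feature order); backward steps remove selected
#' features whose p-value exceeds `p_remove`. Stopping follows
#' [stepwise_config()]. The final weights and bias are the ordinary
#' least-squares solution on the full training set; with no selected
#' feature the model is bias-only with bias equal to the class-label mean.
#'
#' @param features A `wl_features` object or a numeric epoch x feature
#'   matrix.
#' @param labels 0/1 class labels per epoch (taken from
#'   `features$labels` when omitted).
#' @param config A [stepwise_config()].
#' @param subject_id Stored in the model metadata.
#' @return A `wl_model`: `selected_features` (ordered id data frame),
#'   `weights`, `bias`, `stepwise_trace`, `training_meta`.
#' @export
asswlda_fit <- function(features, labels = NULL,
                        config = stepwise_config(),
                        subject_id = NULL) {
  if (inherits(features, "wl_features")) {
    X <- features$features
    ids <- features$ids
    if (is.null(labels)) labels <- features$labels
    if (is.null(subject_id)) subject_id <- features$subject_id
  } else {
    X <- as.matrix(features)
    ids <- data.frame(channel = colnames(X),
                      freq_hz = NA_real_, band = NA_character_)
    if (is.null(ids$channel)) ids$channel <- paste0("f", seq_len(ncol(X)))
  }
  if (is.null(labels)) stop("class labels are required", call. = FALSE)
  y <- as.numeric(labels)
  if (length(y) != nrow(X)) stop("labels must match the epoch count",
                                 call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1", call. = FALSE)
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 == 0 || n1 == 0) {
    stop("both classes must be present in the training data",
         call. = FALSE)
  }
  if (min(n0, n1) < config$min_epochs_per_class) {
    stop("need at least ", config$min_epochs_per_class,
         " epochs per class (have ", n0, " / ", n1, ")", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)

  use_val <- config$val_fraction > 0 &&
    floor(min(n0, n1) * config$val_fraction) >= 2
  if (use_val) {
    val_idx <- with_local_seed(config$split_seed, {
      c(sample(which(y == 0), floor(n0 * config$val_fraction)),
        sample(which(y == 1), floor(n1 * config$val_fraction)))
    })
    tr_idx <- setdiff(seq_len(n), val_idx)
  }

  sel <- integer(0)
  trace <- list()
  snapshots <- list()
  val_hist <- numeric(0)
  best_val <- Inf; best_step <- 0L; since_best <- 0L
  stop_reason <- "exhausted"
  step <- 0L

  add_trace <- function(action, j, crit) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, action = action,
      feature = paste0(ids$channel[j], "@", ids$freq_hz[j]),
      feature_index = j, criterion = crit)
  }

  repeat {
    if (length(sel) >= config$max_features) {
      stop_reason <- "max_features"; break
    }
    cand <- setdiff(seq_len(p), sel)
    if (!length(cand)) { stop_reason <- "exhausted"; break }
    k <- length(sel)
    dfres <- n - k - 2L
    if (dfres < 1L) { stop_reason <- "df_exhausted"; break }
    qrD <- qr(cbind(1, X[, sel, drop = FALSE]))
    r <- qr.resid(qrD, y)
    Z <- qr.resid(qrD, X[, cand, drop = FALSE])
    zz <- colSums(Z^2)
    zr <- colSums(Z * r)
    rss0 <- sum(r^2)
    num <- ifelse(zz > 1e-10, zr^2 / zz, 0)
    rss1 <- pmax(rss0 - num, 0)
    Fst <- ifelse(rss1 > 0, num / (rss1 / dfres), Inf)
    pv <- stats::pf(Fst, 1, dfres, lower.tail = FALSE)
    pv[zz <= 1e-10] <- 1
    best <- which.min(pv)            # first minimum = lowest feature index
    if (!(pv[best] < config$p_enter)) { stop_reason <- "no_candidate"; break }
    j <- cand[best]
    step <- step + 1L
    sel <- c(sel, j)
    add_trace("enter", j, pv[best])

    # backward elimination (never the feature entered this step)
    repeat {
      if (length(sel) < 2L) break
      D <- cbind(1, X[, sel, drop = FALSE])
      qr2 <- qr(D)
      res <- qr.resid(qr2, y)
      df2 <- n - length(sel) - 1L
      if (df2 < 1L) break
      s2 <- sum(res^2) / df2
      R <- qr.R(qr2)
      XtXinv <- chol2inv(R)
      se <- sqrt(pmax(diag(XtXinv), 0) * s2)
      beta <- qr.coef(qr2, y)
      tt <- abs(beta[-1] / se[-1])
      prem <- 2 * stats::pt(tt, df2, lower.tail = FALSE)
      prem[!is.finite(prem)] <- 1
      removable <- which(prem > config$p_remove & sel != j)
      if (!length(removable)) break
      worst <- removable[which.max(prem[removable])]
      jr <- sel[worst]
      add_trace("remove", jr, prem[worst])
      sel <- sel[-worst]
    }

    snapshots[[step]] <- sel
    if (use_val) {
      fit <- ols_fit(X[tr_idx, , drop = FALSE], y[tr_idx], sel)
      pred <- as.vector(X[val_idx, sel, drop = FALSE] %*% fit$weights) +
        fit$bias
      mse <- mean((y[val_idx] - pred)^2)
      val_hist <- c(val_hist, mse)
      if (mse < best_val - 1e-12) {
        best_val <- mse; best_step <- step; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$val_patience) {
          sel <- snapshots[[best_step]]
          stop_reason <- "validation"
          break
        }
      }
    }
  }

  if (length(sel)) {
    fit <- ols_fit(X, y, sel)
    weights <- fit$weights; bias <- fit$bias
  } else {
    weights <- numeric(0); bias <- mean(y)
  }
  trace_df <- if (length(trace)) do.call(rbind, trace)
              else data.frame(step = integer(0), action = character(0),
                              feature = character(0),
                              feature_index = integer(0),
                              criterion = numeric(0))
  structure(
    list(selected_features = ids[sel, , drop = FALSE],
         weights = weights, bias = bias,
         stepwise_trace = trace_df,
         stop_reason = stop_reason,
         validation_mse = val_hist,
         iaf = if (inherits(features, "wl_features")) features$iaf
               else NA_real_,
         transform = if (inherits(features, "wl_features"))
                       features$transform else NA_character_,
         training_meta = list(subject_id = subject_id,
                              n_class0 = n0, n_class1 = n1,
                              config = unclass(config))),
    class = "wl_model")
}

#' @export
print.wl_model <- function(x, ...) {
  cat(sprintf("<wl_model> %d selected feature(s), bias %.4f (stop: %s)\n",
              nrow(x$selected_features), x$bias, x$stop_reason))
  if (nrow(x$selected_features)) {
    cat("  ", paste0(x$selected_features$channel, "@",
                     x$selected_features$freq_hz,
                     collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Score features with a trained workload model
#'
#' Evaluates the linear discriminant `y(t) = sum_i w_i f_i(t) + b` per
#' retained epoch. Values are not clipped to `[0, 1]`: the trained scale
#' makes easy tend to 0 and hard to 1, but clipping would bias the window
#' averages downstream.
#'
#' @param model A `wl_model`.
#' @param features A `wl_features` object (or matrix with matching
#'   columns); every selected feature id must be present, otherwise the
#'   missing id is named in the error.
#' @return A `wl_scores` list: `y`, `start_times`, `epoch_shift`.
#' @export
asswlda_score <- function(model, features) {
  stopifnot(inherits(model, "wl_model"))
  if (inherits(features, "wl_features")) {
    X <- features$features
    have <- paste0(features$ids$channel, "@", features$ids$freq_hz)
    start_times <- features$start_times
    epoch_shift <- features$epoch_shift
  } else {
    X <- as.matrix(features)
    have <- colnames(X)
    start_times <- seq_len(nrow(X)) - 1
    epoch_shift <- 1
  }
  sel <- model$selected_features
  if (nrow(sel)) {
    want <- paste0(sel$channel, "@", sel$freq_hz)
    cols <- match(want, have)
    if (anyNA(cols)) {
      stop("feature(s) required by the model are missing: ",
           paste(want[is.na(cols)], collapse = ", "), call. = FALSE)
    }
    y <- as.vector(X[, cols, drop = FALSE] %*% model$weights) + model$bias
  } else {
    y <- rep(model$bias, nrow(X))
  }
  structure(list(y = y, start_times = start_times,
                 epoch_shift = epoch_shift,
                 subject_id = model$training_meta$subject_id),
            class = "wl_scores")
}

#' Workload index: moving average of the discriminant output
#'
#' Averages the epoch-level discriminant values over consecutive windows
#' of `window` seconds (one output per window, i.e. 8-s time resolution by
#' default). Each output records its coverage — the fraction of expected
#' epochs actually retained in the window; outputs with coverage below
#' `min_coverage` are reported missing so sparse windows cannot
#' masquerade as full averages.
#'
#' @param scores A `wl_scores` object from [asswlda_score()].
#' @param window Averaging window length, s.
#' @param min_coverage Minimum fraction of expected epochs per window.
#' @return A `wl_series` data frame: `timestamp_s` (window center),
#'   `y_mean`, `wl` (NA below coverage), `coverage`, `n_epochs`.
#' @export
workload_index <- function(scores, window = 8, min_coverage = 0.25) {
  stopifnot(inherits(scores, "wl_scores"))
  if (window < scores$epoch_shift) {
    stop("window (", window, " s) must be at least one epoch shift (",
         scores$epoch_shift, " s)", call. = FALSE)
  }
  st <- scores$start_times
  t0 <- floor(min(st) / window) * window
  t1 <- max(st)
  edges <- seq(t0, t1 + window, by = window)
  expected <- window / scores$epoch_shift
  ks <- seq_len(length(edges) - 1L)
  out <- data.frame(timestamp_s = edges[ks] + window / 2,
                    y_mean = NA_real_, wl = NA_real_,
                    coverage = 0, n_epochs = 0L)
  for (k in ks) {
    inw <- st >= edges[k] - 1e-9 & st < edges[k + 1L] - 1e-9
    nk <- sum(inw)
    out$n_epochs[k] <- nk
    out$coverage[k] <- nk / expected
    if (nk > 0) out$y_mean[k] <- mean(scores$y[inw])
    if (out$coverage[k] >= min_coverage) out$wl[k] <- out$y_mean[k]
  }
  out <- out[out$n_epochs > 0 | (out$timestamp_s > min(st) &
                                 out$timestamp_s < t1), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "min_coverage") <- min_coverage
  attr(out, "subject_id") <- scores$subject_id
  class(out) <- c("wl_series", "data.frame")
  out
}

# Model serialization -----------------------------------------------------

#' Write a workload model to JSON
#' @param model A `wl_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "wl_model"))
  obj <- list(
    subject = model$training_meta$subject_id,
    iaf_hz = model$iaf,
    transform = model$transform,
    selected_features = model$selected_features,
    weights = model$weights,
    bias = model$bias,
    stop_reason = model$stop_reason,
    trace = model$stepwise_trace,
    validation_mse = model$validation_mse,
    config = model$training_meta$config,
    n_class0 = model$training_meta$n_class0,
    n_class1 = model$training_meta$n_class1)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Read a workload model from JSON
#' @param path Path written by [write_model()].
#' @return A `wl_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- as.data.frame(obj$selected_features)
  if (!nrow(sel)) sel <- data.frame(channel = character(0),
                                    freq_hz = numeric(0),
                                    band = character(0))
  cfg <- do.call(stepwise_config, obj$config)
  structure(
    list(selected_features = sel,
         weights = as.numeric(obj$weights),
         bias = obj$bias,
         stepwise_trace = as.data.frame(obj$trace),
         stop_reason = obj$stop_reason,
         validation_mse = as.numeric(obj$validation_mse),
         iaf = obj$iaf_hz,
         transform = obj$transform,
         training_meta = list(subject_id = obj$subject,
                              n_class0 = obj$n_class0,
                              n_class1 = obj$n_class1,
                              config = unclass(cfg))),
    class = "wl_model")
}
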