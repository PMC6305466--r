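# Evaluation battery: ROC-AUC with shuffled-label baseline, nonparametric
# paired tests with FDR correction, condition / event-window aggregation
# and NASA-TLX scoring.

#' Area under the ROC curve
#'
#' `AUC = P(score_1 > score_0) + P(tie) / 2`, computed from the rank-sum
#' (Mann-Whitney) identity; equal to the trapezoidal ROC area.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 class labels (class 1 expected to score higher).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1",
                                      call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n0 == 0 || n1 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Shuffled-label AUC baseline
#'
#' Recomputes the AUC under random permutations of the labels, the chance
#' reference the classifier must beat. The permutation null is centered at
#' 0.5 regardless of how separable the true scores are.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param n_shuffles Number of label permutations.
#' @param seed RNG seed (the global RNG state is restored afterwards).
#' @return A list with `auc` (vector of shuffled AUCs), `mean`, `sd`.
#' @export
shuffled_baseline <- function(scores, labels, n_shuffles = 100, seed = 1) {
  stopifnot(n_shuffles >= 1)
  labels <- as.numeric(labels)
  aucs <- with_local_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      roc_auc(scores, sample(labels))
    }, 0)
  })
  list(auc = aucs, mean = mean(aucs), sd = stats::sd(aucs))
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (standard practice). The exact null
#' distribution is used for n <= `exact_max` without ties in the absolute
#' differences; otherwise the normal approximation with continuity
#' correction applies.
#'
#' @param x First paired sample, or the differences when `y` is NULL.
#' @param y Optional second paired sample.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A list with `statistic` (V), `p_value`, `n` (pairs after zero
#'   removal), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero", call. = FALSE)
  if (n < 2) stop("need at least 2 nonzero differences", call. = FALSE)
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Friedman rank test for repeated measures
#'
#' Rank-based nonparametric analogue of the repeated-measures ANOVA,
#' applied to a complete subjects x conditions table.
#'
#' @param table Numeric matrix or data frame, one row per subject, one
#'   column per condition; no missing cells.
#' @return A list with `statistic` (Friedman chi-squared), `df`,
#'   `p_value`.
#' @export
friedman_rm_test <- function(table) {
  m <- as.matrix(table)
  if (anyNA(m)) stop("the subjects x conditions table has missing cells",
                     call. = FALSE)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  }
  # fully tied rows: every condition gets the same average rank, so the
  # statistic is 0 by definition (the tie correction otherwise yields 0/0)
  if (all(apply(m, 1, function(r) diff(range(r)) == 0))) {
    return(list(statistic = 0, df = ncol(m) - 1, p_value = 1))
  }
  ht <- stats::friedman.test(m)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter), p_value = ht$p.value)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted q-values; monotone nondecreasing in the sorted order
#' and never smaller than the raw p-values.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
fdr_correct <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Window labelling shared by the aggregation operations -------------------

label_series_windows <- function(wl, annotations, lap = NULL) {
  ann <- parse_annotations(annotations)
  cond <- ann[ann$type == "condition", , drop = FALSE]
  if (!is.null(lap)) cond <- cond[cond$lap %in% lap, , drop = FALSE]
  w <- attr(wl, "window")
  lo <- wl$timestamp_s - w / 2
  hi <- wl$timestamp_s + w / 2
  hour <- road <- rep(NA_character_, nrow(wl))
  lap_out <- rep(NA_integer_, nrow(wl))
  for (k in seq_len(nrow(cond))) {
    inside <- lo >= cond$onset_s[k] - 1e-9 &
              hi <= cond$onset_s[k] + cond$duration_s[k] + 1e-9
    hour[inside] <- cond$hour[k]
    road[inside] <- cond$road[k]
    lap_out[inside] <- cond$lap[k]
  }
  data.frame(hour = hour, road = road, lap = lap_out)
}

#' Per-condition workload means
#'
#' Averages the workload index over each (hour, road) cell, by default on
#' third-lap (testing) data only. A window contributes to a cell only when
#' it lies entirely inside one annotated segment. Event windows can be
#' excluded.
#'
#' @param wl A `wl_series` from [workload_index()].
#' @param annotations Annotation data frame covering the score timeline.
#' @param lap Lap(s) to aggregate (default 3, the testing lap).
#' @param exclude_events Drop windows overlapping annotated event windows.
#' @param event_windows Named event window lengths in seconds.
#' @return Data frame `hour`, `road`, `mean_wl`, `n_windows` (one row per
#'   cell; empty cells yield NA with a warning).
#' @export
aggregate_conditions <- function(wl, annotations, lap = 3,
                                 exclude_events = FALSE,
                                 event_windows = c(Car = 20,
                                                   Pedestrian = 10)) {
  stopifnot(inherits(wl, "wl_series"))
  lab <- label_series_windows(wl, annotations, lap = lap)
  keep <- !is.na(lab$hour) & !is.na(wl$wl)
  if (exclude_events) {
    ann <- parse_annotations(annotations)
    ev <- ann[ann$type == "event", , drop = FALSE]
    w <- attr(wl, "window")
    for (k in seq_len(nrow(ev))) {
      len <- event_windows[[ev$event[k]]]
      ov <- wl$timestamp_s + w / 2 > ev$onset_s[k] &
            wl$timestamp_s - w / 2 < ev$onset_s[k] + len
      keep <- keep & !ov
    }
  }
  cells <- expand.grid(hour = .hours, road = .roads,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$mean_wl <- NA_real_
  cells$n_windows <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- keep & lab$hour == cells$hour[i] & lab$road == cells$road[i]
    cells$n_windows[i] <- sum(sel, na.rm = TRUE)
    if (cells$n_windows[i] > 0) {
      cells$mean_wl[i] <- mean(wl$wl[which(sel)])
    }
  }
  empty <- cells[is.na(cells$mean_wl), , drop = FALSE]
  if (nrow(empty)) {
    warning("empty condition cell(s): ",
            paste(empty$hour, empty$road, sep = "/", collapse = ", "),
            call. = FALSE)
  }
  cells
}

#' Event-window vs matched no-event-window workload
#'
#' For each annotated event (third lap), averages the workload index over
#' a fixed window from the event onset (20 s for Car, 10 s for Pedestrian)
#' and over a matched window at the same circuit position of the previous
#' lap: the lap-2 segment with the same hour and road, at the same offset
#' from the segment start.
#'
#' @param wl A `wl_series`.
#' @param annotations Annotation data frame with event annotations.
#' @param event_windows Named window lengths per event type, s.
#' @return Data frame with one row per event: `position`, `event`, `hour`,
#'   `road`, `event_mean`, `matched_mean`, `n_event`, `n_matched`. Empty
#'   when no events are annotated.
#' @export
event_window_analysis <- function(wl, annotations,
                                  event_windows = c(Car = 20,
                                                    Pedestrian = 10)) {
  stopifnot(inherits(wl, "wl_series"))
  ann <- parse_annotations(annotations)
  ev <- ann[ann$type == "event", , drop = FALSE]
  out <- data.frame(position = character(0), event = character(0),
                    hour = character(0), road = character(0),
                    event_mean = numeric(0), matched_mean = numeric(0),
                    n_event = integer(0), n_matched = integer(0))
  if (!nrow(ev)) return(out)
  cond <- ann[ann$type == "condition", , drop = FALSE]
  win_mean <- function(start, len) {
    sel <- wl$timestamp_s >= start - 1e-9 &
           wl$timestamp_s <= start + len + 1e-9 & !is.na(wl$wl)
    list(mean = if (any(sel)) mean(wl$wl[sel]) else NA_real_,
         n = sum(sel))
  }
  for (k in seq_len(nrow(ev))) {
    len <- event_windows[[ev$event[k]]]
    host <- cond[cond$onset_s <= ev$onset_s[k] + 1e-9 &
                 cond$onset_s + cond$duration_s >= ev$onset_s[k] - 1e-9, ,
                 drop = FALSE]
    if (!nrow(host)) {
      stop("event '", ev$label[k],
           "' does not fall inside any condition segment", call. = FALSE)
    }
    host <- host[1, ]
    match_seg <- cond[cond$hour == host$hour & cond$road == host$road &
                      cond$lap == host$lap - 1L, , drop = FALSE]
    if (!nrow(match_seg)) {
      stop("no previous-lap segment to match event '", ev$label[k],
           "' (", host$hour, "/", host$road, " lap ", host$lap - 1L, ")",
           call. = FALSE)
    }
    offset <- ev$onset_s[k] - host$onset_s
    e <- win_mean(ev$onset_s[k], len)
    m <- win_mean(match_seg$onset_s[1] + offset, len)
    out <- rbind(out, data.frame(
      position = ev$position[k], event = ev$event[k],
      hour = host$hour, road = host$road,
      event_mean = e$mean, matched_mean = m$mean,
      n_event = e$n, n_matched = m$n))
  }
  rownames(out) <- NULL
  out
}

#' NASA Task Load Index score
#'
#' Six workload factors are rated on 0-100 scales; 15 pairwise comparisons
#' (every unordered factor pair once) determine per-factor weights as win
#' counts (summing to 15). The score is the weighted mean
#' `sum(rating * weight) / 15`, on a 0-100 scale.
#'
#' @param ratings Named numeric vector of six ratings in `[0, 100]`.
#' @param choices Data frame with columns `factor_a`, `factor_b`, `winner`
#'   covering all 15 pairs, `winner` equal to one of the pair.
#' @return A list with `score`, `weights` (named, sum 15).
#' @export
nasa_tlx_score <- function(ratings, choices) {
  if (length(ratings) != 6 || is.null(names(ratings))) {
    stop("`ratings` must be a named vector of six values", call. = FALSE)
  }
  if (any(ratings < 0) || any(ratings > 100)) {
    stop("ratings must lie in [0, 100]", call. = FALSE)
  }
  factors <- names(ratings)
  choices <- as.data.frame(choices)
  need <- c("factor_a", "factor_b", "winner")
  if (!all(need %in% names(choices))) {
    stop("`choices` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(choices) != 15) {
    stop("exactly 15 pairwise comparisons are required (got ",
         nrow(choices), ")", call. = FALSE)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  want <- utils::combn(factors, 2)
  want_keys <- key(want[1, ], want[2, ])
  got_keys <- key(choices$factor_a, choices$factor_b)
  if (!setequal(want_keys, got_keys) || anyDuplicated(got_keys)) {
    stop("choices must cover every unordered factor pair exactly once",
         call. = FALSE)
  }
  ok <- choices$winner == choices$factor_a |
        choices$winner == choices$factor_b
  if (!all(ok)) {
    stop("each winner must be one of the compared factors (rows ",
         paste(which(!ok), collapse = ", "), ")", call. = FALSE)
  }
  weights <- table(factor(choices$winner, levels = factors))
  score <- sum(ratings[factors] * as.numeric(weights)) / 15
  list(score = score, weights = stats::setNames(as.numeric(weights),
                                                factors))
}
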