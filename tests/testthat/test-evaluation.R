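test_that("AUC handles separation, ties, and the four-pair worked case", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals brute-force pair counting on random inputs", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(rnorm(n), 1))   # rounding induces ties
    expect_equal(roc_auc(scores, labels),
                 auc_bruteforce(scores, labels))
  }
})

test_that("the shuffled-label baseline is centered at 0.5 and reproducible", {
  set.seed(52)
  scores <- rnorm(60)
  labels <- rep(c(0, 1), 30)
  sb <- shuffled_baseline(scores, labels, n_shuffles = 1000, seed = 9)
  expect_gt(sb$mean, 0.48); expect_lt(sb$mean, 0.52)

  # permutation invariance: perfectly separated scores still center at 0.5
  sep <- c(rnorm(30), rnorm(30) + 10)
  sep_lab <- rep(c(0, 1), each = 30)
  expect_equal(roc_auc(sep, sep_lab), 1)
  sb2 <- shuffled_baseline(sep, sep_lab, n_shuffles = 1000, seed = 9)
  expect_gt(sb2$mean, 0.48); expect_lt(sb2$mean, 0.52)

  one <- shuffled_baseline(scores, labels, n_shuffles = 1, seed = 3)
  expect_identical(one$auc,
                   shuffled_baseline(scores, labels, 1, seed = 3)$auc)
})

test_that("signed-rank test: exact worked case, tie symmetry, zero handling", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r$p_value, 0.0625)
  expect_equal(r$statistic, 15)
  expect_equal(r$method, "exact")

  sym <- wilcoxon_signed_rank(c(-2, -1, 1, 2))
  expect_equal(sym$p_value, 1)

  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
  # zero differences are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5))$n, 5)
})

test_that("signed-rank exact p matches full sign-pattern enumeration", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n, 0.3), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcoxon_exact_bruteforce(d), tolerance = 1e-12)
  }
})

test_that("Friedman test: degenerate table, maximal ordering, rank oracle", {
  flat <- matrix(3, 8, 4)
  r <- friedman_rm_test(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # all 16 subjects rank 4 conditions identically -> n (k - 1) = 48
  ordered <- matrix(rep(1:4, each = 16), 16, 4) + matrix(rnorm(64, sd = 1e-6), 16)
  r <- friedman_rm_test(ordered)
  expect_equal(r$statistic, 48, tolerance = 1e-6)
  expect_equal(r$statistic, friedman_bruteforce(ordered),
               tolerance = 1e-6)

  set.seed(54)
  for (rep in 1:10) {
    m <- matrix(rnorm(5 * 4), 5, 4)
    expect_equal(friedman_rm_test(m)$statistic, friedman_bruteforce(m),
                 tolerance = 1e-10)
  }

  expect_error(friedman_rm_test(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(friedman_rm_test(matrix(1:3, 1)), "at least 2")
})

test_that("both nonparametric tests keep their nominal type-I error", {
  set.seed(55)
  n_rep <- 1000
  wil <- vapply(seq_len(n_rep), function(i) {
    wilcoxon_signed_rank(rnorm(16))$p_value
  }, 0)
  expect_gt(mean(wil < 0.05), 0.03)
  expect_lt(mean(wil < 0.05), 0.07)

  fri <- vapply(seq_len(n_rep), function(i) {
    friedman_rm_test(matrix(rnorm(16 * 4), 16, 4))$p_value
  }, 0)
  expect_gt(mean(fri < 0.05), 0.03)
  expect_lt(mean(fri < 0.05), 0.07)
})

test_that("Benjamini-Hochberg reproduces the three-test worked example", {
  expect_equal(fdr_correct(c(0.0005, 0.01, 0.64)),
               c(0.0015, 0.015, 0.64))
  expect_equal(fdr_correct(0.2), 0.2)
  expect_error(fdr_correct(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("q-values dominate p-values and match a direct step-up oracle", {
  step_up <- function(p) {          # independent BH implementation
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(56)
  for (rep in 1:20) {
    p <- runif(sample(1:12, 1))
    q <- fdr_correct(p)
    expect_equal(q, step_up(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p order
  }
  # constant vectors (and any single value) are fixed points of the
  # step-up adjustment
  expect_equal(fdr_correct(rep(0.2, 5)), rep(0.2, 5))
})

protocol_ann <- default_protocol()

test_that("condition aggregation averages full windows per hour x road cell", {
  ts <- seq(4, 536, by = 8)
  wl <- make_series(ts, rep(0.7, length(ts)))
  cells <- aggregate_conditions(wl, protocol_ann)
  expect_equal(cells$mean_wl, rep(0.7, 4))
  expect_true(all(cells$n_windows > 0))

  # knock out one cell's whole span (Normal/Easy lap 3: 220-260 s)
  wl2 <- wl
  wl2$wl[wl2$timestamp_s > 220 & wl2$timestamp_s < 260] <- NA
  expect_warning(cells2 <- aggregate_conditions(wl2, protocol_ann),
                 "Normal/Easy")
  expect_true(is.na(cells2$mean_wl[cells2$hour == "Normal" &
                                   cells2$road == "Easy"]))
  expect_equal(cells2$mean_wl[cells2$hour == "Rush" &
                              cells2$road == "Hard"], 0.7)
})

test_that("event windows recover an injected workload elevation exactly", {
  ts <- seq(4, 536, by = 8)
  base <- rep(0.4, length(ts))
  ann <- parse_annotations(protocol_ann)
  ev <- ann[ann$type == "event", ]
  lens <- c(Car = 20, Pedestrian = 10)
  elevated <- base
  for (k in seq_len(nrow(ev))) {
    inw <- ts >= ev$onset_s[k] & ts <= ev$onset_s[k] + lens[[ev$event[k]]]
    elevated[inw] <- 0.7
  }
  wl <- make_series(ts, elevated)
  res <- event_window_analysis(wl, protocol_ann)
  expect_equal(nrow(res), 4)                       # 2 events x 2 hours
  expect_setequal(unique(res$event), c("Pedestrian", "Car"))
  expect_equal(res$event_mean - res$matched_mean, rep(0.3, 4))
  # a 20-s car window can never hold fewer 8-s points than a 10-s one
  expect_true(all(res$n_event[res$event == "Car"] >=
                  res$n_event[res$event == "Pedestrian"]))
  expect_true(all(res$n_event > 0) && all(res$n_matched > 0))
})

test_that("no annotated events yield an empty result, not an error", {
  ts <- seq(4, 100, by = 8)
  wl <- make_series(ts, rep(0.5, length(ts)))
  ann <- data.frame(onset_s = 0, duration_s = 104,
                    label = "hour=Normal;road=Easy;lap=1")
  expect_equal(nrow(event_window_analysis(wl, ann)), 0)
})

test_that("events without a previous-lap match are reported", {
  ts <- seq(4, 100, by = 8)
  wl <- make_series(ts, rep(0.5, length(ts)))
  ann <- data.frame(
    onset_s = c(0, 10), duration_s = c(104, 10),
    label = c("hour=Normal;road=Easy;lap=3",
              "event=Pedestrian;position=p9"))
  expect_error(event_window_analysis(wl, ann), "no previous-lap")
})

tlx_factors <- c("Mental", "Physical", "Temporal", "Performance",
                 "Effort", "Frustration")

tlx_choices <- function(winner_fun) {
  pairs <- t(utils::combn(tlx_factors, 2))
  data.frame(factor_a = pairs[, 1], factor_b = pairs[, 2],
             winner = apply(pairs, 1, winner_fun))
}

test_that("NASA-TLX weighting reproduces the hand-computed example", {
  # winner = earlier factor in the list -> weights 5,4,3,2,1,0
  ch <- tlx_choices(function(p) {
    p[which.min(match(p, tlx_factors))]
  })
  ratings <- stats::setNames(c(100, 80, 60, 40, 20, 0), tlx_factors)
  r <- nasa_tlx_score(ratings, ch)
  expect_equal(r$weights, stats::setNames(c(5, 4, 3, 2, 1, 0),
                                          tlx_factors))
  expect_equal(r$score, 1100 / 15, tolerance = 1e-10)

  expect_equal(nasa_tlx_score(stats::setNames(rep(100, 6), tlx_factors),
                              ch)$score, 100)
  expect_equal(nasa_tlx_score(stats::setNames(rep(0, 6), tlx_factors),
                              ch)$score, 0)
})

test_that("NASA-TLX input validation catches incomplete or bad choices", {
  ch <- tlx_choices(function(p) p[1])
  ratings <- stats::setNames(rep(50, 6), tlx_factors)
  expect_error(nasa_tlx_score(ratings, ch[-1, ]), "15")
  dup <- ch; dup$factor_b[2] <- dup$factor_b[1]; dup$factor_a[2] <- dup$factor_a[1]
  expect_error(nasa_tlx_score(ratings, dup), "exactly once")
  bad <- ch; bad$winner[3] <- "Sleepiness"
  expect_error(nasa_tlx_score(ratings, bad), "one of the compared")
  expect_error(nasa_tlx_score(stats::setNames(c(rep(50, 5), 150),
                                              tlx_factors), ch),
               "\\[0, 100\\]")
})
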