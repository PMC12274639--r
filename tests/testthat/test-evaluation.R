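test_that("merged-class confusion counts enumerate correctly", {
  cm <- window_confusion(c("2", "0", "1", "0"), c("1", "2", "0", "0"))
  expect_equal(unclass(cm)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))

  truth <- c("0", "1", "2", "0", "excluded")
  cm2 <- window_confusion(truth, truth)
  expect_equal(cm2$FP + cm2$FN, 0L)
  expect_equal(cm2$TP + cm2$TN, 4L)   # excluded dropped

  cm3 <- window_confusion(rep("0", 4), c("1", "2", "0", "0"))
  expect_equal(cm3$TP + cm3$FP, 0L)

  expect_error(window_confusion("0", c("0", "1")), class = "hf_data_error")
})

test_that("merging classes before or after counting is equivalent", {
  set.seed(77)
  for (i in 1:20) {
    truth <- sample(c("0", "1", "2", "excluded"), 200, replace = TRUE)
    pred <- sample(c("0", "1", "2"), 200, replace = TRUE)
    a <- window_confusion(pred, truth)
    pre_merged_pred <- ifelse(pred == "0", "0", "1")
    pre_merged_truth <- ifelse(truth == "excluded", "excluded",
                               ifelse(truth == "0", "0", "1"))
    b <- window_confusion(pre_merged_pred, pre_merged_truth)
    expect_identical(unclass(a), unclass(b))
  }
})

test_that("window metrics reproduce the hand-computed fixture", {
  cm <- structure(list(TP = 8L, FP = 2L, FN = 4L, TN = 86L),
                  class = "hf_confusion")
  m <- window_metrics(cm)
  expect_equal(m$Sens, 8 / 12)
  expect_equal(m$Spec, 86 / 88)
  expect_equal(m$PPV, 0.8)
  expect_equal(m$NPV, 86 / 90)
  expect_equal(m$F1, 16 / 22)
  expect_equal(round(c(m$Sens, m$Spec, m$PPV, m$NPV, m$F1), 5),
               c(0.66667, 0.97727, 0.80000, 0.95556, 0.72727))

  # predictivity: 9 of 12 true Class 1 windows called HF
  m2 <- window_metrics(cm, class1_pred = c(rep("1", 6), rep("2", 3),
                                           rep("0", 3)))
  expect_equal(m2$Pred, 0.75)
})

test_that("zero denominators are reported absent, never zero", {
  cm <- structure(list(TP = 0L, FP = 0L, FN = 0L, TN = 10L),
                  class = "hf_confusion")
  m <- window_metrics(cm)
  expect_true(is.na(m$Sens))
  expect_true(is.na(m$PPV))
  expect_equal(m$Spec, 1)
  expect_true(is.na(window_metrics(cm, class1_pred = character(0))$Pred))
})

test_that("F1 equals the harmonic mean of PPV and sensitivity", {
  set.seed(55)
  for (i in 1:50) {
    cm <- structure(as.list(stats::setNames(rpois(4, 20) + 1L,
                                            c("TP", "FP", "FN", "TN"))),
                    class = "hf_confusion")
    m <- window_metrics(cm)
    expect_equal(m$F1, 2 / (1 / m$PPV + 1 / m$Sens), tolerance = 1e-12)
  }
})

test_that("event outcomes match the worked latency fixture", {
  # two events; first positives 58 s before one onset and 5 s after the other
  ends <- sort(c(seq(0, 2000, by = 5), 442, 1005))
  pred <- ifelse(ends %in% c(442, 1005), "1", "0")
  oc <- event_outcomes(pred, ends, c(500, 1000))
  expect_equal(oc$outcome, c("predicted", "detected"))
  expect_equal(oc$latency_s, c(-58, 5))
})

test_that("only the first identification counts and misses are explicit", {
  ends <- c(940, 980, 990, 1005, 1500)
  pred <- c("0", "1", "1", "2", "0")
  oc <- event_outcomes(pred, ends, 1000)
  expect_equal(oc$outcome, "predicted")
  expect_equal(oc$latency_s, -20)

  oc2 <- event_outcomes(rep("0", 5), ends, 1000)
  expect_equal(oc2$outcome, "missed")
  expect_true(is.na(oc2$latency_s))

  # positives outside [-60, +30] never identify the event
  oc3 <- event_outcomes(c("1", "0", "1"), c(935, 990, 1035), 1000)
  expect_equal(oc3$outcome, "missed")
  # the candidate interval is closed at both ends
  oc4 <- event_outcomes(c("1", "0"), c(940, 990), 1000)
  expect_equal(oc4$latency_s, -60)
  oc5 <- event_outcomes(c("0", "1"), c(990, 1030), 1000)
  expect_equal(oc5$outcome, "detected")
})

test_that("a shared positive window goes to the nearer onset", {
  # positive at 1030 is a candidate for both onsets; 1000 is nearer
  oc <- event_outcomes("1", 1030, c(1000, 1080))
  expect_equal(oc$outcome, c("detected", "missed"))
  expect_equal(oc$latency_s, c(30, NA_real_))
  # at 1045 only the 1080 interval holds it, despite 1000 being barely farther
  oc2 <- event_outcomes("1", 1045, c(1000, 1080))
  expect_equal(oc2$outcome, c("missed", "predicted"))
  expect_equal(oc2$latency_s, c(NA_real_, -35))
})

test_that("event matching agrees with brute-force enumeration", {
  set.seed(404)
  for (i in 1:50) {
    onsets <- sort(sample(seq(300, 6900, by = 1),
                          sample(1:6, 1)))
    onsets <- onsets[c(TRUE, diff(onsets) > 120)]
    ends <- seq(59, 7199, by = 5)
    pred <- sample(c("0", "1"), length(ends), replace = TRUE,
                   prob = c(0.97, 0.03))
    got <- event_outcomes(pred, ends, onsets)
    want <- oracle_outcomes(ends[pred == "1"], onsets)
    expect_equal(got$outcome, want$outcome)
    expect_equal(got$latency_s, want$latency_s)
  }
})

test_that("session metrics combine window and event measures", {
  # 4 events: predicted(-58), detected(+5), missed, predicted(-20)
  onsets <- c(1000, 3000, 5000, 7000)
  ends <- sort(c(seq(59, 7500, by = 500), 942, 3005, 6980))
  pred <- ifelse(ends %in% c(942, 3005, 6980), "1", "0")
  truth <- rep("0", length(ends))
  sm <- session_metrics(pred, truth, ends, onsets, session_id = "S")
  expect_equal(sm$PR, 0.5)
  expect_equal(sm$IR, 0.75)
  expect_equal(sm$IL, (-58 + 5 - 20) / 3, tolerance = 1e-9)
  expect_equal(round(sm$IL, 2), -24.33)
  expect_equal(sm$n_events, 4L)

  sm0 <- session_metrics(rep("0", 3), rep("0", 3), c(100, 200, 300),
                         numeric(0))
  expect_true(is.na(sm0$PR) && is.na(sm0$IR) && is.na(sm0$IL))
})

test_that("all-missed sessions report zero rates and absent latency", {
  sm <- session_metrics(rep("0", 10), rep("0", 10),
                        seq(100, 1000, by = 100), c(450, 900))
  expect_equal(sm$PR, 0)
  expect_equal(sm$IR, 0)
  expect_true(is.na(sm$IL))
})

test_that("aggregation averages sessions and excludes event-free ones", {
  s1 <- session_metrics(c("1", "0"), c("1", "0"), c(950, 1500), 1000, "a")
  s2 <- session_metrics(c("0", "0"), c("1", "0"), c(950, 1500), 1000, "b")
  s3 <- session_metrics(c("0", "0"), c("0", "0"), c(100, 200), numeric(0), "c")
  agg <- aggregate_sessions(list(s1, s2, s3))
  pr <- agg[agg$measure == "PR", ]
  expect_equal(pr$mean, 0.5)        # sessions a (1.0) and b (0.0)
  expect_equal(pr$n_sessions, 2L)   # event-free session c excluded
  expect_error(aggregate_sessions(list()), class = "hf_data_error")
})

test_that("identification rate bounds prediction rate on random sessions", {
  set.seed(71)
  for (i in 1:25) {
    onsets <- sort(sample(seq(500, 6500, by = 500), 4))
    ends <- seq(59, 7199, by = 5)
    pred <- sample(c("0", "1", "2"), length(ends), replace = TRUE,
                   prob = c(0.9, 0.05, 0.05))
    sm <- session_metrics(pred, rep("0", length(ends)), ends, onsets)
    expect_gte(sm$IR, sm$PR)
    expect_true(sm$PR >= 0 && sm$IR <= 1)
  }
})

test_that("the threshold detector fires on the classical criterion", {
  # ramp 0 -> 2.5 uS over 25 s then plateau: exactly one detection
  v <- c(seq(0, 2.5, length.out = 26), rep(2.5, 200))
  expect_length(freedman_detect(mk_trace(v + 1)), 1L)

  # 1.5 uS rise over 30 s: below threshold
  v2 <- c(seq(0, 1.5, length.out = 31), rep(1.5, 100))
  expect_length(freedman_detect(mk_trace(v2)), 0L)

  # 2 uS over 60 s: the 30-s increment never reaches 2
  v3 <- c(seq(0, 2, length.out = 61), rep(2, 100))
  expect_length(freedman_detect(mk_trace(v3)), 0L)
})

test_that("the threshold detector is offset-invariant and refractory", {
  v <- c(rep(0, 50), seq(0, 3, length.out = 21), rep(3, 150))
  d0 <- freedman_detect(mk_trace(v))
  d5 <- freedman_detect(mk_trace(v + 5))
  expect_identical(d0, d5)
  expect_length(d0, 1L)

  # two fast spikes ~43 s apart collapse to one under the 60 s refractory
  up <- seq(0, 3.2, length.out = 11)
  down <- seq(3.2, 0, length.out = 16)[-1]
  v2 <- c(rep(0, 40), up, down, rep(0, 14), up, down, rep(0, 100))
  expect_length(freedman_detect(mk_trace(v2)), 1L)
  expect_length(freedman_detect(mk_trace(v2), refractory_s = 30), 2L)
})
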