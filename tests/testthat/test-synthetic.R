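test_that("sessions are fully determined by the seed", {
  cfg <- synth_config(duration_h = 2, event_rate_per_h = 2, seed = 42)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$trace$sc_uS, b$trace$sc_uS)
  expect_identical(a$true_events, b$true_events)
  expect_identical(a$perceived_markers, b$perceived_markers)
  c <- simulate_session(synth_config(duration_h = 2, event_rate_per_h = 2,
                                     seed = 43))
  expect_false(identical(a$trace$sc_uS, c$trace$sc_uS))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(simulate_session(synth_config(duration_h = 1, seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("a clean single event reaches exactly its amplitude", {
  cfg <- clean_config(duration_h = 2, event_rate_per_h = 0.6,
                      amplitude_range_uS = c(3, 3), seed = 11)
  s <- simulate_session(cfg)
  ev <- confirmed_events(s$true_events)
  expect_gte(nrow(ev), 1L)
  expect_equal(max(s$trace$sc_uS) - cfg$baseline_uS, 3, tolerance = 1e-6)
})

test_that("a zero event rate gives a flat-plus-noise trace with no events", {
  s <- simulate_session(synth_config(duration_h = 1, event_rate_per_h = 0,
                                     scr_rate_per_h = 0,
                                     night_sweat_rate_per_h = 0,
                                     artifact_rate_per_h = 0, seed = 5))
  expect_equal(nrow(s$true_events), 0L)
  expect_lt(diff(range(s$trace$sc_uS)), 1)
})

test_that("infeasible event rates are rejected", {
  expect_error(synth_config(event_rate_per_h = 10, refractory_s = 480),
               class = "hf_data_error")
})

test_that("inter-event gaps respect the refractory period", {
  cfg <- synth_config(duration_h = 24, event_rate_per_h = 2, seed = 20)
  s <- simulate_session(cfg)
  on <- confirmed_events(s$true_events)$onset_s
  expect_gte(min(diff(on)), cfg$refractory_s)
})

test_that("perceived markers are a delayed subset of true events", {
  cfg <- synth_config(duration_h = 24, event_rate_per_h = 2, seed = 8)
  s <- simulate_session(cfg)
  mk <- s$perceived_markers
  on <- confirmed_events(s$true_events)$onset_s
  expect_lt(nrow(mk), length(on))
  # every marker lags its own event by (0, 60] seconds
  gap <- vapply(mk$onset_s, function(m) m - max(on[on <= m]), 0)
  expect_true(all(gap > 0 & gap <= 60))
})

test_that("atypical sessions sit higher and spike lower than typical ones", {
  t_cfg <- clean_config(duration_h = 4, event_rate_per_h = 2,
                        pattern = "typical", seed = 12)
  a_cfg <- clean_config(duration_h = 4, event_rate_per_h = 2,
                        pattern = "atypical", seed = 12)
  ts <- simulate_session(t_cfg)
  as_ <- simulate_session(a_cfg)
  expect_gt(stats::median(as_$trace$sc_uS), stats::median(ts$trace$sc_uS))
  amp <- function(s) max(s$trace$sc_uS) - stats::median(s$trace$sc_uS)
  expect_lt(amp(as_), amp(ts))
})

test_that("the classical detector fires on strong events and not weak ones", {
  strong <- clean_config(duration_h = 50, event_rate_per_h = 4,
                         amplitude_range_uS = c(2.5, 8),
                         rise_s_range = c(10, 25), seed = 99)
  s <- simulate_session(strong)
  on <- confirmed_events(s$true_events)$onset_s
  expect_gte(length(on), 100L)
  det <- freedman_detect(s$trace)
  hit <- vapply(on, function(o) any(det >= o - 60 & det <= o + 30), TRUE)
  expect_true(all(hit))

  weak <- clean_config(duration_h = 50, event_rate_per_h = 4,
                       amplitude_range_uS = c(0.5, 1.5),
                       rise_s_range = c(10, 25), seed = 98)
  s2 <- simulate_session(weak)
  expect_gte(nrow(s2$true_events), 100L)
  expect_length(freedman_detect(s2$trace), 0L)
})

test_that("cohorts share traits within participant and balance patterns", {
  cfg <- synth_config(duration_h = 1, seed = 2)
  co <- simulate_cohort(cfg, n_participants = 10, visits_per_participant = 3)
  expect_length(co$sessions, 30L)
  expect_equal(sum(co$participants$pattern == "typical"), 5L)
  pat <- vapply(co$sessions, function(s) s$config$pattern, "")
  pid <- vapply(co$sessions, function(s) s$trace$participant_id, "")
  for (p in unique(pid)) {
    expect_length(unique(pat[pid == p]), 1L)
  }
  base <- vapply(co$sessions, function(s) s$config$baseline_uS, 0)
  for (p in unique(pid)) {
    expect_length(unique(base[pid == p]), 1L)
  }
})

test_that("32 Hz generation downsamples to a coherent 1 Hz trace", {
  cfg <- clean_config(duration_h = 0.2, event_rate_per_h = 4,
                      sampling_rate_hz = 32, seed = 31)
  s <- simulate_session(cfg)
  expect_equal(s$trace$sampling_rate_hz, 32)
  d <- downsample_to_1hz(s$trace)
  expect_equal(d$sampling_rate_hz, 1)
  expect_equal(length(d), 720L)
  # block means preserve the event peak to within the within-second slope
  expect_equal(max(d$sc_uS), max(s$trace$sc_uS), tolerance = 0.1)
})

test_that("session files round-trip through the writer", {
  s <- simulate_session(synth_config(duration_h = 0.5, event_rate_per_h = 4,
                                     seed = 77))
  dir <- withr::local_tempdir()
  write_synth_session(s, dir)
  expect_true(all(file.exists(file.path(dir, c("trace.csv", "events.csv",
                                               "markers.csv", "mask.csv",
                                               "manifest.json")))))
  back <- read_sc_trace(file.path(dir, "trace.csv"), 1)
  expect_equal(back$sc_uS, s$trace$sc_uS, tolerance = 1e-9)
  ev <- read_hf_events(file.path(dir, "events.csv"))
  expect_equal(ev$onset_s, s$true_events$onset_s)
})
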