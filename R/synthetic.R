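#' Configuration for the synthetic skin-conductance generator
#'
#' Defines the study conditions the generator emulates: ambulatory 48-h
#' sessions of 1 Hz skin conductance with hot-flash events (a spike followed
#' by a gradual decline), slow baseline drift, white measurement noise,
#' sparse rectangular motion artifacts, prolonged nighttime episodes (night
#' sweats) and participant markers that lag the physiological onset and are
#' present for only a fraction of events. Two morphology patterns exist:
#' `typical` (low baseline, large spikes) and `atypical` (elevated baseline,
#' smaller and therefore harder-to-see changes).
#'
#' Event onsets are drawn from a homogeneous Poisson process thinned to a
#' minimum inter-event spacing (`refractory_s`, default 480 s, which keeps
#' train-scheme label zones of neighbouring events from overlapping) and
#' rounded to the 1 Hz grid. Each event adds `amplitude * S(t)` where `S`
#' rises from 0 to 1 over `rise_s` along a normalized logistic ramp and then
#' decays as `exp(-(t - t_peak) / tau)`.
#'
#' The event onset recorded in the ground-truth log is the
#' perception-aligned reference time; the sweat response begins
#' `perception_lag_s` seconds earlier, reflecting that skin conductance
#' starts rising before a hot flash is subjectively perceived. Identification
#' latencies are therefore measured against the perception-aligned onset, as
#' in ambulatory studies, and a model watching the conductance rise can
#' legitimately fire before it.
#'
#' @param duration_h Session length in hours (default 48).
#' @param event_rate_per_h Hot-flash rate (default 0.5/h).
#' @param refractory_s Minimum spacing between event onsets (default 480 s).
#' @param pattern `"typical"` or `"atypical"`; switches the baseline and
#'   amplitude defaults below when they are left `NULL`.
#' @param baseline_uS Session baseline (default 2 typical, 6 atypical).
#' @param amplitude_range_uS Event amplitude range (default 2-8 typical,
#'   0.5-2 atypical).
#' @param rise_s_range Rise time range, seconds (default 10-40 typical,
#'   30-120 atypical: atypical events show a smaller and slower conductance
#'   change, hence a smaller rate of change).
#' @param perception_lag_s_range Seconds by which the conductance rise leads
#'   the perception-aligned reference onset (default 10-40, consistent with ambulatory
#'   identification latencies around -20 s and pre-onset label zones
#'   beginning 30 s before the marker).
#' @param decay_tau_s_range Decay time-constant range, seconds (default
#'   60-300).
#' @param noise_sd_uS Sensor-level white noise SD at the native 32 Hz rate
#'   (default 0.05). Traces generated directly at 1 Hz carry this noise
#'   attenuated by the 1-s mean filter (divided by `sqrt(32)`), so the two
#'   generation modes are statistically consistent.
#' @param drift_amplitude_uS,drift_period_h Sinusoidal baseline drift
#'   (defaults 0.3 uS over a 6 h period).
#' @param artifact_rate_per_h,artifact_width_s_range,artifact_amplitude_uS
#'   Sparse rectangular artifacts (default 1/h, 1-5 s wide, 1 uS).
#' @param scr_rate_per_h,scr_amplitude_range_uS,scr_rise_s_range,scr_decay_tau_s_range
#'   Spontaneous (nonspecific) skin-conductance responses: small
#'   spike-then-recovery transients unrelated to hot flashes that pervade
#'   real electrodermal recordings and are the main confounder any HF
#'   detector must reject. Defaults: 8/h (sparse: one every 7-8 minutes,
#'   averaging wake and sleep at a torso site, so roughly a third of 60-s
#'   windows contact one), amplitude 0.05-0.5 uS, rise 2-6 s, recovery time
#'   constant 10-40 s.
#' @param marked_fraction Fraction of events carrying a participant marker
#'   (default 0.35; most events go unperceived or unlogged).
#' @param marker_delay_median_s,marker_delay_sdlog,marker_delay_cap_s
#'   Lognormal delay of the perceived marker after the physiological onset
#'   (median 15 s, capped at 60 s).
#' @param night_sweat_rate_per_h Rate of prolonged nighttime episodes during
#'   the nightly third of each 24 h (default 0.02/h).
#' @param sampling_rate_hz 1 (default) or 32 (to exercise the 32 Hz -> 1 Hz
#'   reduction).
#' @param seed RNG seed; the session is fully determined by it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_h = 48,
                         event_rate_per_h = 0.5,
                         refractory_s = 480,
                         pattern = c("typical", "atypical"),
                         baseline_uS = NULL,
                         amplitude_range_uS = NULL,
                         rise_s_range = NULL,
                         perception_lag_s_range = c(10, 40),
                         decay_tau_s_range = c(60, 300),
                         noise_sd_uS = 0.05,
                         drift_amplitude_uS = 0.3,
                         drift_period_h = 6,
                         artifact_rate_per_h = 1,
                         artifact_width_s_range = c(1, 5),
                         artifact_amplitude_uS = 1,
                         scr_rate_per_h = 8,
                         scr_amplitude_range_uS = c(0.05, 0.5),
                         scr_rise_s_range = c(2, 6),
                         scr_decay_tau_s_range = c(10, 40),
                         marked_fraction = 0.35,
                         marker_delay_median_s = 15,
                         marker_delay_sdlog = 0.5,
                         marker_delay_cap_s = 60,
                         night_sweat_rate_per_h = 0.02,
                         sampling_rate_hz = 1,
                         seed = 1) {
  pattern <- match.arg(pattern)
  if (is.null(baseline_uS)) {
    baseline_uS <- if (pattern == "typical") 2.0 else 6.0
  }
  if (is.null(amplitude_range_uS)) {
    amplitude_range_uS <- if (pattern == "typical") c(2, 8) else c(0.5, 2)
  }
  if (is.null(rise_s_range)) {
    rise_s_range <- if (pattern == "typical") c(10, 40) else c(30, 120)
  }
  cfg <- list(duration_h = duration_h, event_rate_per_h = event_rate_per_h,
              refractory_s = refractory_s, pattern = pattern,
              baseline_uS = baseline_uS,
              amplitude_range_uS = amplitude_range_uS,
              rise_s_range = rise_s_range,
              perception_lag_s_range = perception_lag_s_range,
              decay_tau_s_range = decay_tau_s_range,
              noise_sd_uS = noise_sd_uS,
              drift_amplitude_uS = drift_amplitude_uS,
              drift_period_h = drift_period_h,
              artifact_rate_per_h = artifact_rate_per_h,
              artifact_width_s_range = artifact_width_s_range,
              artifact_amplitude_uS = artifact_amplitude_uS,
              scr_rate_per_h = scr_rate_per_h,
              scr_amplitude_range_uS = scr_amplitude_range_uS,
              scr_rise_s_range = scr_rise_s_range,
              scr_decay_tau_s_range = scr_decay_tau_s_range,
              marked_fraction = marked_fraction,
              marker_delay_median_s = marker_delay_median_s,
              marker_delay_sdlog = marker_delay_sdlog,
              marker_delay_cap_s = marker_delay_cap_s,
              night_sweat_rate_per_h = night_sweat_rate_per_h,
              sampling_rate_hz = sampling_rate_hz, seed = seed)
  if (duration_h <= 0 || refractory_s <= 0 || noise_sd_uS < 0 ||
      any(amplitude_range_uS <= 0) || any(rise_s_range <= 0) ||
      any(perception_lag_s_range < 0) || any(decay_tau_s_range <= 0)) {
    stop_data("synth_config ranges must be positive")
  }
  # rate infeasible if the mean Poisson gap is below the enforced spacing
  if (event_rate_per_h > 0 && 3600 / event_rate_per_h < refractory_s) {
    stop_data(sprintf(
      "event rate %.3g/h incompatible with a %.0f s refractory period",
      event_rate_per_h, refractory_s))
  }
  class(cfg) <- "synth_config"
  cfg
}

# normalized logistic rise (exactly 0 at onset, 1 at peak) then exponential decay
event_shape <- function(t, onset, rise_s, tau_s) {
  s <- numeric(length(t))
  peak <- onset + rise_s
  up <- t >= onset & t <= peak
  lo <- stats::plogis(-4)
  s[up] <- (stats::plogis(8 * (t[up] - onset) / rise_s - 4) - lo) / (1 - 2 * lo)
  dn <- t > peak
  s[dn] <- exp(-(t[dn] - peak) / tau_s)
  s
}

poisson_onsets <- function(rate_per_s, t_min, t_max, refractory_s) {
  if (rate_per_s <= 0 || t_max <= t_min) return(numeric(0))
  onsets <- numeric(0)
  t <- t_min
  repeat {
    t <- t + stats::rexp(1, rate_per_s)
    if (t > t_max) break
    if (length(onsets) == 0L || t - onsets[length(onsets)] >= refractory_s) {
      onsets <- c(onsets, t)
    }
  }
  onsets
}

#' Simulate one skin-conductance session with ground truth
#'
#' Draws events, builds the conductance trace and produces delayed
#' participant markers for a random subset of events; see [synth_config] for
#' what is emulated. Everything is determined by `config$seed`. Event onsets
#' are simulated "expert-grade" ground truth; the human adjudication workflow
#' of real studies is emulated by this ground truth plus the marker-delay
#' model, not implemented.
#'
#' @param config A [synth_config].
#' @param participant_id,session_id Identifiers stamped on the trace.
#' @return A list of class `synth_session` with elements `trace`
#'   ([sc_trace]), `true_events` ([hf_events]: confirmed events plus any
#'   night sweats), `perceived_markers` ([hf_events]), `mask` (empty
#'   [exclusion_mask]) and `config`.
#' @export
simulate_session <- function(config, participant_id = "P01",
                             session_id = "S01") {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  dur <- config$duration_h * 3600
  margin <- 300
  onsets <- poisson_onsets(config$event_rate_per_h / 3600,
                           margin, dur - margin, config$refractory_s)
  onsets <- round(onsets)  # events live on the 1 Hz grid
  n_ev <- length(onsets)
  amp <- stats::runif(n_ev, config$amplitude_range_uS[1], config$amplitude_range_uS[2])
  rise <- round(stats::runif(n_ev, config$rise_s_range[1], config$rise_s_range[2]))
  tau <- stats::runif(n_ev, config$decay_tau_s_range[1], config$decay_tau_s_range[2])
  # the sweat response leads the perception-aligned reference onset
  lag <- round(stats::runif(n_ev, config$perception_lag_s_range[1],
                            config$perception_lag_s_range[2]))
  phys_onsets <- onsets - lag

  # night sweats: prolonged episodes during the nightly third of each day
  ns_onsets <- numeric(0)
  if (config$night_sweat_rate_per_h > 0) {
    cand <- poisson_onsets(config$night_sweat_rate_per_h / 3600,
                           margin, dur - margin, config$refractory_s)
    hour_of_day <- (cand / 3600) %% 24
    ns_onsets <- round(cand[hour_of_day < 8])
    ns_onsets <- ns_onsets[!vapply(ns_onsets, function(o) {
      n_ev > 0 && min(abs(onsets - o)) < config$refractory_s
    }, TRUE)]
  }
  n_ns <- length(ns_onsets)
  ns_amp <- stats::runif(n_ns, 1, 3)
  ns_rise <- round(stats::runif(n_ns, 30, 120))
  ns_tau <- stats::runif(n_ns, 1200, 2400)

  fs <- config$sampling_rate_hz
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sc <- rep(config$baseline_uS, length(t))
  if (config$drift_amplitude_uS > 0) {
    sc <- sc + config$drift_amplitude_uS *
      sin(2 * pi * t / (config$drift_period_h * 3600))
  }
  for (i in seq_len(n_ev)) {
    sc <- sc + amp[i] * event_shape(t, phys_onsets[i], rise[i], tau[i])
  }
  for (i in seq_len(n_ns)) {
    sc <- sc + ns_amp[i] * event_shape(t, ns_onsets[i], ns_rise[i], ns_tau[i])
  }
  # spontaneous (nonspecific) SCRs: unlabeled small transients everywhere
  if (config$scr_rate_per_h > 0) {
    n_scr <- stats::rpois(1, config$scr_rate_per_h * config$duration_h)
    if (n_scr > 0) {
      scr_t <- round(stats::runif(n_scr, 0, dur))
      scr_a <- stats::runif(n_scr, config$scr_amplitude_range_uS[1],
                            config$scr_amplitude_range_uS[2])
      scr_r <- pmax(1, round(stats::runif(n_scr, config$scr_rise_s_range[1],
                                          config$scr_rise_s_range[2])))
      scr_tau <- stats::runif(n_scr, config$scr_decay_tau_s_range[1],
                              config$scr_decay_tau_s_range[2])
      for (i in seq_len(n_scr)) {
        sc <- sc + scr_a[i] * event_shape(t, scr_t[i], scr_r[i], scr_tau[i])
      }
    }
  }
  if (config$artifact_rate_per_h > 0) {
    n_art <- stats::rpois(1, config$artifact_rate_per_h * config$duration_h)
    if (n_art > 0) {
      a_start <- stats::runif(n_art, 0, dur)
      a_width <- stats::runif(n_art, config$artifact_width_s_range[1],
                              config$artifact_width_s_range[2])
      a_sign <- sample(c(-1, 1), n_art, replace = TRUE)
      for (i in seq_len(n_art)) {
        hit <- t >= a_start[i] & t < a_start[i] + a_width[i]
        sc[hit] <- sc[hit] + a_sign[i] * config$artifact_amplitude_uS
      }
    }
  }
  if (config$noise_sd_uS > 0) {
    # noise_sd_uS is sensor-level (32 Hz) white noise; a 1 Hz trace carries
    # it attenuated by the 1-s mean filter, keeping the direct 1 Hz mode
    # statistically consistent with 32 Hz generation + downsample_to_1hz
    eff_sd <- if (fs == 1) config$noise_sd_uS / sqrt(32) else config$noise_sd_uS
    sc <- sc + stats::rnorm(length(t), 0, eff_sd)
  }
  sc <- pmax(sc, 0)

  true_events <- hf_events(
    onset_s = c(onsets, ns_onsets),
    source = "expert",
    status = c(rep("confirmed", n_ev), rep("night_sweat", n_ns)),
    pattern = config$pattern
  )
  marked <- if (n_ev > 0) {
    which(stats::runif(n_ev) < config$marked_fraction)
  } else integer(0)
  delay <- pmin(stats::rlnorm(length(marked),
                              meanlog = log(config$marker_delay_median_s),
                              sdlog = config$marker_delay_sdlog),
                config$marker_delay_cap_s)
  markers <- hf_events(onset_s = onsets[marked] + delay,
                       source = "participant", status = "confirmed",
                       pattern = config$pattern)
  structure(
    list(trace = sc_trace(t, sc, fs, participant_id = participant_id,
                          session_id = session_id),
         true_events = true_events,
         perceived_markers = markers,
         mask = exclusion_mask(),
         config = config),
    class = "synth_session"
  )
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf(
    "<synth_session> %s/%s: %.1f h, %d confirmed event(s), %d night sweat(s), %d marker(s)\n",
    x$trace$participant_id, x$trace$session_id, x$config$duration_h,
    sum(x$true_events$status == "confirmed"),
    sum(x$true_events$status == "night_sweat"),
    nrow(x$perceived_markers)))
  invisible(x)
}

#' Simulate a cohort of participants with repeat sessions
#'
#' Participant-level traits (morphology pattern, baseline level, amplitude
#' tendency) are drawn once per participant and shared across that
#' participant's visits; per-visit seeds derive deterministically from the
#' master seed. The first `ceiling(n/2)` participants are typical and the
#' rest atypical, so cohorts are pattern-balanced by construction.
#'
#' @param config Base [synth_config]; per-participant configs override
#'   pattern, baseline and amplitude range.
#' @param n_participants Number of participants.
#' @param visits_per_participant Sessions per participant (default 3).
#' @return A list of class `synth_cohort`: `sessions` (list of
#'   [simulate_session] results), `participants` (trait table) and `config`.
#' @export
simulate_cohort <- function(config, n_participants,
                            visits_per_participant = 3) {
  stopifnot(inherits(config, "synth_config"), n_participants >= 1)
  n_typ <- ceiling(n_participants / 2)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  participants <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n_participants)),
    pattern = rep(c("typical", "atypical"),
                  c(n_typ, n_participants - n_typ)),
    stringsAsFactors = FALSE
  )
  # per-participant trait jitter around the pattern defaults
  sessions <- list()
  for (i in seq_len(n_participants)) {
    set.seed((config$seed + 7919L * i) %% .Machine$integer.max)
    base_jit <- stats::runif(1, 0.8, 1.2)
    amp_jit <- stats::runif(1, 0.8, 1.2)
    pat <- participants$pattern[i]
    proto <- synth_config(pattern = pat)   # pattern-specific defaults
    for (v in seq_len(visits_per_participant)) {
      cfg <- config
      cfg$pattern <- pat
      cfg$baseline_uS <- proto$baseline_uS * base_jit
      cfg$amplitude_range_uS <- proto$amplitude_range_uS * amp_jit
      cfg$rise_s_range <- proto$rise_s_range
      cfg$seed <- (config$seed + 1000L * i + v) %% .Machine$integer.max
      sessions[[length(sessions) + 1L]] <-
        simulate_session(cfg, participant_id = participants$participant_id[i],
                         session_id = sprintf("V%d", v))
    }
  }
  structure(list(sessions = sessions, participants = participants,
                 config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d participants x %d sessions (%d typical, %d atypical)\n",
              nrow(x$participants),
              length(x$sessions) / nrow(x$participants),
              sum(x$participants$pattern == "typical"),
              sum(x$participants$pattern == "atypical")))
  invisible(x)
}

#' Write a synthetic session's files
#'
#' Emits the trace, event log, marker log and mask CSVs plus a JSON manifest
#' echoing the generating configuration and seed.
#'
#' @param session A [simulate_session] result.
#' @param dir Output directory (created if needed).
#' @export
write_synth_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sc_trace(session$trace, file.path(dir, "trace.csv"))
  write_hf_events(session$true_events, file.path(dir, "events.csv"))
  write_hf_events(session$perceived_markers, file.path(dir, "markers.csv"))
  write_exclusion_mask(session$mask, file.path(dir, "mask.csv"))
  jsonlite::write_json(unclass(session$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
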