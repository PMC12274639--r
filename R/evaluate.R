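#' Window-level confusion counts with HF classes merged
#'
#' Classes 1 and 2 both indicate an ongoing hot flash, so they are merged
#' into a single HF class before counting: a window counts as HF if its
#' class is 1 or 2, non-HF if 0. Windows whose true label is `excluded` are
#' dropped (with their predictions) before counting.
#'
#' @param predicted Predicted classes (`0`, `1`, `2`; factor or character).
#' @param truth True labels (`0`, `1`, `2`, `excluded`), aligned with
#'   `predicted` by window.
#' @return A list of class `hf_confusion` with integer `TP`, `FP`, `FN`, `TN`.
#' @export
window_confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_data("predicted and truth must align window for window")
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  keep <- truth != "excluded"
  truth <- truth[keep]; predicted <- predicted[keep]
  t_hf <- truth %in% c("1", "2")
  p_hf <- predicted %in% c("1", "2")
  structure(list(TP = sum(p_hf & t_hf), FP = sum(p_hf & !t_hf),
                 FN = sum(!p_hf & t_hf), TN = sum(!p_hf & !t_hf)),
            class = "hf_confusion")
}

#' @export
print.hf_confusion <- function(x, ...) {
  cat(sprintf("<hf_confusion> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Window-level performance measures
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values `TP/(TP+FP)` and `TN/(TN+FN)`, and
#' `F1 = 2TP/(2TP+FP+FN)` from merged-class confusion counts, plus
#' predictivity: the fraction of true Class 1 (pre-onset) windows the model
#' calls HF. Ratios with a zero denominator are reported as `NA`, never 0.
#'
#' @param counts An [window_confusion] result.
#' @param class1_pred Predicted classes of the windows whose true label is 1
#'   (optional; predictivity is `NA` when absent or empty).
#' @return Named list `Sens`, `Spec`, `Pred`, `PPV`, `NPV`, `F1`.
#' @export
window_metrics <- function(counts, class1_pred = NULL) {
  stopifnot(inherits(counts, "hf_confusion"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  pred <- if (is.null(class1_pred) || length(class1_pred) == 0L) {
    NA_real_
  } else {
    mean(as.character(class1_pred) %in% c("1", "2"))
  }
  list(Sens = ratio(counts$TP, counts$TP + counts$FN),
       Spec = ratio(counts$TN, counts$TN + counts$FP),
       Pred = pred,
       PPV = ratio(counts$TP, counts$TP + counts$FP),
       NPV = ratio(counts$TN, counts$TN + counts$FN),
       F1 = ratio(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN))
}

#' Event-level outcomes: predicted, detected or missed
#'
#' For each reference event, the candidate positives are HF-predicted windows
#' whose end time lies within `[onset - pre_s, onset + post_s]` (defaults 60 s
#' before through 30 s after onset). An event with no candidate is `missed`.
#' Otherwise only the first identification counts: the latency is the
#' earliest candidate end minus the onset, and the event is `predicted` if
#' the latency is negative (before the marker) or `detected` if it is in
#' `[0, post_s]`. A positive window falling in the candidate interval of more
#' than one event is attributed to the nearer onset.
#'
#' @param predicted Predicted classes aligned with `end_s`.
#' @param end_s Window end times (seconds), sorted increasing.
#' @param events Confirmed reference events ([hf_events] or numeric onsets).
#' @param pre_s,post_s Candidate interval half-widths (seconds).
#' @return A `data.frame` with `onset_s`, `outcome` and `latency_s` (`NA`
#'   when missed), one row per event.
#' @export
event_outcomes <- function(predicted, end_s, events, pre_s = 60, post_s = 30) {
  onsets <- if (inherits(events, "data.frame")) events$onset_s else as.numeric(events)
  if (length(predicted) != length(end_s)) {
    stop_data("predicted and end_s must align")
  }
  if (is.unsorted(end_s)) stop_data("end_s must be sorted increasing")
  pos <- end_s[as.character(predicted) %in% c("1", "2")]
  n_ev <- length(onsets)
  outcome <- rep("missed", n_ev)
  latency <- rep(NA_real_, n_ev)
  if (length(pos) > 0L && n_ev > 0L) {
    # a positive shared by several candidate intervals goes to the nearer onset
    assigned <- vapply(pos, function(p) {
      elig <- which(p >= onsets - pre_s & p <= onsets + post_s)
      if (length(elig) == 0L) return(NA_integer_)
      elig[which.min(abs(onsets[elig] - p))]
    }, 0L)
    for (i in seq_len(n_ev)) {
      cand <- pos[!is.na(assigned) & assigned == i]
      if (length(cand) == 0L) next
      latency[i] <- min(cand) - onsets[i]
      outcome[i] <- if (latency[i] < 0) "predicted" else "detected"
    }
  }
  data.frame(onset_s = onsets, outcome = outcome, latency_s = latency)
}

#' Per-session evaluation
#'
#' Combines window-level measures with the event-level ones: prediction rate
#' `PR` (fraction of events predicted before onset), identification rate
#' `IR` (fraction predicted or detected), and identification latency `IL`
#' (mean signed latency over identified events, negative = before the
#' marker). Sessions without events report `NA` for `PR`/`IR`/`IL`.
#'
#' @param predicted,truth Aligned window classes and true labels.
#' @param end_s Window end times.
#' @param events Confirmed reference events for the session.
#' @param session_id Identifier carried into reports.
#' @param pre_s,post_s Candidate interval for [event_outcomes].
#' @return A one-row `data.frame` of class `hf_session_eval`.
#' @export
session_metrics <- function(predicted, truth, end_s, events,
                            session_id = NA_character_,
                            pre_s = 60, post_s = 30) {
  counts <- window_confusion(predicted, truth)
  cls1 <- as.character(truth) == "1"
  wm <- window_metrics(counts, class1_pred = predicted[cls1])
  oc <- event_outcomes(predicted, end_s, events, pre_s = pre_s, post_s = post_s)
  n_ev <- nrow(oc)
  n_pred <- sum(oc$outcome == "predicted")
  n_det <- sum(oc$outcome == "detected")
  il <- if (n_pred + n_det > 0) mean(oc$latency_s, na.rm = TRUE) else NA_real_
  out <- data.frame(session_id = session_id,
                    TP = counts$TP, FP = counts$FP,
                    FN = counts$FN, TN = counts$TN,
                    Sens = wm$Sens, Spec = wm$Spec, Pred = wm$Pred,
                    PPV = wm$PPV, NPV = wm$NPV, F1 = wm$F1,
                    PR = if (n_ev > 0) n_pred / n_ev else NA_real_,
                    IR = if (n_ev > 0) (n_pred + n_det) / n_ev else NA_real_,
                    IL = il, n_events = n_ev,
                    stringsAsFactors = FALSE)
  class(out) <- c("hf_session_eval", "data.frame")
  out
}

#' Aggregate session evaluations
#'
#' Unweighted mean and SD of each measure across sessions. Sessions with no
#' events are excluded from the `PR`/`IR`/`IL` aggregation (and sessions with
#' no identified event from `IL`); window measures average over all sessions
#' where they are defined.
#'
#' @param sessions A `data.frame` of stacked [session_metrics] rows, or a
#'   list of them.
#' @return A `data.frame` with one row per measure: `mean`, `sd`, `n_sessions`.
#' @export
aggregate_sessions <- function(sessions) {
  if (is.list(sessions) && !is.data.frame(sessions)) {
    sessions <- do.call(rbind, sessions)
  }
  if (is.null(sessions) || nrow(sessions) == 0L) {
    stop_data("no sessions to aggregate")
  }
  measures <- c("Sens", "Spec", "Pred", "PPV", "NPV", "F1", "PR", "IR", "IL")
  rows <- lapply(measures, function(m) {
    v <- sessions[[m]]
    if (m %in% c("PR", "IR", "IL")) v <- v[sessions$n_events > 0]
    v <- v[is.finite(v)]
    data.frame(measure = m,
               mean = if (length(v) > 0) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_sessions = length(v))
  })
  do.call(rbind, rows)
}

#' Classical threshold detector for hot flashes
#'
#' The conventional criterion: an increase of at least `threshold_uS`
#' (default 2 uS, i.e. 2 umho) within `span_s` (default 30 s) of skin
#' conductance. The detector slides a trailing comparison over a 1 Hz trace
#' and fires where `sc(t) - sc(t - span_s) >= threshold_uS`. Because the
#' criterion keeps firing throughout one spike, a run of consecutive firing
#' samples is collapsed to its first sample, and a refractory period
#' suppresses re-detection immediately after an accepted onset. Detections
#' can be fed to [event_outcomes] exactly like model positives.
#'
#' @param trace An [sc_trace] at 1 Hz.
#' @param threshold_uS Minimum rise (uS).
#' @param span_s Rise interval (s).
#' @param refractory_s Suppression period after each detection (s).
#' @return Numeric vector of detected onset times (seconds).
#' @export
freedman_detect <- function(trace, threshold_uS = 2, span_s = 30,
                            refractory_s = 60) {
  stopifnot(inherits(trace, "sc_trace"))
  if (abs(trace$sampling_rate_hz - 1) > 1e-9) {
    stop_data("freedman_detect expects a 1 Hz trace")
  }
  t <- trace$time_s; y <- trace$sc_uS
  n <- length(t)
  if (n <= span_s) return(numeric(0))
  # compare each sample with the one exactly span_s earlier (gap-aware)
  t0 <- t[1L]
  off <- as.integer(round(t - t0))
  idx <- rep(NA_integer_, max(off) + 1L)
  idx[off + 1L] <- seq_len(n)
  prev <- rep(NA_integer_, n)
  has_prev <- off >= span_s
  prev[has_prev] <- idx[off[has_prev] - as.integer(span_s) + 1L]
  fire <- !is.na(prev) & (y - y[ifelse(is.na(prev), 1L, prev)] >= threshold_uS)
  # run starts: firing samples not continuing a firing run at the previous second
  contig <- c(FALSE, fire[-n] & abs(diff(t) - 1) < 1e-6)
  starts <- which(fire & !contig)
  onsets <- numeric(0)
  last <- -Inf
  for (i in starts) {
    if (t[i] - last >= refractory_s) {
      onsets <- c(onsets, t[i])
      last <- t[i]
    }
  }
  onsets
}
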