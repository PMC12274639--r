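#' Generate overlapping trailing windows over a 1 Hz trace
#'
#' Windows are identified by the time of their last sample. The first window
#' ends `length_s - 1` seconds after the first sample; successive end times
#' advance by `step_s`. Windows that would span a gap (an excluded or missing
#' block) are skipped.
#'
#' @param trace An [sc_trace] at 1 Hz.
#' @param length_s Window length in seconds (number of 1 Hz samples).
#' @param step_s Step between successive window ends, seconds.
#' @param ends Optional numeric vector restricting output to windows whose end
#'   times are in this set (used to avoid computing features for windows that
#'   are excluded from training).
#' @return An object of class `hf_windows`: end times plus a
#'   `n x length_s` matrix of conductance values, one row per window.
#' @export
generate_windows <- function(trace, length_s, step_s, ends = NULL) {
  stopifnot(inherits(trace, "sc_trace"))
  if (abs(trace$sampling_rate_hz - 1) > 1e-9) {
    stop_data("windowing expects a 1 Hz trace; downsample first")
  }
  length_s <- as.integer(round(length_s))
  t0 <- trace$time_s[1L]
  tmax <- trace$time_s[length(trace$time_s)]
  empty <- function() {
    structure(list(end_s = numeric(0), length_s = length_s, step_s = step_s,
                   values = matrix(numeric(0), 0L, length_s)),
              class = "hf_windows")
  }
  if (tmax - t0 + 1 < length_s) {
    warning(sprintf("trace shorter than window length (%d s); no windows",
                    length_s))
    return(empty())
  }
  cand <- seq(t0 + length_s - 1, tmax, by = step_s)
  if (!is.null(ends)) cand <- cand[round(cand - t0, 6) %in% round(ends - t0, 6)]
  if (length(cand) == 0L) return(empty())
  # map integer offsets from t0 to sample indices; gaps are absent offsets
  off <- as.integer(round(trace$time_s - t0))
  idx <- rep(NA_integer_, max(off) + 1L)
  idx[off + 1L] <- seq_along(off)
  end_off <- as.integer(round(cand - t0))
  rows <- vapply(end_off, function(e) {
    idx[(e - length_s + 1L):e + 1L]
  }, integer(length_s))
  rows <- t(rows)                      # n x length_s index matrix
  ok <- !apply(is.na(rows), 1L, any)   # skip windows spanning a gap
  vals <- matrix(trace$sc_uS[t(rows[ok, , drop = FALSE])],
                 nrow = sum(ok), ncol = length_s, byrow = TRUE)
  structure(list(end_s = cand[ok], length_s = length_s, step_s = step_s,
                 values = vals),
            class = "hf_windows")
}

#' @export
print.hf_windows <- function(x, ...) {
  cat(sprintf("<hf_windows> %d windows of %d s (step %g s)\n",
              length(x$end_s), x$length_s, x$step_s))
  invisible(x)
}

#' Window labeling scheme
#'
#' Offsets (seconds, signed, relative to event onset) delimiting the
#' three-class zones around each confirmed HF onset, as half-open intervals on
#' the window's last timestamp. Two modes exist:
#'
#' * `train`: Class 1 (HF occurrence) for ends in `[-30, 120)`, Class 2 (HF
#'   persistence) in `[120, 240)`, Class 0 (non-HF) in `[-240, -30)` around
#'   confirmed events or within `[-240, 240)` of a rejected candidate;
#'   everything else is excluded to improve class balance.
#' * `test`: Class 1 (pre-HF) in `[-60, 0)`, Class 2 (post-HF) in `[0, 30)`,
#'   excluded in `[30, 1200)` (30 s to 20 min after onset), Class 0 otherwise.
#'
#' When zones of several events overlap, the label with precedence
#' 1 > 2 > 0 > excluded wins (in test mode Class 0 is the complement, so the
#' effective order is 1 > 2 > excluded > 0). A window end exactly at onset is
#' Class 2 in test mode.
#'
#' @param mode `"train"` or `"test"`.
#' @param class1,class2,class0,excluded Length-2 numeric offset intervals
#'   (lower inclusive, upper exclusive) overriding the defaults above.
#'   `class0` applies in train mode only; `excluded` in test mode only.
#' @param rejected_halfwidth_s Train mode: half-width of the Class 0 zone
#'   around rejected candidates (default 240 s).
#' @return A list of class `hf_label_scheme`.
#' @export
label_scheme <- function(mode = c("train", "test"),
                         class1 = NULL, class2 = NULL, class0 = NULL,
                         excluded = NULL, rejected_halfwidth_s = 240) {
  mode <- match.arg(mode)
  defaults <- if (mode == "train") {
    list(class1 = c(-30, 120), class2 = c(120, 240), class0 = c(-240, -30),
         excluded = NULL)
  } else {
    list(class1 = c(-60, 0), class2 = c(0, 30), class0 = NULL,
         excluded = c(30, 1200))
  }
  s <- list(mode = mode,
            class1 = if (is.null(class1)) defaults$class1 else class1,
            class2 = if (is.null(class2)) defaults$class2 else class2,
            class0 = if (is.null(class0)) defaults$class0 else class0,
            excluded = if (is.null(excluded)) defaults$excluded else excluded,
            rejected_halfwidth_s = rejected_halfwidth_s)
  for (nm in c("class1", "class2", "class0", "excluded")) {
    iv <- s[[nm]]
    if (!is.null(iv) && (length(iv) != 2L || iv[1] >= iv[2])) {
      stop_data(sprintf("scheme interval '%s' must be (lo, hi) with lo < hi", nm))
    }
  }
  ivs <- Filter(Negate(is.null), s[c("class1", "class2", "class0", "excluded")])
  ivs <- ivs[order(vapply(ivs, `[`, 0, 1L))]
  if (length(ivs) > 1L) {
    for (i in seq_len(length(ivs) - 1L)) {
      if (ivs[[i]][2] > ivs[[i + 1L]][1]) {
        stop_data("scheme intervals must be disjoint")
      }
    }
  }
  class(s) <- "hf_label_scheme"
  s
}

in_iv <- function(x, onset, iv) {
  # TRUE if x - onset lies in the half-open offset interval iv
  outer(x, onset, function(e, o) e - o >= iv[1] & e - o < iv[2])
}

#' Label windows relative to HF events
#'
#' Assigns each window one of the labels `"0"`, `"1"`, `"2"` or `"excluded"`
#' from its last timestamp and the event onsets, under a [label_scheme].
#' Night sweats must be removed from `events` upstream (see
#' [confirmed_events]); rejected candidates are supplied separately and only
#' consulted in train mode.
#'
#' @param windows An [hf_windows] object (or a numeric vector of end times).
#' @param events Confirmed events: an [hf_events] table or numeric onsets.
#' @param scheme A [label_scheme].
#' @param rejected Rejected candidate events (train mode), same forms.
#' @param night_sweats Night-sweat onsets (same forms). Prolonged nighttime
#'   episodes are excluded from the analysis entirely: windows ending within
#'   `night_sweat_zone` of one are labeled `excluded` in both modes (unless a
#'   confirmed event's Class 1/2 zone also covers them).
#' @param night_sweat_zone Offset interval around a night-sweat onset to
#'   exclude (default `c(-240, 3600)`, covering the episode's slow recovery).
#' @return A `data.frame` with columns `end_s` and `label` (factor with
#'   levels `0`, `1`, `2`, `excluded`), one row per window.
#' @export
label_windows <- function(windows, events, scheme, rejected = NULL,
                          night_sweats = NULL,
                          night_sweat_zone = c(-240, 3600)) {
  stopifnot(inherits(scheme, "hf_label_scheme"))
  ends <- if (inherits(windows, "hf_windows")) windows$end_s else as.numeric(windows)
  onsets <- if (inherits(events, "data.frame")) events$onset_s else as.numeric(events)
  rej <- if (inherits(rejected, "data.frame")) rejected$onset_s else as.numeric(rejected)
  ns <- if (inherits(night_sweats, "data.frame")) night_sweats$onset_s else as.numeric(night_sweats)
  n <- length(ends)
  any_zone <- function(iv, os) {
    if (is.null(iv) || length(os) == 0L) return(rep(FALSE, n))
    rowSums(in_iv(ends, os, iv)) > 0
  }
  in1 <- any_zone(scheme$class1, onsets)
  in2 <- any_zone(scheme$class2, onsets)
  in_ns <- any_zone(night_sweat_zone, ns)
  if (scheme$mode == "train") {
    h <- scheme$rejected_halfwidth_s
    in0 <- any_zone(scheme$class0, onsets) | any_zone(c(-h, h), rej)
    lab <- ifelse(in1, "1", ifelse(in2, "2",
                  ifelse(in_ns, "excluded", ifelse(in0, "0", "excluded"))))
  } else {
    inexc <- any_zone(scheme$excluded, onsets) | in_ns
    lab <- ifelse(in1, "1", ifelse(in2, "2", ifelse(inexc, "excluded", "0")))
  }
  data.frame(end_s = ends,
             label = factor(lab, levels = c("0", "1", "2", "excluded")))
}

#' @rdname label_windows
#' @export
label_windows_train <- function(windows, events, rejected = NULL,
                                scheme = label_scheme("train")) {
  label_windows(windows, events, scheme, rejected = rejected)
}

#' @rdname label_windows
#' @export
label_windows_test <- function(windows, events,
                               scheme = label_scheme("test")) {
  label_windows(windows, events, scheme)
}

#' @export
write_labeled_windows <- function(labels, length_s, path) {
  df <- data.frame(end_s = format_num(labels$end_s),
                   length_s = length_s, label = as.character(labels$label))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
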