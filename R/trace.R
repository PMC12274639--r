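#' Skin-conductance trace
#'
#' Container for a uniformly sampled skin-conductance (SC) time series from a
#' single recording session. Times are seconds from session start; conductance
#' is in microsiemens (uS). After exclusion intervals are removed the trace may
#' contain gaps, in which case consecutive samples are an integer number of
#' sampling intervals apart.
#'
#' @param time_s Numeric vector of sample times, seconds from session start.
#' @param sc_uS Numeric vector of conductance values (uS), same length.
#' @param sampling_rate_hz Sampling rate, typically 32 (raw) or 1 (reduced).
#' @param participant_id,session_id Identifiers carried through reports.
#' @param allow_gaps If `TRUE`, missing blocks (from exclusions or empty
#'   downsampling bins) are permitted; spacing must still be a whole multiple
#'   of the sampling interval.
#' @return An object of class `sc_trace`.
#' @export
sc_trace <- function(time_s, sc_uS, sampling_rate_hz,
                     participant_id = NA_character_,
                     session_id = NA_character_,
                     allow_gaps = FALSE) {
  if (length(time_s) == 0L) {
    stop_format("trace has no samples")
  }
  if (length(time_s) != length(sc_uS)) {
    stop_format("time_s and sc_uS differ in length")
  }
  if (!is.numeric(time_s) || !is.numeric(sc_uS) ||
      anyNA(time_s) || anyNA(sc_uS)) {
    stop_format("time_s and sc_uS must be numeric without missing values")
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop_data("sampling_rate_hz must be a positive number")
  }
  d <- diff(time_s)
  if (any(d <= 0)) {
    bad <- time_s[which(d <= 0)[1L] + 1L]
    stop_data(sprintf("sample times not strictly increasing at time %.6g s", bad))
  }
  dt <- 1 / sampling_rate_hz
  ratio <- d / dt
  if (allow_gaps) {
    off <- abs(ratio - round(ratio))
    bad <- which(off > 1e-6 * pmax(1, ratio))
  } else {
    bad <- which(abs(ratio - 1) > 1e-6)
  }
  if (length(bad) > 0L) {
    stop_data(sprintf("non-uniform sample spacing at time %.6g s",
                      time_s[bad[1L] + 1L]))
  }
  if (any(sc_uS < 0)) {
    stop_data("conductance values must be non-negative")
  }
  structure(
    list(time_s = as.numeric(time_s), sc_uS = as.numeric(sc_uS),
         sampling_rate_hz = sampling_rate_hz,
         participant_id = participant_id, session_id = session_id),
    class = "sc_trace"
  )
}

#' @export
print.sc_trace <- function(x, ...) {
  cat(sprintf("<sc_trace> %d samples at %g Hz, %.1f-%.1f s",
              length(x$time_s), x$sampling_rate_hz,
              min(x$time_s), max(x$time_s)))
  if (!is.na(x$participant_id)) cat(sprintf(", participant %s", x$participant_id))
  if (!is.na(x$session_id)) cat(sprintf(", session %s", x$session_id))
  cat(sprintf("\n  SC range %.3f-%.3f uS\n", min(x$sc_uS), max(x$sc_uS)))
  invisible(x)
}

#' @export
plot.sc_trace <- function(x, events = NULL, ...) {
  graphics::plot(x$time_s, x$sc_uS, type = "l",
                 xlab = "Time (s)", ylab = "Skin conductance (uS)", ...)
  if (!is.null(events)) {
    graphics::abline(v = events$onset_s, col = "red", lty = 2)
  }
  invisible(x)
}

#' @export
length.sc_trace <- function(x) length(x$time_s)

#' Read a skin-conductance trace from CSV
#'
#' Expects columns `time_s` and `sc_uS`. Rows violating time monotonicity or
#' uniform spacing are rejected with an error naming the first offending
#' timestamp; no silent repair is attempted.
#'
#' @param path CSV file path.
#' @param sampling_rate_hz Declared sampling rate of the file.
#' @inheritParams sc_trace
#' @return An [sc_trace].
#' @export
read_sc_trace <- function(path, sampling_rate_hz,
                          participant_id = NA_character_,
                          session_id = NA_character_,
                          allow_gaps = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "sc_uS")
  if (!all(need %in% names(df))) {
    stop_format(sprintf("trace CSV must have columns %s",
                        paste(need, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    stop_format(sprintf("trace CSV '%s' has no data rows", path))
  }
  sc_trace(df$time_s, df$sc_uS, sampling_rate_hz,
           participant_id = participant_id, session_id = session_id,
           allow_gaps = allow_gaps)
}

#' Write a trace to CSV
#'
#' Values are written with enough digits to round-trip within 1e-9.
#'
#' @param trace An [sc_trace].
#' @param path Output CSV path.
#' @export
write_sc_trace <- function(trace, path) {
  df <- data.frame(time_s = format_num(trace$time_s),
                   sc_uS = format_num(trace$sc_uS))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reduce a 32 Hz trace to 1 Hz by block averaging
#'
#' Each output sample at integer second `t` is the mean of all input samples
#' with time in `[t, t + 1)`. Seconds containing no samples become gaps in the
#' output rather than fabricated values.
#'
#' @param trace An [sc_trace] sampled at 32 Hz.
#' @return An [sc_trace] at 1 Hz (possibly with gaps).
#' @export
downsample_to_1hz <- function(trace) {
  stopifnot(inherits(trace, "sc_trace"))
  if (abs(trace$sampling_rate_hz - 32) > 1e-9) {
    stop_data("downsample_to_1hz expects a 32 Hz input trace")
  }
  sec <- floor(trace$time_s + 1e-9)
  means <- tapply(trace$sc_uS, sec, mean)
  t_out <- as.numeric(names(means))
  o <- order(t_out)
  sc_trace(t_out[o], as.numeric(means)[o], sampling_rate_hz = 1,
           participant_id = trace$participant_id,
           session_id = trace$session_id,
           allow_gaps = TRUE)
}

#' Remove samples covered by an exclusion mask
#'
#' Samples whose time falls inside any mask interval `[start_s, end_s)` are
#' dropped; the result carries gaps that downstream windowing refuses to span.
#' A mask with no overlap with the session span produces a warning and the
#' identity result. Applying the same mask twice is a no-op.
#'
#' @param trace An [sc_trace].
#' @param mask An [exclusion_mask].
#' @return An [sc_trace] with gaps where data were removed.
#' @export
apply_exclusions <- function(trace, mask) {
  stopifnot(inherits(trace, "sc_trace"), inherits(mask, "exclusion_mask"))
  iv <- mask$intervals
  if (nrow(iv) == 0L) return(trace)
  drop <- rep(FALSE, length(trace$time_s))
  for (i in seq_len(nrow(iv))) {
    drop <- drop | (trace$time_s >= iv$start_s[i] & trace$time_s < iv$end_s[i])
  }
  if (!any(drop)) {
    span <- range(trace$time_s)
    outside <- all(iv$end_s <= span[1] | iv$start_s > span[2])
    if (outside) {
      warning("exclusion mask does not overlap the session span; trace unchanged")
    }
    return(trace)
  }
  if (all(drop)) stop_data("exclusion mask removes every sample")
  sc_trace(trace$time_s[!drop], trace$sc_uS[!drop],
           trace$sampling_rate_hz,
           participant_id = trace$participant_id,
           session_id = trace$session_id,
           allow_gaps = TRUE)
}

format_num <- function(x) {
  formatC(x, format = "g", digits = 15)
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("hf_format_error", "error", "condition")))
}

stop_data <- function(msg) {
  stop(errorCondition(msg, class = c("hf_data_error", "error", "condition")))
}
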