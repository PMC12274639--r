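#' Hot-flash event log
#'
#' One row per event onset. `source` records who placed the marker
#' (`participant` for perceived events, `expert` for visually adjudicated
#' ones); `status` distinguishes confirmed events, rejected candidates, and
#' prolonged nighttime episodes (night sweats, which are never used as
#' positive labels); `pattern` tags the SC morphology.
#'
#' @param onset_s Numeric vector of onset times, seconds from session start.
#' @param source One of `"participant"`, `"expert"` (recycled).
#' @param status One of `"confirmed"`, `"rejected"`, `"night_sweat"` (recycled).
#' @param pattern One of `"typical"`, `"atypical"`, `"unknown"` (recycled).
#' @return A `data.frame` of class `hf_events`, sorted by onset.
#' @export
hf_events <- function(onset_s = numeric(),
                      source = "expert",
                      status = "confirmed",
                      pattern = "unknown") {
  n <- length(onset_s)
  df <- data.frame(
    onset_s = as.numeric(onset_s),
    source = rep_len(as.character(source), n),
    status = rep_len(as.character(status), n),
    pattern = rep_len(as.character(pattern), n),
    stringsAsFactors = FALSE
  )
  chk <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad) > 0L) {
      stop_data(sprintf("invalid %s value(s): %s", col,
                        paste(bad, collapse = ", ")))
    }
  }
  chk("source", c("participant", "expert"))
  chk("status", c("confirmed", "rejected", "night_sweat"))
  chk("pattern", c("typical", "atypical", "unknown"))
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hf_events", "data.frame")
  df
}

#' Keep only events usable as positive labels
#'
#' Drops night sweats and rejected candidates, leaving confirmed events.
#'
#' @param events An [hf_events] table.
#' @export
confirmed_events <- function(events) {
  events[events$status == "confirmed", , drop = FALSE]
}

#' Rejected candidate events
#'
#' Candidates flagged by the first reviewer but rejected on second review.
#' Their neighbourhoods contribute non-HF (Class 0) windows during training so
#' the model sees HF-like signatures labeled negative.
#'
#' @param events An [hf_events] table.
#' @export
rejected_events <- function(events) {
  events[events$status == "rejected", , drop = FALSE]
}

#' @export
read_hf_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "source", "status", "pattern")
  if (!all(need %in% names(df))) {
    stop_format(sprintf("events CSV must have columns %s",
                        paste(need, collapse = ", ")))
  }
  hf_events(df$onset_s, df$source, df$status, df$pattern)
}

#' @export
write_hf_events <- function(events, path) {
  df <- data.frame(onset_s = format_num(events$onset_s),
                   source = events$source, status = events$status,
                   pattern = events$pattern)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclusion mask
#'
#' Half-open intervals `[start_s, end_s)` of unusable data (device off-body,
#' electrode faults, saturated signal). Intervals are normalized to a sorted,
#' non-overlapping form on construction, so overlapping inputs are merged.
#'
#' @param start_s,end_s Numeric vectors of interval bounds (seconds).
#' @param reason Character vector of free-text reasons (recycled).
#' @return An object of class `exclusion_mask`.
#' @export
exclusion_mask <- function(start_s = numeric(), end_s = numeric(),
                           reason = "") {
  n <- length(start_s)
  if (length(end_s) != n) stop_data("start_s and end_s differ in length")
  if (any(start_s >= end_s)) stop_data("mask intervals need start_s < end_s")
  reason <- rep_len(as.character(reason), n)
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]; reason <- reason[o]
  # merge overlapping / touching intervals
  if (n > 1L) {
    ks <- numeric(0); ke <- numeric(0); kr <- character(0)
    cs <- start_s[1L]; ce <- end_s[1L]; cr <- reason[1L]
    for (i in 2:n) {
      if (start_s[i] <= ce) {
        ce <- max(ce, end_s[i])
        if (nzchar(reason[i]) && !identical(reason[i], cr)) {
          cr <- paste(cr, reason[i], sep = "; ")
        }
      } else {
        ks <- c(ks, cs); ke <- c(ke, ce); kr <- c(kr, cr)
        cs <- start_s[i]; ce <- end_s[i]; cr <- reason[i]
      }
    }
    ks <- c(ks, cs); ke <- c(ke, ce); kr <- c(kr, cr)
    start_s <- ks; end_s <- ke; reason <- kr
  }
  structure(
    list(intervals = data.frame(start_s = start_s, end_s = end_s,
                                reason = reason, stringsAsFactors = FALSE)),
    class = "exclusion_mask"
  )
}

#' @export
print.exclusion_mask <- function(x, ...) {
  cat(sprintf("<exclusion_mask> %d interval(s), %.0f s total\n",
              nrow(x$intervals),
              sum(x$intervals$end_s - x$intervals$start_s)))
  invisible(x)
}

#' @export
read_exclusion_mask <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "reason")
  if (!all(need %in% names(df))) {
    stop_format(sprintf("mask CSV must have columns %s",
                        paste(need, collapse = ", ")))
  }
  exclusion_mask(df$start_s, df$end_s, df$reason)
}

#' @export
write_exclusion_mask <- function(mask, path) {
  df <- data.frame(start_s = format_num(mask$intervals$start_s),
                   end_s = format_num(mask$intervals$end_s),
                   reason = mask$intervals$reason)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
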