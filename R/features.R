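#' Median-subtracted integral of a window
#'
#' `msi = sum(y - median(y)) * dt` with `dt = 1` s at 1 Hz. The median is the
#' usual even/odd sample median. Zero for constant windows and for exact
#' linear ramps; positive when the window ends in a rise steeper than its
#' earlier portion, which is what makes it sensitive to the leading edge of a
#' hot-flash sweat response.
#'
#' @param values Numeric vector of conductance values at 1 Hz (uS).
#' @return The integral in uS.s.
#' @export
compute_msi <- function(values) {
  sum(values - stats::median(values))
}

#' Fit a biexponential curve to one window
#'
#' Models the window's minimum-subtracted conductance `yn = y - min(y)` as
#' `A * exp(B * x^2 + C * x)` on the uniform grid `x` in `[0, 1]` (x = 0 the
#' first sample, x = 1 the last), by Levenberg-Marquardt nonlinear least
#' squares with analytic Jacobian. Start values are `A = max(yn)` (floored at
#' a small positive value), `B = C = 0`, with the bound `A >= 1e-9`; if the
#' first attempt stalls, a small deterministic grid of alternative `(B, C)`
#' starts is tried and the lowest residual fit kept. A flat window
#' (`yn` identically 0) or solver failure yields `converged = FALSE`.
#'
#' @param values Numeric vector, the window's conductance samples.
#' @param ptol,ftol Convergence tolerances on parameters and objective.
#' @param maxiter Iteration cap per start.
#' @param normalize If `TRUE` (the pipeline default), subtract the window
#'   minimum before fitting (`yn = y - min(y)`). Pass `FALSE` when `values`
#'   is already a normalized signal, e.g. when checking parameter recovery
#'   on model-generated curves (whose minimum is not zero, so a second
#'   subtraction would shift them out of the model family).
#' @return A list of class `biexp_fit` with elements `A`, `B`, `C`,
#'   `converged`, `rss` and `n` (window length).
#' @export
fit_biexponential <- function(values, ptol = 1e-10, ftol = 1e-10,
                              maxiter = 1024, normalize = TRUE) {
  n <- length(values)
  yn <- if (normalize) values - min(values) else values
  out <- list(A = NA_real_, B = NA_real_, C = NA_real_,
              converged = FALSE, rss = NA_real_, n = n)
  class(out) <- "biexp_fit"
  if (n < 4L || all(yn == 0)) return(out)
  x <- seq(0, 1, length.out = n)
  x2 <- x^2
  resid_fn <- function(p) yn - p[1] * exp(p[2] * x2 + p[3] * x)
  jac_fn <- function(p) {
    g <- exp(p[2] * x2 + p[3] * x)
    -cbind(g, p[1] * x2 * g, p[1] * x * g)
  }
  ctrl <- minpack.lm::nls.lm.control(ptol = ptol, ftol = ftol,
                                     maxiter = maxiter)
  try_fit <- function(start) {
    r <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                         lower = c(1e-9, -Inf, -Inf), control = ctrl),
      error = function(e) NULL)
    if (is.null(r) || !(r$info %in% 1:4)) return(NULL)
    list(par = r$par, rss = sum(r$fvec^2))
  }
  A0 <- max(max(yn), 1e-9)
  ss <- sum(yn^2)
  best <- try_fit(c(A = A0, B = 0, C = 0))
  # fall back to a small deterministic start grid when the canonical start
  # fails or leaves a poor fit (local minimum on steep windows)
  if (is.null(best) || best$rss > 1e-4 * ss) {
    for (bc in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 1), c(1, -1))) {
      f <- try_fit(c(A = A0, B = bc[1], C = bc[2]))
      if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
      if (!is.null(best) && best$rss <= 1e-12 * max(1, ss)) break
    }
  }
  if (is.null(best)) return(out)
  out$A <- unname(best$par[1]); out$B <- unname(best$par[2])
  out$C <- unname(best$par[3])
  out$rss <- best$rss; out$converged <- TRUE
  out
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<biexp_fit> A=%.4g B=%.4g C=%.4g (rss %.3g, n=%d)\n",
                x$A, x$B, x$C, x$rss, x$n))
  } else {
    cat("<biexp_fit> not converged (flat or degenerate window)\n")
  }
  invisible(x)
}

#' Derivative features of a fitted biexponential
#'
#' With `g(x) = exp(B x^2 + C x)` the fitted curve `y = A g(x)` has
#' `y' = A (2Bx + C) g(x)` and `y'' = A ((2Bx + C)^2 + 2B) g(x)`. The six
#' features are the minima and maxima of `y'`, `y''` and `y' * y''` over the
#' same uniform grid on `[0, 1]` the fit used (grid extrema, not analytic
#' root-finding; a denser grid can be requested for cross-checks). A
#' non-converged fit yields all six features 0 with `degenerate = TRUE`.
#'
#' @param fit A [fit_biexponential] result.
#' @param grid_n Number of grid points (defaults to the fitted window length).
#' @return Named numeric vector `d1min, d1max, d2min, d2max, d1d2min, d1d2max`
#'   with attribute `degenerate`.
#' @export
curvefit_features <- function(fit, grid_n = fit$n) {
  nm <- c("d1min", "d1max", "d2min", "d2max", "d1d2min", "d1d2max")
  if (!isTRUE(fit$converged)) {
    out <- stats::setNames(rep(0, 6L), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  x <- seq(0, 1, length.out = grid_n)
  lin <- 2 * fit$B * x + fit$C
  g <- exp(fit$B * x^2 + fit$C * x)
  d1 <- fit$A * lin * g
  d2 <- fit$A * (lin^2 + 2 * fit$B) * g
  d12 <- d1 * d2
  out <- c(d1min = min(d1), d1max = max(d1),
           d2min = min(d2), d2max = max(d2),
           d1d2min = min(d12), d1d2max = max(d12))
  attr(out, "degenerate") <- FALSE
  out
}

#' Available feature names and their default window configurations
#'
#' `msi` uses 30 s windows; the six curvefit features use 60 s windows. All
#' default to a 5 s step. These window/step combinations were the
#' best-performing ones in the source study's sensitivity analysis.
#'
#' @export
hf_feature_names <- function() {
  c("msi", "d1min", "d1max", "d2min", "d2max", "d1d2min", "d1d2max")
}

#' @rdname hf_feature_names
#' @param feature A feature name.
#' @export
default_window <- function(feature) {
  feature <- match.arg(feature, hf_feature_names())
  if (feature == "msi") c(length_s = 30, step_s = 5) else c(length_s = 60, step_s = 5)
}

#' Compute feature values for a set of windows
#'
#' Applies [compute_msi] and/or the curvefit family to every window. The
#' biexponential is fitted once per window and shared by all six curvefit
#' features.
#'
#' @param windows An [hf_windows] object.
#' @param features Character vector of feature names (see [hf_feature_names]).
#' @return A `data.frame` with `end_s`, one column per feature, and a logical
#'   `degenerate` column marking windows whose curve fit did not converge
#'   (curvefit features are 0 there).
#' @export
compute_features <- function(windows, features = hf_feature_names()) {
  stopifnot(inherits(windows, "hf_windows"))
  features <- match.arg(features, hf_feature_names(), several.ok = TRUE)
  n <- length(windows$end_s)
  out <- data.frame(end_s = windows$end_s)
  curve_feats <- setdiff(features, "msi")
  if ("msi" %in% features) {
    out$msi <- apply(windows$values, 1L, compute_msi)
  }
  degenerate <- rep(FALSE, n)
  if (length(curve_feats) > 0L) {
    vals <- matrix(0, n, 6L,
                   dimnames = list(NULL, c("d1min", "d1max", "d2min", "d2max",
                                           "d1d2min", "d1d2max")))
    for (i in seq_len(n)) {
      fit <- fit_biexponential(windows$values[i, ])
      f <- curvefit_features(fit)
      vals[i, ] <- f
      degenerate[i] <- attr(f, "degenerate")
    }
    for (cf in curve_feats) out[[cf]] <- vals[, cf]
  }
  out$degenerate <- degenerate
  out
}

#' Extract one feature as a time series over a whole trace
#'
#' Convenience wrapper: generates windows at the feature's default (or given)
#' window length and step, then computes the feature per window. Gaps in the
#' trace propagate as missing windows.
#'
#' @param trace An [sc_trace] at 1 Hz.
#' @param feature Feature name.
#' @param window_length_s,step_s Overrides of [default_window].
#' @return A `data.frame` with `end_s`, `value` and `degenerate`.
#' @export
extract_feature_series <- function(trace, feature,
                                   window_length_s = NULL, step_s = NULL) {
  feature <- match.arg(feature, hf_feature_names())
  dw <- default_window(feature)
  if (is.null(window_length_s)) window_length_s <- dw[["length_s"]]
  if (is.null(step_s)) step_s <- dw[["step_s"]]
  w <- generate_windows(trace, window_length_s, step_s)
  ft <- compute_features(w, feature)
  data.frame(end_s = ft$end_s, value = ft[[feature]],
             degenerate = ft$degenerate)
}

#' @export
write_feature_table <- function(features, path) {
  df <- features
  for (nm in setdiff(names(df), "degenerate")) df[[nm]] <- format_num(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
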