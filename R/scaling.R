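#' Feature scaling chain fitted on training data only
#'
#' Four stages, all parameterized exclusively by the training values:
#'
#' 1. a monotone normality transform chosen from a small fixed family
#'    (identity, signed log, cube root, arcsinh) by minimizing the absolute
#'    sample skewness of the transformed training data, with identity
#'    preferred on ties;
#' 2. robust scaling: subtract the training median, divide by the training
#'    IQR (linear-interpolation quartiles);
#' 3. `atan` to bound the range to `(-pi/2, pi/2)`;
#' 4. standardization by the post-arctan training mean and SD.
#'
#' If the training IQR is zero the robust stage degrades to median removal
#' only; if the post-arctan SD is zero the final stage degrades to mean
#' removal. Both degradations set the `degenerate` flag. Test data are scaled
#' with [apply_scaler] using these frozen parameters and never contribute
#' statistics.
#'
#' @param train_values Numeric vector of at least 10 finite training values.
#' @return A list of class `hf_scaler`.
#' @export
fit_scaler <- function(train_values) {
  x <- train_values[is.finite(train_values)]
  if (length(x) < 10L) {
    stop_data("fit_scaler needs at least 10 finite training values")
  }
  sk <- vapply(names(normality_transforms()), function(id) {
    abs(sample_skewness(normality_transforms()[[id]](x)))
  }, 0)
  sk[!is.finite(sk)] <- Inf
  best <- min(sk)
  # tie-break toward the earliest family member (identity first)
  transform_id <- names(sk)[which(sk <= best + 1e-6)[1L]]
  tx <- normality_transforms()[[transform_id]](x)
  med <- unname(stats::quantile(tx, 0.5, type = 7))
  q <- unname(stats::quantile(tx, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  degenerate <- FALSE
  if (!(iqr > 0)) { iqr <- 1; degenerate <- TRUE }
  z <- atan((tx - med) / iqr)
  post_mean <- mean(z)
  post_sd <- stats::sd(z)
  if (!(post_sd > 0)) { post_sd <- 1; degenerate <- TRUE }
  structure(list(transform_id = transform_id, train_median = med,
                 train_iqr = iqr, post_arctan_mean = post_mean,
                 post_arctan_sd = post_sd, degenerate = degenerate,
                 n_train = length(x)),
            class = "hf_scaler")
}

#' @rdname fit_scaler
#' @param values Numeric vector to scale (train or test).
#' @param scaler A fitted `hf_scaler`.
#' @return Scaled values; non-finite inputs propagate as `NA`.
#' @export
apply_scaler <- function(values, scaler) {
  stopifnot(inherits(scaler, "hf_scaler"))
  out <- rep(NA_real_, length(values))
  ok <- is.finite(values)
  tx <- normality_transforms()[[scaler$transform_id]](values[ok])
  z <- atan((tx - scaler$train_median) / scaler$train_iqr)
  out[ok] <- (z - scaler$post_arctan_mean) / scaler$post_arctan_sd
  out
}

#' @export
print.hf_scaler <- function(x, ...) {
  cat(sprintf(
    "<hf_scaler> transform=%s median=%.4g IQR=%.4g post-arctan mean=%.4g sd=%.4g%s\n",
    x$transform_id, x$train_median, x$train_iqr,
    x$post_arctan_mean, x$post_arctan_sd,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

normality_transforms <- function() {
  list(
    identity = function(v) v,
    signed_log = function(v) sign(v) * log1p(abs(v)),
    cube_root = function(v) sign(v) * abs(v)^(1 / 3),
    arcsinh = function(v) asinh(v)
  )
}

sample_skewness <- function(v) {
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 == 0) return(0)
  mean((v - m)^3) / s2^1.5
}
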