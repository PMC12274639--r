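#' Fit a three-class hot-flash window classifier
#'
#' The central model of the package: a univariate multinomial logistic
#' regression on one scaled window feature, predicting the window classes
#' 0 (non-HF), 1 (HF onset proximity) and 2 (late HF). The feature is passed
#' through the train-fitted scaling chain ([fit_scaler]) before the logistic
#' fit, and the fitted object freezes both the scaler parameters and the
#' logistic coefficients, so prediction on new sessions uses training
#' statistics only.
#'
#' Optimization uses an L2 (ridge) penalty with iteration cap `maxit` and a
#' fixed RNG seed for the coefficient initialization, making refits
#' bit-for-bit reproducible. Class weights implement cost-sensitive training:
#' up-weighting Class 1 penalizes missed pre-onset windows more than missed
#' late-HF windows.
#'
#' @param formula A formula `label ~ feature` naming the label column and a
#'   single feature column of `data`.
#' @param data A `data.frame` holding the label (values in `0, 1, 2`, or the
#'   factor produced by [label_windows] — `excluded` rows are dropped) and
#'   the feature. Rows with non-finite feature values are dropped.
#' @param lambda L2 penalty strength (weight decay; the default 0.5 matches
#'   the conventional unit-strength ridge of common logistic solvers).
#' @param class_weights Named numeric vector of per-class costs, e.g.
#'   `c("0" = 1, "1" = 2, "2" = 1)`.
#' @param seed RNG seed for reproducible coefficient initialization.
#' @param maxit Iteration cap for the optimizer.
#' @return An object of class `hf_model` with `print`, `summary`, `coef` and
#'   `predict` methods.
#' @examples
#' set.seed(1)
#' d <- data.frame(label = rep(c(0, 1, 2), each = 100),
#'                 msi = rnorm(300, rep(c(-3, 0, 3), each = 100), 0.5))
#' m <- hf_fit(label ~ msi, d)
#' table(predict(m, d), d$label)
#' @export
hf_fit <- function(formula, data, lambda = 0.5,
                   class_weights = c("0" = 1, "1" = 1, "2" = 1),
                   seed = 10, maxit = 10000) {
  vars <- all.vars(formula)
  if (length(vars) != 2L) {
    stop_data("hf_fit expects a univariate formula of the form label ~ feature")
  }
  label_col <- vars[1L]; feature <- vars[2L]
  if (!all(c(label_col, feature) %in% names(data))) {
    stop_data(sprintf("data must contain columns '%s' and '%s'",
                      label_col, feature))
  }
  lab <- as.character(data[[label_col]])
  keep <- lab %in% c("0", "1", "2") & is.finite(data[[feature]])
  lab <- factor(lab[keep], levels = c("0", "1", "2"))
  xraw <- data[[feature]][keep]
  missing_cls <- setdiff(c("0", "1", "2"), unique(as.character(lab)))
  if (length(missing_cls) > 0L) {
    stop_data(sprintf("training data lack class(es): %s",
                      paste(missing_cls, collapse = ", ")))
  }
  scaler <- fit_scaler(xraw)
  s <- apply_scaler(xraw, scaler)
  w <- unname(class_weights[as.character(lab)])
  if (anyNA(w)) stop_data("class_weights must name classes 0, 1 and 2")
  df <- data.frame(.label = lab, .s = s, .w = w)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  fit <- nnet::multinom(.label ~ .s, data = df, weights = .w,
                        decay = lambda, maxit = maxit, trace = FALSE)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  cf <- stats::coef(fit)           # 2 x 2: rows classes 1,2; cols intercept, slope
  structure(
    list(feature = feature, scaler = scaler,
         coefficients = matrix(as.numeric(cf), 2L, 2L,
                               dimnames = list(c("1", "2"),
                                               c("(Intercept)", "scaled"))),
         lambda = lambda, class_weights = class_weights,
         seed = seed, maxit = maxit, n_train = nrow(df),
         train_class_counts = table(lab),
         call = match.call()),
    class = "hf_model"
  )
}

#' @export
print.hf_model <- function(x, ...) {
  cat(sprintf("<hf_model> univariate multinomial logistic on '%s'\n", x$feature))
  cat(sprintf("  trained on %d windows (class counts: %s)\n", x$n_train,
              paste(sprintf("%s=%d", names(x$train_class_counts),
                            as.integer(x$train_class_counts)), collapse = ", ")))
  cat(sprintf("  scaler: %s transform; L2 penalty %g; seed %d\n",
              x$scaler$transform_id, x$lambda, x$seed))
  invisible(x)
}

#' @export
summary.hf_model <- function(object, ...) {
  print(object)
  cat("  coefficients (log-odds vs class 0):\n")
  print(round(object$coefficients, 5))
  cat("  class weights:",
      paste(sprintf("%s=%g", names(object$class_weights),
                    object$class_weights), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.hf_model <- function(object, ...) object$coefficients

#' Predict window classes or class probabilities
#'
#' Applies the frozen scaler then the softmax over the stored logistic
#' coefficients. Windows with missing or non-finite feature values are
#' assigned class 0 (non-HF) and flagged via the `"imputed"` attribute;
#' their probability rows are `NA` when `type = "prob"`.
#'
#' @param object An [hf_fit] model.
#' @param newdata A `data.frame` containing the model's feature column, or a
#'   numeric vector of raw feature values.
#' @param type `"class"` (default) for hard labels, `"prob"` for the
#'   three-column probability matrix.
#' @param ... Unused.
#' @export
predict.hf_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (is.data.frame(newdata)) {
    if (!object$feature %in% names(newdata)) {
      stop_data(sprintf("newdata lacks feature column '%s'", object$feature))
    }
    newdata[[object$feature]]
  } else {
    as.numeric(newdata)
  }
  s <- apply_scaler(x, object$scaler)
  n <- length(s)
  eta <- cbind(0,
               object$coefficients["1", 1] + object$coefficients["1", 2] * s,
               object$coefficients["2", 1] + object$coefficients["2", 2] * s)
  m <- apply(eta, 1L, max)
  p <- exp(eta - m)
  p <- p / rowSums(p)
  colnames(p) <- c("0", "1", "2")
  imputed <- !is.finite(s)
  if (type == "prob") {
    p[imputed, ] <- NA_real_
    attr(p, "imputed") <- imputed
    return(p)
  }
  cls <- c("0", "1", "2")[max.col(p, ties.method = "first")]
  cls[imputed] <- "0"
  out <- factor(cls, levels = c("0", "1", "2"))
  attr(out, "imputed") <- imputed
  out
}

#' Save / load a fitted model as a JSON artifact
#'
#' The artifact stores the scaler parameters, logistic coefficients and
#' training configuration in plain text with full numeric precision, so a
#' reloaded model reproduces predictions to machine precision.
#'
#' @param model An `hf_model`.
#' @param path JSON file path.
#' @export
write_hf_model <- function(model, path) {
  obj <- list(
    feature = model$feature,
    scaler = unclass(model$scaler),
    coefficients = list(class1 = as.numeric(model$coefficients["1", ]),
                        class2 = as.numeric(model$coefficients["2", ])),
    lambda = model$lambda,
    class_weights = as.list(model$class_weights),
    seed = model$seed, maxit = model$maxit, n_train = model$n_train
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_hf_model
#' @export
read_hf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- obj$scaler
  class(scaler) <- "hf_scaler"
  cw <- unlist(obj$class_weights)
  structure(
    list(feature = obj$feature, scaler = scaler,
         coefficients = matrix(c(obj$coefficients$class1,
                                 obj$coefficients$class2),
                               2L, 2L, byrow = TRUE,
                               dimnames = list(c("1", "2"),
                                               c("(Intercept)", "scaled"))),
         lambda = obj$lambda, class_weights = cw,
         seed = obj$seed, maxit = obj$maxit, n_train = obj$n_train,
         train_class_counts = NULL, call = NULL),
    class = "hf_model"
  )
}
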