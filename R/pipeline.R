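#' End-to-end run configuration
#'
#' Bundles everything a reproducible run needs: the synthetic cohort
#' settings, the participant-level train/test split, the features to model,
#' window and labeling parameters, and the classifier configuration. A run
#' replayed from the same configuration is byte-identical.
#'
#' @param synth A [synth_config] for the cohort (its `seed` drives all
#'   randomness in the run).
#' @param n_participants,visits_per_participant Cohort size (defaults 12 x 3).
#' @param n_test_typical,n_test_atypical Held-out participants per pattern
#'   (defaults 3 + 3, leaving the rest for training).
#' @param features Feature names to fit, one univariate model each.
#' @param window_length_s,step_s Optional overrides of the per-feature
#'   [default_window]; `NULL` keeps the defaults.
#' @param train_scheme,test_scheme [label_scheme]s (defaults reproduce the
#'   train/test labeling rules).
#' @param lambda,class_weights,model_seed,maxit Classifier settings, see
#'   [hf_fit].
#' @param pre_s,post_s Event candidate interval for [event_outcomes].
#' @param out_dir Optional directory for reports and artifacts.
#' @return A list of class `hf_run_config`.
#' @export
hf_run_config <- function(synth = synth_config(duration_h = 2),
                          n_participants = 12,
                          visits_per_participant = 3,
                          n_test_typical = 3,
                          n_test_atypical = 3,
                          features = c("msi", "d2max"),
                          window_length_s = NULL,
                          step_s = NULL,
                          train_scheme = label_scheme("train"),
                          test_scheme = label_scheme("test"),
                          lambda = 0.5,
                          class_weights = c("0" = 1, "1" = 1, "2" = 1),
                          model_seed = 10,
                          maxit = 10000,
                          pre_s = 60, post_s = 30,
                          out_dir = NULL) {
  features <- match.arg(features, hf_feature_names(), several.ok = TRUE)
  cfg <- list(synth = synth, n_participants = n_participants,
              visits_per_participant = visits_per_participant,
              n_test_typical = n_test_typical,
              n_test_atypical = n_test_atypical,
              features = features,
              window_length_s = window_length_s, step_s = step_s,
              train_scheme = train_scheme, test_scheme = test_scheme,
              lambda = lambda, class_weights = class_weights,
              model_seed = model_seed, maxit = maxit,
              pre_s = pre_s, post_s = post_s, out_dir = out_dir)
  n_typ <- ceiling(n_participants / 2)
  if (n_test_typical > n_typ || n_test_atypical > n_participants - n_typ) {
    stop_data("test split requests more participants than the cohort holds")
  }
  if (n_test_typical + n_test_atypical >= n_participants) {
    stop_data("no participants left for training")
  }
  class(cfg) <- "hf_run_config"
  cfg
}

window_params_for <- function(config, feature) {
  dw <- default_window(feature)
  c(length_s = if (is.null(config$window_length_s)) dw[["length_s"]]
               else config$window_length_s,
    step_s = if (is.null(config$step_s)) dw[["step_s"]] else config$step_s)
}

#' Run the full prediction pipeline on a synthetic cohort
#'
#' Simulates the cohort, holds out test participants (balanced across
#' typical and atypical morphology; the last participants of each pattern
#' block), labels training sessions under the train scheme and test sessions
#' under the test scheme, extracts features (training features only for
#' non-excluded windows), fits one [hf_fit] model per feature on the pooled
#' training windows, predicts every test window, and evaluates per 48-h-
#' session with [session_metrics]. Reports are stratified three ways: all
#' test sessions, typical-pattern only, atypical-pattern only.
#'
#' @param config An [hf_run_config].
#' @param cohort Optionally a pre-simulated [simulate_cohort] result (used by
#'   [sensitivity_sweep] to share one simulation across configurations).
#' @return A list of class `hf_run`: `models` (per feature), `sessions`
#'   (per-session, per-feature evaluation rows), `aggregates` (per feature x
#'   stratum), `split`, and `config`.
#' @export
run_hf_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "hf_run_config"))
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$synth, config$n_participants,
                              config$visits_per_participant)
  }
  parts <- cohort$participants
  test_ids <- c(utils::tail(parts$participant_id[parts$pattern == "typical"],
                            config$n_test_typical),
                utils::tail(parts$participant_id[parts$pattern == "atypical"],
                            config$n_test_atypical))
  train_ids <- setdiff(parts$participant_id, test_ids)
  is_test <- vapply(cohort$sessions,
                    function(s) s$trace$participant_id %in% test_ids, TRUE)

  models <- list()
  session_rows <- list()
  for (feature in config$features) {
    wp <- window_params_for(config, feature)
    # ---- train: pooled labeled windows from train participants ----
    train_tabs <- lapply(cohort$sessions[!is_test], function(s) {
      ev <- confirmed_events(s$true_events)
      rej <- rejected_events(s$true_events)
      ns <- s$true_events[s$true_events$status == "night_sweat", , drop = FALSE]
      w_all <- generate_windows(s$trace, wp[["length_s"]], wp[["step_s"]])
      lab <- label_windows(w_all, ev, config$train_scheme, rejected = rej,
                           night_sweats = ns)
      keep <- lab$label != "excluded"
      if (!any(keep)) return(NULL)
      w_kept <- generate_windows(s$trace, wp[["length_s"]], wp[["step_s"]],
                                 ends = lab$end_s[keep])
      ft <- compute_features(w_kept, feature)
      ft$label <- lab$label[keep][match(ft$end_s, lab$end_s[keep])]
      ft
    })
    train_df <- do.call(rbind, Filter(Negate(is.null), train_tabs))
    model <- hf_fit(stats::as.formula(paste("label ~", feature)), train_df,
                    lambda = config$lambda,
                    class_weights = config$class_weights,
                    seed = config$model_seed, maxit = config$maxit)
    models[[feature]] <- model
    # ---- test: whole-session prediction and evaluation ----
    for (s in cohort$sessions[is_test]) {
      ev <- confirmed_events(s$true_events)
      ns <- s$true_events[s$true_events$status == "night_sweat", , drop = FALSE]
      w <- generate_windows(s$trace, wp[["length_s"]], wp[["step_s"]])
      ft <- compute_features(w, feature)
      lab <- label_windows(w, ev, config$test_scheme, night_sweats = ns)
      pred <- predict(model, ft)
      row <- session_metrics(pred, lab$label, ft$end_s, ev,
                             session_id = paste(s$trace$participant_id,
                                                s$trace$session_id, sep = "_"),
                             pre_s = config$pre_s, post_s = config$post_s)
      row$feature <- feature
      row$participant_id <- s$trace$participant_id
      row$pattern <- s$config$pattern
      session_rows[[length(session_rows) + 1L]] <- row
    }
  }
  sessions <- do.call(rbind, session_rows)
  strata <- list(all = rep(TRUE, nrow(sessions)),
                 typical = sessions$pattern == "typical",
                 atypical = sessions$pattern == "atypical")
  aggregates <- list()
  for (feature in config$features) {
    for (st in names(strata)) {
      sel <- sessions$feature == feature & strata[[st]]
      if (!any(sel)) next
      agg <- aggregate_sessions(sessions[sel, , drop = FALSE])
      agg$feature <- feature
      agg$stratum <- st
      aggregates[[paste(feature, st, sep = ".")]] <- agg
    }
  }
  run <- structure(
    list(models = models, sessions = sessions,
         aggregates = do.call(rbind, aggregates),
         split = list(train = train_ids, test = test_ids),
         config = config),
    class = "hf_run"
  )
  if (!is.null(config$out_dir)) write_hf_run(run, config$out_dir)
  run
}

#' @export
print.hf_run <- function(x, ...) {
  cat(sprintf("<hf_run> features: %s; train %d / test %d participants\n",
              paste(x$config$features, collapse = ", "),
              length(x$split$train), length(x$split$test)))
  agg <- x$aggregates
  for (feature in unique(agg$feature)) {
    for (st in unique(agg$stratum)) {
      a <- agg[agg$feature == feature & agg$stratum == st, ]
      if (nrow(a) == 0) next
      cat(sprintf("  %s [%s]: ", feature, st))
      cat(paste(sprintf("%s=%.3f", a$measure, a$mean), collapse = " "), "\n")
    }
  }
  invisible(x)
}

#' Write run reports
#'
#' Per-session CSV (one row per session and feature, all nine measures plus
#' confusion counts) and an aggregate JSON of mean/SD per measure, feature
#' and stratum, plus model artifacts and the echoed configuration. Output is
#' deterministic: replaying a run from its stored configuration reproduces
#' the files byte for byte.
#'
#' @param run An [run_hf_pipeline] result.
#' @param dir Output directory.
#' @export
write_hf_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sess <- run$sessions
  num <- vapply(sess, is.numeric, TRUE)
  sess[num] <- lapply(sess[num], function(v) format_num(v))
  utils::write.csv(sess, file.path(dir, "sessions.csv"),
                   row.names = FALSE, quote = FALSE)
  agg <- run$aggregates
  agg_list <- lapply(split(agg, paste(agg$feature, agg$stratum, sep = ".")),
                     function(a) {
                       stats::setNames(
                         lapply(seq_len(nrow(a)), function(i) {
                           list(mean = a$mean[i], sd = a$sd[i],
                                n_sessions = a$n_sessions[i])
                         }), a$measure)
                     })
  jsonlite::write_json(agg_list, file.path(dir, "aggregates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (feature in names(run$models)) {
    write_hf_model(run$models[[feature]],
                   file.path(dir, sprintf("model_%s.json", feature)))
  }
  cfg <- run$config
  cfg$train_scheme <- unclass(cfg$train_scheme)
  cfg$test_scheme <- unclass(cfg$test_scheme)
  cfg$synth <- unclass(cfg$synth)
  cfg$class_weights <- as.list(cfg$class_weights)
  cfg$out_dir <- NULL   # echoed config describes the run, not its location
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Sensitivity sweep over window and labeling parameters
#'
#' Re-runs segmentation, feature extraction, training and evaluation for
#' every combination of window length, step and Class 1 pre/post onset
#' bounds, reusing a single simulated cohort. Each configuration contributes
#' one row per feature and stratum with the aggregate measures; a
#' configuration that fails downstream is marked failed and the sweep
#' continues.
#'
#' @param config Base [hf_run_config].
#' @param window_lengths_s,steps_s Grids (defaults 30/45/60 and 2/5).
#' @param class1_bounds List of `c(pre, post)` offsets for the train-scheme
#'   Class 1 zone (default just the standard `c(-30, 120)`).
#' @return A `data.frame`, one row per configuration x feature x stratum.
#' @export
sensitivity_sweep <- function(config,
                              window_lengths_s = c(30, 45, 60),
                              steps_s = c(2, 5),
                              class1_bounds = list(c(-30, 120))) {
  cohort <- simulate_cohort(config$synth, config$n_participants,
                            config$visits_per_participant)
  rows <- list()
  for (wl in window_lengths_s) for (st in steps_s) for (cb in class1_bounds) {
    cfg <- config
    cfg$window_length_s <- wl
    cfg$step_s <- st
    cfg$train_scheme <- label_scheme("train", class1 = cb)
    res <- tryCatch(run_hf_pipeline(cfg, cohort = cohort),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        window_length_s = wl, step_s = st,
        class1_pre = cb[1], class1_post = cb[2],
        feature = NA_character_, stratum = NA_character_,
        measure = NA_character_, mean = NA_real_, sd = NA_real_,
        n_sessions = NA_integer_, failed = TRUE,
        error = conditionMessage(res))
      next
    }
    agg <- res$aggregates
    agg$window_length_s <- wl
    agg$step_s <- st
    agg$class1_pre <- cb[1]
    agg$class1_post <- cb[2]
    agg$failed <- FALSE
    agg$error <- ""
    rows[[length(rows) + 1L]] <- agg[, c("window_length_s", "step_s",
                                         "class1_pre", "class1_post",
                                         "feature", "stratum", "measure",
                                         "mean", "sd", "n_sessions",
                                         "failed", "error")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
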