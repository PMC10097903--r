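log_line <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%OS2"), stage, msg))
}

#' Simulate a cohort of session logs to disk
#'
#' Builds the cohort described by `config`, simulates one dual-task session
#' per participant and writes each as a plain-text directory under `out_dir`,
#' together with `manifest.csv` recording the per-session seeds.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return The manifest data frame, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- build_cohort(config$n_participants, config$score_mean,
                         config$score_sd, seed = config$seed)
  seeds <- derive_seeds(config$seed + 1L, max(config$n_participants, 1L))
  for (i in seq_len(nrow(cohort))) {
    log <- simulate_session(cohort[i, ], config$street, config$task,
                            config$model, seed = seeds[i])
    write_session_log(log, file.path(out_dir, cohort$participant_id[i]))
    if (!quiet) log_line("simulate", cohort$participant_id[i])
  }
  manifest <- cbind(cohort, session_seed = seeds[seq_len(nrow(cohort))])
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Extract the feature table from a directory of session logs
#'
#' Reads every participant directory under `log_dir` and assembles the
#' 68-feature row per participant. A corrupt log produces a warning for that
#' participant and the run continues; the failed ids are attached as the
#' `"failures"` attribute.
#'
#' @param log_dir Directory produced by [cmd_simulate()].
#' @param out_file Optional CSV path for the feature table.
#' @param quiet Suppress progress messages.
#' @return The feature table (un-imputed; `NA` marks undefined slots).
#' @export
cmd_extract <- function(log_dir, out_file = NULL, quiet = TRUE) {
  dirs <- list.dirs(log_dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "meta"))]
  rows <- list()
  failures <- character()
  for (d in dirs) {
    row <- tryCatch({
      log <- read_session_log(d)
      fv <- assemble_feature_vector(log)
      cbind(data.frame(participant_id = log$profile$participant_id,
                       true_score = log$profile$true_score),
            as.data.frame(as.list(fv), check.names = FALSE))
    }, error = function(e) {
      warning("skipping ", basename(d), ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(row)) failures <- c(failures, basename(d)) else
      rows[[length(rows) + 1L]] <- row
    if (!quiet) log_line("extract", basename(d))
  }
  if (!length(rows)) {
    warning("no readable session logs under ", log_dir)
    tbl <- data.frame(participant_id = character(), true_score = numeric())
  } else {
    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
  }
  if (!is.null(out_file)) write_feature_table(tbl, out_file)
  attr(tbl, "failures") <- failures
  tbl
}

#' Run the full statistical and model analysis of a feature table
#'
#' Imputes missing slots, writes the 68-row correlation screening report, and
#' evaluates every configured regressor x feature-subset combination under
#' leave-one-subject-out cross-validation, writing per-model prediction
#' tables, a combined summary, and (for `"rfe"` mode) selection-frequency
#' tables.
#'
#' @param tbl A feature table or a path to one.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for the report files.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the correlation table, screening result and
#'   all `eval_result` objects.
#' @export
cmd_analyze <- function(tbl, config = pipeline_config(), out_dir,
                        quiet = TRUE) {
  if (is.character(tbl)) tbl <- read_feature_table(tbl)
  if (nrow(tbl) < 3) stop("analysis needs at least 3 participants")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tbl <- impute_feature_table(tbl)

  corr <- build_correlation_table(tbl, config$r_threshold, config$alpha)
  write_correlation_report(corr, file.path(out_dir, "correlations.csv"))
  scr <- screen_features(corr, config$r_threshold, config$alpha)
  writeLines(c(sprintf("flagged_features=%d", scr$count), scr$flagged),
             file.path(out_dir, "screening.txt"))
  if (!quiet) log_line("analyze", sprintf("screening: %d flagged", scr$count))

  evals <- list()
  summary_rows <- list()
  for (kind in config$models) {
    for (mode in config$modes) {
      key <- paste(kind, mode, sep = "_")
      spec <- model_spec(kind, seed = config$seed)
      ev <- loso_evaluate(tbl, spec, mode = mode, rfe_k = config$rfe_k)
      evals[[key]] <- ev
      write.csv(ev$predictions,
                file.path(out_dir, paste0("predictions_", key, ".csv")),
                row.names = FALSE)
      if (identical(mode, "rfe"))
        write.csv(selection_frequency(ev$fold_features),
                  file.path(out_dir, paste0("selection_frequency_", kind, ".csv")),
                  row.names = FALSE)
      summary_rows[[key]] <- data.frame(
        model = kind, mode = mode, mae = ev$mae, acc = ev$acc, cc = ev$cc,
        ba_bias = ev$bland_altman$bias, ba_lo = ev$bland_altman$lo,
        ba_hi = ev$bland_altman$hi)
      if (!quiet) log_line("analyze", sprintf("%s: MAE %.3f", key, ev$mae))
    }
  }
  write.csv(do.call(rbind, summary_rows),
            file.path(out_dir, "results_summary.csv"), row.names = FALSE)
  invisible(list(correlations = corr, screening = scr, evals = evals))
}

#' Build hand-auditable micro fixtures
#'
#' Writes a tiny, fully hand-constructed session log (5 Stroop events and 4
#' crossing attempts per block, 5 Hz sampling, three identical blocks) and a
#' companion `expected_features.csv` holding the hand-derived value of each of
#' the 17 per-block feature quantities. Used by the test suite as an
#' independent oracle for the feature-extraction pipeline.
#'
#' @param out_dir Output directory.
#' @return Invisibly, a list with the log path, the expected-value table and
#'   the in-memory `session_log`.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- fixture_session_log()
  log_path <- file.path(out_dir, log$profile$participant_id)
  write_session_log(log, log_path)
  expected <- fixture_expected_features()
  write.csv(expected, file.path(out_dir, "expected_features.csv"),
            row.names = FALSE)
  invisible(list(log_path = log_path, expected = expected, log = log))
}

# A fully hand-written micro session: every channel value is chosen so the 17
# feature quantities have simple closed-form values (see
# fixture_expected_features()).
fixture_session_log <- function() {
  street <- street_config(sample_rate = 5)
  task <- task_config(n_stimuli = 5, stim_duration = 2)
  stroop <- function(b) data.frame(
    dual_task = b, onset = c(0, 2, 4, 6, 8), condition = task$conditions[b],
    congruent = TRUE,
    response = c("match", "match", "mismatch", "timeout", "match"),
    correct = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    rt = c(0.8, 1.0, 1.2, NA, 0.6))
  attempts <- function(b) data.frame(
    dual_task = b,
    t_start = c(0, 4, 7, 9.5), t_move = c(0.1, 4.1, 7.1, 9.6),
    t_exit = c(2.5, 6.0, 8.6, 10.9), t_arrival = c(4.5, 7.0, 10.8, 11.0),
    t_end = c(3.0, 6.5, 9.0, 10.0),
    tsc = c(3.0, 2.5, 2.0, NA), ttc = c(2.0, 1.0, 2.2, NA),
    outcome = c("safe", "unsafe", "safe", "truncated"))
  tt <- seq(0, 9.8, by = 0.2)
  kin <- function(b) data.frame(
    dual_task = b, t = tt, x = rep(c(-0.1, 0.1), 25), y = 0,
    vx = rep(c(0.2, -0.2), 25), vy = c(rep(1.5, 30), rep(0, 20)))
  head_fun <- function(b) {
    yaw <- rep(10, 50)                       # ignored: inside attempts
    yaw[tt >= 3 & tt < 4] <- c(0, 45, 0, -45, 0)   # two >30 deg excursions
    yaw[tt >= 6.5 & tt < 7] <- 0
    yaw[tt >= 9 & tt < 9.5] <- 0
    data.frame(dual_task = b, t = tt, yaw = yaw, pitch = 0)
  }
  blocks <- lapply(1:3, function(b) {
    list(dual_task = b, condition = task$conditions[b], duration = 10,
         stroop = stroop(b), kinematics = kin(b), head = head_fun(b),
         attempts = attempts(b), gaps = c(4.5, 2.5, 3.8, 0.2))
  })
  structure(list(
    profile = list(participant_id = "P_FIX", true_score = 12, latent_z = 0,
                   age = 23),
    street = street, task = task, blocks = blocks),
    class = "session_log")
}

# Hand-derived expected values for the fixture session (identical per block):
#   CNST: 3 of 5 events correct (the timeout counts incorrect)
#   RTST: mean(0.8, 1.0, 1.2, 0.6) = 0.9 (timeout excluded)
#   NSC/NUC/NA: safe TTCs 2.0 and 2.2 (> 1.5), unsafe 1.0; truncated excluded
#   TSC: mean(3.0, 2.5, 2.0) = 2.5; extremes 3.0 / 2.0
#   TTC: mean over safe = mean(2.0, 2.2) = 2.1
#   SDX: x alternates +/-0.1 over 50 samples -> sqrt(50 * 0.01 / 49)
#   ETPX: two equally occupied 0.1 m bins -> 1 bit
#   MVX: mean of +/-0.2 alternation = 0; SDVX = sqrt(50 * 0.04 / 49)
#   MVY: (30 * 1.5) / 50 = 0.9; SDVY = sqrt((30 * 0.6^2 + 20 * 0.9^2) / 49)
#   FN: pre-crossing yaw counts 8 at 0 deg, 1 at 45, 1 at -45 -> 64 + 1 + 1
#   HT: one excursion to +45 and one to -45 in the first waiting interval
fixture_expected_features <- function() {
  data.frame(
    quantity = FEATURE_QUANTITIES,
    value = c(CNST = 3, RTST = 0.9, NUC = 1, NSC = 2, "NA" = 3, TSC = 2.5,
              TSC_MAX = 3.0, TSC_MIN = 2.0, TTC = 2.1,
              SDX = sqrt(50 * 0.01 / 49), ETPX = 1, MVX = 0, MVY = 0.9,
              SDVX = sqrt(50 * 0.04 / 49),
              SDVY = sqrt((30 * 0.6^2 + 20 * 0.9^2) / 49), FN = 66, HT = 2))
}
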