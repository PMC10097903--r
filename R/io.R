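#' Write / read a session log as a plain-text directory
#'
#' A session log is stored as one directory per participant holding
#' `events.csv` (Stroop events), `kinematics.csv`, `head.csv`, `attempts.csv`,
#' `gaps.csv` and a `meta` file of `key=value` lines echoing the participant
#' profile and the street/task configuration. Timestamps are written with six
#' decimal places; a round trip reproduces every field to that precision.
#'
#' @param log A `session_log`.
#' @param path Directory to create/read (the participant directory itself).
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns a `session_log`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  meta <- c(
    sprintf("participant_id=%s", log$profile$participant_id),
    sprintf("true_score=%g", log$profile$true_score),
    sprintf("latent_z=%.10g", log$profile$latent_z),
    sprintf("age=%g", log$profile$age %||% NA),
    sprintf("street.%s=%g", names(unclass(log$street)), unlist(log$street)),
    sprintf("task.n_stimuli=%d", log$task$n_stimuli),
    sprintf("task.stim_duration=%g", log$task$stim_duration),
    sprintf("task.n_dual_tasks=%d", log$task$n_dual_tasks),
    sprintf("task.conditions=%s", paste(log$task$conditions, collapse = ",")))
  writeLines(meta, file.path(path, "meta"))

  bind <- function(field) do.call(rbind, lapply(log$blocks, `[[`, field))
  ev <- bind("stroop")
  ev$onset <- num(ev$onset); ev$rt <- num(ev$rt)
  write.csv(ev, file.path(path, "events.csv"), row.names = FALSE, quote = FALSE)

  kin <- bind("kinematics")
  for (cl in c("t", "x", "y", "vx", "vy")) kin[[cl]] <- num(kin[[cl]])
  write.csv(kin, file.path(path, "kinematics.csv"), row.names = FALSE,
            quote = FALSE)

  hd <- bind("head")
  for (cl in c("t", "yaw", "pitch")) hd[[cl]] <- num(hd[[cl]])
  write.csv(hd, file.path(path, "head.csv"), row.names = FALSE, quote = FALSE)

  at <- bind("attempts")
  for (cl in c("t_start", "t_move", "t_exit", "t_arrival", "t_end", "tsc",
               "ttc")) at[[cl]] <- num(at[[cl]])
  write.csv(at, file.path(path, "attempts.csv"), row.names = FALSE,
            quote = FALSE)

  gp <- do.call(rbind, lapply(log$blocks, function(b)
    data.frame(dual_task = b$dual_task, gap = num(b$gaps))))
  write.csv(gp, file.path(path, "gaps.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  need <- file.path(path, c("meta", "events.csv", "kinematics.csv", "head.csv",
                            "attempts.csv", "gaps.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("session log at ", path, " is missing: ",
         paste(basename(missing), collapse = ", "))
  kv <- strsplit(readLines(file.path(path, "meta")), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                   vapply(kv, `[[`, "", 1))
  mnum <- function(key) as.numeric(meta[[key]])
  profile <- list(participant_id = meta[["participant_id"]],
                  true_score = mnum("true_score"),
                  latent_z = mnum("latent_z"), age = mnum("age"))
  street <- street_config(
    roadway_width = mnum("street.roadway_width"),
    margin = mnum("street.margin"),
    vehicle_speed = mnum("street.vehicle_speed"),
    walk_speed = mnum("street.walk_speed"),
    safety_margin = mnum("street.safety_margin"),
    crossable_fraction = mnum("street.crossable_fraction"),
    sample_rate = mnum("street.sample_rate"))
  task <- task_config(
    n_stimuli = mnum("task.n_stimuli"),
    stim_duration = mnum("task.stim_duration"),
    n_dual_tasks = mnum("task.n_dual_tasks"),
    conditions = strsplit(meta[["task.conditions"]], ",")[[1]])

  read_tab <- function(file, numeric_cols, time_cols = character()) {
    df <- read.csv(file.path(path, file), stringsAsFactors = FALSE)
    for (cl in numeric_cols) {
      v <- df[[cl]]
      if (is.character(v)) v[v == ""] <- NA
      df[[cl]] <- as.numeric(v)
    }
    for (cl in time_cols) {
      bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
      if (length(bad))
        stop(sprintf("%s: negative timestamp in field '%s' at data line %d",
                     file, cl, bad[1]))
    }
    df
  }
  ev <- read_tab("events.csv", c("onset", "rt"), "onset")
  kin <- read_tab("kinematics.csv", c("t", "x", "y", "vx", "vy"), "t")
  hd <- read_tab("head.csv", c("t", "yaw", "pitch"), "t")
  at <- read_tab("attempts.csv",
                 c("t_start", "t_move", "t_exit", "t_arrival", "t_end",
                   "tsc", "ttc"), c("t_start", "t_end"))
  gp <- read_tab("gaps.csv", "gap")

  dur <- task$n_stimuli * task$stim_duration
  blocks <- lapply(seq_len(task$n_dual_tasks), function(b) {
    pick <- function(df) {
      out <- df[df$dual_task == b, , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    at_b <- pick(at)
    if (nrow(at_b) == 0) at_b <- empty_attempts()
    list(dual_task = b, condition = task$conditions[b], duration = dur,
         stroop = pick(ev), kinematics = pick(kin), head = pick(hd),
         attempts = at_b, gaps = gp$gap[gp$dual_task == b])
  })
  structure(list(profile = profile, street = street, task = task,
                 blocks = blocks),
            class = "session_log")
}

#' Write / read a cohort feature table
#'
#' Comma-separated with header: `participant_id`, `true_score`, then the 68
#' feature columns named as in [feature_names()].
#'
#' @param tbl A feature table.
#' @param path CSV file path.
#' @return `read_feature_table()` returns the table; the writer returns
#'   `path` invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
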