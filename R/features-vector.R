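# The 17 per-block quantities, in the canonical order of the feature table.
FEATURE_QUANTITIES <- c("CNST", "RTST", "NUC", "NSC", "NA", "TSC", "TSC_MAX",
                        "TSC_MIN", "TTC", "SDX", "ETPX", "MVX", "MVY",
                        "SDVX", "SDVY", "FN", "HT")

#' Names of the 68 session features
#'
#' Seventeen quantities (Stroop performance: CNST, RTST; crossing behavior:
#' NUC, NSC, NA, TSC, TSC_MAX, TSC_MIN, TTC; trajectory/velocity: SDX, ETPX,
#' MVX, MVY, SDVX, SDVY; head behavior: FN, HT), each measured in the three
#' dual-task blocks and averaged over them, giving 17 x 4 = 68 features with
#' suffixes `_DT1`, `_DT2`, `_DT3`, `_MEAN`.
#'
#' @return Character vector of length 68 in stable order (quantity-major).
#' @export
feature_names <- function() {
  as.vector(t(outer(FEATURE_QUANTITIES, c("_DT1", "_DT2", "_DT3", "_MEAN"),
                    paste0)))
}

#' @rdname feature_names
#' @export
stroop_feature_names <- function() {
  fn <- feature_names()
  fn[grepl("^(CNST|RTST)_", fn)]
}

#' @rdname feature_names
#' @export
behavior_feature_names <- function() {
  setdiff(feature_names(), stroop_feature_names())
}

#' @param dual_task Block index (1, 2 or 3).
#' @rdname feature_names
#' @export
dual_task_feature_names <- function(dual_task) {
  paste0(FEATURE_QUANTITIES, "_DT", dual_task)
}

# The 17 quantities for one block of a session log.
block_features <- function(block, street) {
  sp <- stroop_performance(block$stroop)
  cs <- crossing_summaries(block$attempts, street$safety_margin)
  kin <- block$kinematics
  waits <- waiting_intervals(block$attempts, block$duration)
  hd <- block$head
  ht <- 0L
  pre_rows <- rep(FALSE, nrow(hd))
  for (k in seq_len(nrow(waits))) {
    sel <- hd$t >= waits$from[k] & hd$t < waits$to[k]
    pre_rows <- pre_rows | sel
    ht <- ht + count_head_turns(hd$yaw[sel])
  }
  fn <- compute_fn(accumulate_attention(hd[pre_rows, , drop = FALSE]))
  c(CNST = sp$cnst, RTST = sp$rtst, NUC = cs$nuc, NSC = cs$nsc,
    "NA" = cs$na_cross, TSC = cs$tsc, TSC_MAX = cs$tsc_max,
    TSC_MIN = cs$tsc_min, TTC = cs$ttc, SDX = compute_sdx(kin$x),
    ETPX = compute_etpx(kin$x), MVX = compute_mv(kin$vx),
    MVY = compute_mv(kin$vy), SDVX = compute_sdv(kin$vx),
    SDVY = compute_sdv(kin$vy), FN = fn, HT = ht)
}

#' Assemble the 68-feature vector of a dual-task session
#'
#' Computes the 17 quantities per dual-task block and their three-block
#' arithmetic means, in the stable order of [feature_names()]. Quantities that
#' are undefined for a block (e.g. TTC with no safe crossing, RTST with no
#' responded stimulus) are `NA` and are resolved at the cohort level by
#' [impute_feature_table()].
#'
#' @param log A `session_log` from [simulate_session()] or [read_session_log()].
#' @return Named numeric vector of length 68.
#' @export
assemble_feature_vector <- function(log) {
  stopifnot(inherits(log, "session_log"))
  if (length(log$blocks) != log$task$n_dual_tasks)
    stop("incomplete session log: expected ", log$task$n_dual_tasks, " blocks")
  per_block <- vapply(log$blocks, block_features, numeric(17), street = log$street)
  out <- cbind(per_block, rowMeans(per_block))
  vec <- as.vector(t(out))
  names(vec) <- feature_names()
  vec
}

#' Extract a cohort feature table from session logs
#'
#' @param logs A list of `session_log` objects.
#' @return A data frame with `participant_id`, `true_score` and the 68 feature
#'   columns, one row per session.
#' @export
extract_features <- function(logs) {
  rows <- lapply(logs, function(log) {
    fv <- assemble_feature_vector(log)
    cbind(data.frame(participant_id = log$profile$participant_id,
                     true_score = log$profile$true_score),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Impute missing feature values with the cohort median
#'
#' Participants with, for instance, no safe crossing in a block have no TTC
#' for that slot; for fixed-length model input such slots are filled with the
#' cohort median of the column. The number of imputed cells per column is
#' recorded in the `"imputed"` attribute.
#'
#' @param tbl A feature table from [extract_features()].
#' @return The table with `NA` feature cells replaced by column medians.
#' @export
impute_feature_table <- function(tbl) {
  cols <- intersect(feature_names(), names(tbl))
  imputed <- integer(0)
  for (cl in cols) {
    miss <- is.na(tbl[[cl]])
    if (any(miss)) {
      tbl[[cl]][miss] <- median(tbl[[cl]], na.rm = TRUE)
      imputed[cl] <- sum(miss)
    }
  }
  attr(tbl, "imputed") <- imputed
  tbl
}

#' Simulate a cohort and extract its feature table
#'
#' Convenience wrapper: builds a cohort, simulates one session per participant
#' (session seeds derived from `seed`) and returns the imputed feature table.
#'
#' @param n Cohort size.
#' @param seed Top-level seed.
#' @param score_mean,score_sd Cohort score distribution.
#' @param street,task,model Component configurations.
#' @return A feature table (see [extract_features()]), imputed.
#' @export
simulate_cohort_features <- function(n, seed = 1L, score_mean = 13,
                                     score_sd = 3, street = street_config(),
                                     task = task_config(),
                                     model = behavior_model()) {
  cohort <- build_cohort(n, score_mean, score_sd, seed = seed)
  seeds <- derive_seeds(seed + 1L, max(n, 1L))
  logs <- lapply(seq_len(n), function(i) {
    simulate_session(cohort[i, ], street, task, model, seed = seeds[i])
  })
  impute_feature_table(extract_features(logs))
}
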