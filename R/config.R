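#' Street geometry and traffic configuration
#'
#' Describes the virtual two-lane street: a 6 m roadway with a 0.5 m safe
#' margin on each side, vehicles at 30 km/h, a walker at the normal human
#' walking speed of 1.5 m/s, and the 1.5 s safe-crossing margin. The traffic
#' gap stream is designed so that a fixed fraction of inter-vehicle gaps
#' (default 50%) admits a safe crossing.
#'
#' @param roadway_width Roadway width in metres (default 6).
#' @param margin Safe margin on each side of the roadway in metres (default 0.5).
#' @param vehicle_speed Vehicle speed in km/h (default 30).
#' @param walk_speed Walking speed in m/s (default 1.5).
#' @param safety_margin Minimum time, in seconds, between the walker leaving
#'   the roadway and the next vehicle arriving for a crossing to count as safe
#'   (default 1.5; the comparison is strict).
#' @param crossable_fraction Design fraction of inter-vehicle gaps that admit a
#'   safe crossing (default 0.5).
#' @param sample_rate Sampling rate, in Hz, of the kinematic and head channels
#'   (default 50, typical of head-mounted displays).
#' @return An object of class `street_config`.
#' @seealso [crossable_gap_threshold()], [sample_gap_sequence()]
#' @export
#' @examples
#' street_config()
#' crossable_gap_threshold(street_config())  # 6/1.5 + 1.5 = 5.5 s
street_config <- function(roadway_width = 6, margin = 0.5, vehicle_speed = 30,
                          walk_speed = 1.5, safety_margin = 1.5,
                          crossable_fraction = 0.5, sample_rate = 50) {
  stopifnot(roadway_width >= 0, margin >= 0, vehicle_speed > 0, walk_speed > 0,
            safety_margin >= 0, sample_rate > 0,
            crossable_fraction > 0, crossable_fraction <= 1)
  structure(list(roadway_width = roadway_width, margin = margin,
                 vehicle_speed = vehicle_speed, walk_speed = walk_speed,
                 safety_margin = safety_margin,
                 crossable_fraction = crossable_fraction,
                 sample_rate = sample_rate),
            class = "street_config")
}

#' Stroop task schedule configuration
#'
#' Each dual-task block presents `n_stimuli` audio-visual Stroop stimuli for
#' `stim_duration` seconds each, so a block lasts exactly
#' `n_stimuli * stim_duration` seconds (144 s at the defaults). The three
#' dual-task blocks use the color-matching, word-matching and
#' interference-matching conditions in turn.
#'
#' @param n_stimuli Number of stimuli per dual-task block (default 72).
#' @param stim_duration Presentation time per stimulus in seconds (default 2).
#' @param n_dual_tasks Number of dual-task blocks (default 3).
#' @param conditions Ordered stimulus conditions, one per block.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_stimuli = 72, stim_duration = 2, n_dual_tasks = 3,
                        conditions = c("color", "word", "interference")) {
  stopifnot(n_stimuli > 0, stim_duration > 0, n_dual_tasks >= 1,
            length(conditions) >= n_dual_tasks)
  structure(list(n_stimuli = as.integer(n_stimuli),
                 stim_duration = stim_duration,
                 n_dual_tasks = as.integer(n_dual_tasks),
                 conditions = conditions[seq_len(n_dual_tasks)]),
            class = "task_config")
}

#' Generative behavior model for simulated participants
#'
#' Coefficients linking the latent processing-speed trait `z` (standardized
#' score) to every behavioral channel. These are design constants of the
#' simulator, not measured quantities: their contract is that cohorts generated
#' under the defaults reproduce the qualitative feature-score correlation
#' structure seen in dual-task assessments (faster and more accurate Stroop
#' responses, more safe crossings, more head scanning, higher mean forward
#' velocity for higher-trait participants).
#'
#' Response times are drawn per stimulus from a normal distribution with mean
#' `rt_intercept[condition] - rt_slope * z` plus a per-session intercept jitter,
#' floored at `rt_floor`; draws exceeding the stimulus duration become timeouts
#' (no response, counted incorrect). Answer correctness is Bernoulli with
#' probability `plogis(acc_intercept[condition] + acc_slope * z)`. The
#' interference condition has a larger RT intercept and a lower accuracy
#' intercept than color/word (the Stroop effect).
#'
#' @param rt_intercept Named per-condition mean response time in seconds.
#' @param rt_slope Reduction of mean RT per unit of latent trait, s/z (> 0
#'   means higher trait responds faster).
#' @param rt_sd Within-session RT standard deviation, s.
#' @param rt_session_sd Between-session RT intercept jitter SD, s
#'   (non-trait individual variability).
#' @param rt_floor Lower bound on response time, s (motor floor).
#' @param acc_intercept Named per-condition accuracy intercepts, logits.
#' @param acc_slope Accuracy gain per unit trait, logits/z.
#' @param gap_eff_base,gap_eff_slope Gap-acceptance discrimination: the
#'   probability of accepting a gap `g` is
#'   `plogis(gap_eff_base * exp(gap_eff_slope * z) * (g_perceived - threshold - gap_bias))`.
#' @param gap_bias Conservatism bias in seconds added to the crossing threshold.
#' @param gap_perception_sd SD of the perceptual noise on the gap duration, s.
#' @param gap_miss_base,gap_miss_slope Attentional gap misses: under dual-task
#'   load a waiting walker fails to evaluate a gap onset with probability
#'   `plogis(gap_miss_base - gap_miss_slope * z)`, so lower-trait participants
#'   let more usable gaps pass unexamined.
#' @param reaction_base,reaction_slope,reaction_sd,reaction_floor Reaction
#'   delay (s) between gap onset and starting to walk:
#'   `max(reaction_floor, N(reaction_base - reaction_slope * z, reaction_sd))`.
#' @param scan_rate_base,scan_rate_slope Head-scanning oscillation frequency in
#'   Hz while waiting: `scan_rate_base + scan_rate_slope * z` (floored at 0.05).
#' @param scan_amplitude,scan_amplitude_sd Mean and SD of the scan amplitude in
#'   degrees (per waiting interval).
#' @param yaw_noise_sd Additive yaw sensor noise SD, degrees.
#' @param lateral_wobble_sd Stationary SD of the lateral (x) position process
#'   while walking, metres.
#' @param vy_noise_sd Additive noise on forward velocity, m/s.
#' @param pitch_mean,pitch_sd Head pitch distribution, degrees.
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(
    rt_intercept = c(color = 0.85, word = 0.90, interference = 1.10),
    rt_slope = 0.12, rt_sd = 0.30, rt_session_sd = 0.08, rt_floor = 0.20,
    acc_intercept = c(color = 2.2, word = 2.0, interference = 1.4),
    acc_slope = 0.8,
    gap_eff_base = 1.5, gap_eff_slope = 0.4, gap_bias = 0.25,
    gap_perception_sd = 0.5, gap_miss_base = -1, gap_miss_slope = 0.6,
    reaction_base = 0.7, reaction_slope = 0.15, reaction_sd = 0.15,
    reaction_floor = 0.15,
    scan_rate_base = 0.45, scan_rate_slope = 0.12,
    scan_amplitude = 55, scan_amplitude_sd = 8, yaw_noise_sd = 3,
    lateral_wobble_sd = 0.03, vy_noise_sd = 0.03,
    pitch_mean = -5, pitch_sd = 3) {
  stopifnot(all(rt_intercept > 0), rt_sd > 0, rt_floor > 0,
            gap_eff_base > 0, gap_perception_sd >= 0,
            reaction_floor > 0, scan_amplitude > 0)
  structure(as.list(environment()), class = "behavior_model")
}

#' @export
print.street_config <- function(x, ...) {
  cat("Street configuration\n")
  cat(sprintf("  roadway %.1f m + %.1f m margins, vehicles %.0f km/h, walker %.1f m/s\n",
              x$roadway_width, x$margin, x$vehicle_speed, x$walk_speed))
  cat(sprintf("  safety margin %.1f s (crossable gap > %.2f s), %.0f%% of gaps crossable, %g Hz sampling\n",
              x$safety_margin, crossable_gap_threshold(x),
              100 * x$crossable_fraction, x$sample_rate))
  invisible(x)
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("Task configuration: %d dual-tasks (%s), %d stimuli x %g s = %g s per block\n",
              x$n_dual_tasks, paste(x$conditions, collapse = ", "),
              x$n_stimuli, x$stim_duration, x$n_stimuli * x$stim_duration))
  invisible(x)
}

#' Full pipeline configuration
#'
#' Bundles cohort, street, task, behavior-model, screening and model settings
#' into one serializable object driving [cmd_simulate()], [cmd_extract()] and
#' [cmd_analyze()].
#'
#' @param n_participants Cohort size (default 50).
#' @param score_mean,score_sd Cohort true-score distribution on the 0-19
#'   clinical scale (normal, clipped to 1-19; defaults 13 and 3).
#' @param seed Top-level seed from which all stage seeds derive.
#' @param street,task,model Component configurations.
#' @param r_threshold,alpha Screening thresholds (strict `|r| >` and `p <`).
#' @param models Regressor kinds to evaluate.
#' @param modes Feature-subset modes to evaluate.
#' @param rfe_k Subset size retained by recursive feature elimination.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 50, score_mean = 13, score_sd = 3,
                            seed = 1L, street = street_config(),
                            task = task_config(), model = behavior_model(),
                            r_threshold = 0.3, alpha = 0.05,
                            models = c("lasso", "svr", "xgboost"),
                            modes = c("all", "rfe"), rfe_k = 10) {
  stopifnot(n_participants >= 0, score_sd > 0)
  structure(list(n_participants = as.integer(n_participants),
                 score_mean = score_mean, score_sd = score_sd,
                 seed = as.integer(seed), street = street, task = task,
                 model = model, r_threshold = r_threshold, alpha = alpha,
                 models = match.arg(models, several.ok = TRUE),
                 modes = match.arg(modes,
                                   c("all", "rfe", "stroop_only", "behavior_only"),
                                   several.ok = TRUE),
                 rfe_k = rfe_k),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] object.
#' @param path File path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  # named numeric vectors become YAML maps (as.list) so names survive
  x <- lapply(config, function(v) {
    if (!is.list(v)) return(v)
    lapply(unclass(v), function(e)
      if (!is.null(names(e)) && length(e) > 1) as.list(e) else e)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  num_vec <- function(v) unlist(v)
  pipeline_config(
    n_participants = x$n_participants, score_mean = x$score_mean,
    score_sd = x$score_sd, seed = x$seed,
    street = do.call(street_config, x$street),
    task = do.call(task_config, x$task),
    model = do.call(behavior_model, lapply(x$model, num_vec)),
    r_threshold = x$r_threshold, alpha = x$alpha,
    models = x$models, modes = x$modes, rfe_k = x$rfe_k)
}
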