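#' Simulate a Stroop stimulus/response stream for one dual-task block
#'
#' Presents `n_stimuli` audio-visual match/mismatch stimuli at fixed
#' `stim_duration` onset spacing. Correctness per stimulus is Bernoulli with
#' probability `plogis(acc_intercept[condition] + acc_slope * z)`; response
#' time is drawn from a normal distribution centred at
#' `rt_intercept[condition] - rt_slope * z` (plus a per-call session jitter),
#' floored at the motor floor `rt_floor`. A draw beyond the stimulus duration
#' means no response was produced in time: the event becomes a timeout,
#' counted incorrect, with no recorded RT.
#'
#' @param task A [task_config()].
#' @param condition One of the conditions in `task$conditions`.
#' @param profile A single-row participant profile (see [build_cohort()]), or
#'   any list with a `latent_z` element.
#' @param model A [behavior_model()].
#' @param seed Optional integer seed (otherwise the caller's RNG stream).
#' @param dual_task_index Block index stored with the events.
#' @return A data frame of `n_stimuli` Stroop events with columns
#'   `dual_task`, `onset`, `condition`, `congruent`, `response`
#'   (`"match"`/`"mismatch"`/`"timeout"`), `correct` and `rt`
#'   (`NA` for timeouts).
#' @export
#' @examples
#' ev <- simulate_stroop_stream(task_config(), "color",
#'                              list(latent_z = 0), behavior_model(), seed = 1)
#' nrow(ev)                     # 72
#' max(ev$onset) + 2            # 144 s block span
simulate_stroop_stream <- function(task, condition, profile, model,
                                   seed = NULL, dual_task_index = 1L) {
  stopifnot(inherits(task, "task_config"), inherits(model, "behavior_model"))
  if (!condition %in% names(model$rt_intercept))
    stop("unknown Stroop condition: ", condition)
  z <- profile$latent_z
  n <- task$n_stimuli
  local_seed(seed, {
    onset <- (seq_len(n) - 1L) * task$stim_duration
    session_shift <- rnorm(1, 0, model$rt_session_sd)
    mu <- model$rt_intercept[[condition]] - model$rt_slope * z + session_shift
    rt_raw <- rnorm(n, mu, model$rt_sd)
    rt <- pmax(model$rt_floor, rt_raw)
    timeout <- rt > task$stim_duration
    p_correct <- plogis(model$acc_intercept[[condition]] + model$acc_slope * z)
    correct <- runif(n) < p_correct
    correct[timeout] <- FALSE
    congruent <- runif(n) < 0.5
    # the true answer is "match" iff the stimulus pair is congruent
    truth <- ifelse(congruent, "match", "mismatch")
    flipped <- ifelse(congruent, "mismatch", "match")
    response <- ifelse(timeout, "timeout", ifelse(correct, truth, flipped))
    rt[timeout] <- NA_real_
    data.frame(dual_task = as.integer(dual_task_index), onset = onset,
               condition = condition, congruent = congruent,
               response = response, correct = correct, rt = rt)
  })
}
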