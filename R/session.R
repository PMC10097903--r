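#' Simulate a full dual-task session for one participant
#'
#' Runs the three dual-task blocks (color, word and interference Stroop
#' conditions at the defaults). Within each block the walker waits at the
#' start point at the near roadway edge, scans the street with an oscillating
#' head yaw, and evaluates each inter-vehicle gap at its onset unless an
#' attentional miss occurs (a noisy perceived gap duration passed through a
#' trait-dependent logistic acceptance rule). On acceptance the walker enters
#' the roadway after a trait-dependent reaction delay, traverses it and the
#' far margin at fixed walking speed with lateral wobble, then resets
#' instantly to the start point. Attempts are classified safe when
#' the next vehicle arrives strictly more than `safety_margin` seconds after
#' the walker leaves the roadway; attempts cut off by the end of the block are
#' recorded as truncated. Kinematic (x, y, vx, vy) and head (yaw, pitch)
#' channels are sampled at `street$sample_rate` over the whole block, and a
#' Stroop event stream runs concurrently.
#'
#' Each random channel (traffic, gap decisions, kinematic noise, head motion,
#' Stroop) draws from its own sub-stream derived from `seed`, so a given
#' channel reproduces exactly even if another channel's model changes.
#'
#' @param profile One participant row from [build_cohort()] (or a list with
#'   `participant_id`, `true_score`, `latent_z`).
#' @param street A [street_config()].
#' @param task A [task_config()].
#' @param model A [behavior_model()].
#' @param seed Integer seed; identical inputs and seed give an identical log.
#' @return A `session_log` object: a list with elements `profile`, `street`,
#'   `task` and `blocks`, where each block holds data frames `stroop`,
#'   `kinematics`, `head`, `attempts` and the numeric `gaps` vector used.
#' @export
#' @examples
#' cohort <- build_cohort(2, seed = 1)
#' log <- simulate_session(cohort[1, ], seed = 10)
#' length(log$blocks)
#' nrow(log$blocks[[1]]$stroop)
simulate_session <- function(profile, street = street_config(),
                             task = task_config(), model = behavior_model(),
                             seed = 1L) {
  stopifnot(inherits(street, "street_config"), inherits(task, "task_config"),
            inherits(model, "behavior_model"))
  profile <- as.list(profile)
  seeds <- matrix(derive_seeds(seed, task$n_dual_tasks * 5L), ncol = 5L)
  blocks <- lapply(seq_len(task$n_dual_tasks), function(b) {
    simulate_block(profile, street, task, model,
                   condition = task$conditions[b], dual_task_index = b,
                   seeds = seeds[b, ])
  })
  structure(list(profile = profile, street = street, task = task,
                 blocks = blocks),
            class = "session_log")
}

# One dual-task block. seeds: traffic, decisions, kinematics, head, stroop.
simulate_block <- function(profile, street, task, model, condition,
                           dual_task_index, seeds) {
  z <- profile$latent_z
  dur <- task$n_stimuli * task$stim_duration
  v <- street$walk_speed
  # the walker waits at the near roadway edge (inside the start margin):
  # y = 0 is the waiting point, the roadway spans [0, width], the destination
  # marker sits a margin beyond the far edge
  total_dist <- street$roadway_width + street$margin
  exit_dist <- street$roadway_width
  thr <- crossable_gap_threshold(street)

  gaps <- sample_gap_sequence(street, horizon = dur + 4 * thr, seed = seeds[1])
  pass_times <- cumsum(c(0, gaps))          # vehicle pass times at the crossing

  attempts <- local_seed(seeds[2], {
    eff <- model$gap_eff_base * exp(model$gap_eff_slope * z)
    miss_p <- plogis(model$gap_miss_base - model$gap_miss_slope * z)
    rows <- list()
    t_free <- 0
    for (i in seq_along(gaps)) {
      onset <- pass_times[i]
      if (onset >= dur) break
      if (onset < t_free) next
      if (runif(1) < miss_p) next      # gap onset not evaluated (attention)
      perceived <- gaps[i] + rnorm(1, 0, model$gap_perception_sd)
      p_accept <- plogis(eff * (perceived - thr - model$gap_bias))
      if (runif(1) >= p_accept) next
      d <- max(model$reaction_floor,
               rnorm(1, model$reaction_base - model$reaction_slope * z,
                     model$reaction_sd))
      t_move <- onset + d
      t_exit <- t_move + exit_dist / v
      t_end <- t_move + total_dist / v
      t_arrival <- pass_times[i + 1]
      if (t_end > dur) {
        rows[[length(rows) + 1L]] <- data.frame(
          dual_task = dual_task_index, t_start = onset, t_move = t_move,
          t_exit = t_exit, t_arrival = t_arrival, t_end = dur,
          tsc = NA_real_, ttc = NA_real_, outcome = "truncated")
        t_free <- dur
        break
      }
      ttc <- t_arrival - t_exit
      rows[[length(rows) + 1L]] <- data.frame(
        dual_task = dual_task_index, t_start = onset, t_move = t_move,
        t_exit = t_exit, t_arrival = t_arrival, t_end = t_end,
        tsc = t_end - onset, ttc = ttc,
        outcome = if (ttc > street$safety_margin) "safe" else "unsafe")
      t_free <- t_end
    }
    if (length(rows)) do.call(rbind, rows) else empty_attempts()
  })

  dt <- 1 / street$sample_rate
  tt <- seq(0, dur - dt, by = dt)
  n_samp <- length(tt)

  # membership of each sample in an attempt ([t_start, t_end)) / walking phase
  in_attempt <- rep(FALSE, n_samp)
  walking <- rep(FALSE, n_samp)
  y <- numeric(n_samp)
  for (k in seq_len(nrow(attempts))) {
    a <- attempts[k, ]
    sel <- tt >= a$t_start & tt < a$t_end
    in_attempt[sel] <- TRUE
    w <- tt >= a$t_move & tt < a$t_end
    walking[w] <- TRUE
    y[w] <- pmin(total_dist, v * (tt[w] - a$t_move))
  }

  kinematics <- local_seed(seeds[3], {
    # lateral position: mean-reverting (OU-like) wobble, calmer while waiting
    tau <- 2
    phi <- exp(-dt / tau)
    innov_sd <- model$lateral_wobble_sd * sqrt(1 - phi^2)
    eps <- rnorm(n_samp, 0, innov_sd) * ifelse(walking, 1, 0.3)
    x <- as.numeric(stats::filter(eps, phi, method = "recursive"))
    vx <- c(0, diff(x)) / dt
    vy <- v * walking + rnorm(n_samp, 0, model$vy_noise_sd)
    data.frame(dual_task = dual_task_index, t = tt, x = x, y = y,
               vx = vx, vy = vy)
  })

  head_df <- local_seed(seeds[4], {
    yaw <- rnorm(n_samp, 0, 8)              # roughly facing destination
    f <- max(0.05, model$scan_rate_base + model$scan_rate_slope * z)
    waits <- waiting_intervals(attempts, dur)
    for (k in seq_len(nrow(waits))) {
      sel <- tt >= waits$from[k] & tt < waits$to[k]
      if (!any(sel)) next
      amp <- min(120, max(35, rnorm(1, model$scan_amplitude,
                                    model$scan_amplitude_sd)))
      yaw[sel] <- amp * sin(2 * pi * f * (tt[sel] - waits$from[k])) +
        rnorm(sum(sel), 0, model$yaw_noise_sd)
    }
    pitch <- rnorm(n_samp, model$pitch_mean, model$pitch_sd)
    data.frame(dual_task = dual_task_index, t = tt,
               yaw = pmin(180, pmax(-180, yaw)),
               pitch = pmin(89.5, pmax(-89.5, pitch)))
  })

  stroop <- simulate_stroop_stream(task, condition, profile, model,
                                   seed = seeds[5],
                                   dual_task_index = dual_task_index)

  list(dual_task = dual_task_index, condition = condition, duration = dur,
       stroop = stroop, kinematics = kinematics, head = head_df,
       attempts = attempts, gaps = gaps)
}

empty_attempts <- function() {
  data.frame(dual_task = integer(), t_start = numeric(), t_move = numeric(),
             t_exit = numeric(), t_arrival = numeric(), t_end = numeric(),
             tsc = numeric(), ttc = numeric(), outcome = character())
}

# Pre-crossing (waiting) intervals: the complement of attempt spans in [0, dur).
waiting_intervals <- function(attempts, dur) {
  if (nrow(attempts) == 0)
    return(data.frame(from = 0, to = dur))
  a <- attempts[order(attempts$t_start), ]
  from <- c(0, a$t_end)
  to <- c(a$t_start, dur)
  keep <- to > from
  data.frame(from = from[keep], to = to[keep])
}

#' @export
print.session_log <- function(x, ...) {
  na <- sum(vapply(x$blocks, function(b) nrow(b$attempts), 1L))
  cat(sprintf("Dual-task session log: participant %s (score %.0f), %d blocks, %d crossing attempts\n",
              x$profile$participant_id, x$profile$true_score,
              length(x$blocks), na))
  invisible(x)
}
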