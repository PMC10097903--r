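#' Time to collision for a completed crossing attempt
#'
#' TTC is the interval between the walker leaving the roadway (time `T1`) and
#' the next vehicle arriving at the crossing point (time `T2`): `TTC = T2 - T1`.
#' With several conflict lanes the binding (smallest) interval is returned.
#'
#' @param attempt A one-row attempt record (with `t_exit`, `t_arrival`,
#'   `outcome`), or a list with numeric `lane_exit_times` and
#'   `vehicle_arrival_times`.
#' @return TTC in seconds.
#' @export
#' @examples
#' compute_ttc(list(lane_exit_times = 10, vehicle_arrival_times = 13.2)) # 3.2
compute_ttc <- function(attempt) {
  attempt <- as.list(attempt)
  if (!is.null(attempt$outcome) && identical(attempt$outcome, "truncated"))
    stop("TTC is undefined for a truncated attempt")
  t1 <- attempt$lane_exit_times %||% attempt$t_exit
  t2 <- attempt$vehicle_arrival_times %||% attempt$t_arrival
  if (is.null(t1) || is.null(t2) || length(t1) != length(t2) || !length(t1))
    stop("attempt must carry matching lane exit and vehicle arrival times")
  min(t2 - t1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a completed crossing attempt as safe or unsafe
#'
#' A crossing is safe iff its time to collision strictly exceeds the safety
#' margin (more than 1.5 s, at the default, between leaving the roadway and
#' the vehicle's arrival). A TTC exactly equal to the margin is unsafe.
#'
#' @param attempt A completed attempt (see [compute_ttc()]).
#' @param safety_margin Safety margin in seconds (default 1.5).
#' @return `"safe"` or `"unsafe"`.
#' @export
classify_crossing <- function(attempt, safety_margin = 1.5) {
  if (compute_ttc(attempt) > safety_margin) "safe" else "unsafe"
}

#' Trajectory dispersion: sample standard deviation of lateral position
#'
#' `SDX = sqrt( sum((x_i - mean(x))^2) / (N - 1) )`, the sample standard
#' deviation (N-1 denominator) of the x-axis trajectory, measuring how well
#' the walker holds direction.
#'
#' @param xs Numeric vector of lateral positions (N >= 2).
#' @return SDX in metres.
#' @export
compute_sdx <- function(xs) {
  if (length(xs) < 2) stop("SDX needs at least two samples")
  sd(xs)
}

#' Trajectory entropy of the lateral position distribution
#'
#' Shannon entropy (base 2) of the binned x-position distribution:
#' positions are counted into fixed-width bins (edges at integer multiples of
#' `bin_width`), `P` is the occupied-bin relative frequency, and
#' `ETPX = -sum(P * log2(P))` with `0 * log2(0) := 0`.
#'
#' @param xs Numeric vector of lateral positions (non-empty).
#' @param bin_width Bin width in metres (default 0.1).
#' @return Entropy in bits.
#' @export
#' @examples
#' compute_etpx(c(0.01, 0.11, 0.21, 0.31))  # 4 equal bins -> 2 bits
compute_etpx <- function(xs, bin_width = 0.1) {
  if (!length(xs)) stop("ETPX needs at least one sample")
  stopifnot(bin_width > 0)
  idx <- floor(xs / bin_width + 1e-9)
  p <- tabulate(as.integer(factor(idx)))
  p <- p / length(xs)
  -sum(p * log2(p))
}

#' Mean velocity along one axis
#'
#' `MV = mean(v_i)`. Applied to the vx channel it yields MVX, to vy it yields
#' MVY.
#'
#' @param vs Numeric vector of per-sample velocities (non-empty).
#' @return Mean velocity in m/s.
#' @export
compute_mv <- function(vs) {
  if (!length(vs)) stop("MV needs at least one sample")
  mean(vs)
}

#' Velocity dispersion along one axis
#'
#' `SDV = sqrt( sum((v_i - MV)^2) / (N - 1) )`; smoother movement gives a
#' lower SDV.
#'
#' @param vs Numeric vector of per-sample velocities (N >= 2).
#' @return Sample standard deviation of velocity in m/s.
#' @export
compute_sdv <- function(vs) {
  if (length(vs) < 2) stop("SDV needs at least two samples")
  sd(vs)
}

#' Accumulate head orientation into the 180 x 360 attention matrix
#'
#' Each pre-crossing head sample increments one cell of a 180 (elevation
#' degrees) x 360 (azimuth degrees) accumulator at 1 degree resolution, so the
#' matrix total equals the number of samples. Rows cover pitch in
#' [-90, 90) degrees, columns yaw in [-180, 180) degrees.
#'
#' @param heads Data frame with `yaw` and `pitch` columns in degrees (may be
#'   empty, giving an all-zero matrix).
#' @return A 180 x 360 numeric matrix of counts.
#' @export
accumulate_attention <- function(heads) {
  mat <- matrix(0, nrow = 180, ncol = 360)
  if (is.null(heads) || nrow(as.data.frame(heads)) == 0) return(mat)
  heads <- as.data.frame(heads)
  row <- pmin(180L, pmax(1L, as.integer(floor(heads$pitch)) + 91L))
  col <- pmin(360L, pmax(1L, as.integer(floor(heads$yaw)) + 181L))
  idx <- (col - 1L) * 180L + row
  counts <- tabulate(idx, nbins = 180L * 360L)
  mat[] <- counts
  mat
}

#' Attention dispersion score of an attention matrix
#'
#' `FN = sum(a_ij^2)`, the sum of squared cell counts (no square root; the
#' printed form of the statistic). A true Frobenius norm is available with
#' `frobenius = TRUE`, off by default.
#'
#' @param A An attention matrix from [accumulate_attention()].
#' @param frobenius If `TRUE` return `sqrt(sum(a_ij^2))` instead.
#' @return Non-negative dispersion score.
#' @export
compute_fn <- function(A, frobenius = FALSE) {
  s <- sum(A^2)
  if (frobenius) sqrt(s) else s
}

#' Count head turns in a yaw trace
#'
#' A head turn is an excursion of the yaw angle beyond `threshold` degrees to
#' either side of the crossing direction, counted with hysteresis: after
#' `|yaw|` rises above the threshold, it must fall back below it before the
#' next excursion can count.
#'
#' @param yaw Numeric vector of yaw angles in degrees, time ordered.
#' @param threshold Excursion threshold in degrees (default 30).
#' @return Integer count of head turns.
#' @export
#' @examples
#' count_head_turns(c(0, 45, 0, -45, 0))  # 2
count_head_turns <- function(yaw, threshold = 30) {
  if (!length(yaw)) return(0L)
  above <- abs(yaw) > threshold
  sum(above & !c(FALSE, above[-length(above)]))
}

#' Stroop performance summary of one dual-task block
#'
#' `CNST` is the number of correct answers (timeouts count as incorrect);
#' `RTST` is the mean response time over responded events (timeouts carry no
#' RT and are excluded). With zero responded events RTST is `NA` and is later
#' handled by the missing-value rule.
#'
#' @param events A Stroop event data frame (see [simulate_stroop_stream()]).
#' @return A list with elements `cnst` and `rtst`.
#' @export
stroop_performance <- function(events) {
  if (is.null(events) || nrow(events) == 0)
    stop("Stroop performance needs a non-empty event list")
  responded <- events$response != "timeout"
  list(cnst = sum(events$correct),
       rtst = if (any(responded)) mean(events$rt[responded]) else NA_real_)
}

#' Crossing-attempt summaries of one dual-task block
#'
#' Counts safe (NSC) and unsafe (NUC) completed crossings and their sum
#' (NA_CROSS); summarises the time spent crossing (TSC: mean, max and min over
#' completed attempts, measured from standing at the start point until
#' reaching the destination) and the mean time to collision over safe
#' attempts. Truncated attempts (cut off by the block clock) are excluded
#' everywhere. Empty categories yield `NA` values, flagged for downstream
#' imputation.
#'
#' @param attempts An attempt data frame (see [simulate_session()]).
#' @param safety_margin Safety margin in seconds used to classify attempts.
#' @return A list with `nsc`, `nuc`, `na_cross`, `tsc`, `tsc_max`, `tsc_min`,
#'   `ttc`.
#' @export
crossing_summaries <- function(attempts, safety_margin = 1.5) {
  attempts <- as.data.frame(attempts)
  done <- attempts[attempts$outcome != "truncated", , drop = FALSE]
  if (nrow(done) == 0) {
    return(list(nsc = 0L, nuc = 0L, na_cross = 0L, tsc = NA_real_,
                tsc_max = NA_real_, tsc_min = NA_real_, ttc = NA_real_))
  }
  ttc <- done$t_arrival - done$t_exit
  safe <- ttc > safety_margin
  list(nsc = sum(safe), nuc = sum(!safe), na_cross = nrow(done),
       tsc = mean(done$tsc), tsc_max = max(done$tsc), tsc_min = min(done$tsc),
       ttc = if (any(safe)) mean(ttc[safe]) else NA_real_)
}
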