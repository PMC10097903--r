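#' Minimal gap duration admitting a safe crossing
#'
#' Under the whole-roadway traffic model the 6 m roadway is one conflict zone
#' with a single gap stream. A walker starting at the roadway edge at gap onset
#' needs `roadway_width / walk_speed` seconds to traverse it and must still
#' have strictly more than `safety_margin` seconds before the next vehicle
#' arrives, so a gap admits a safe crossing iff it exceeds
#' `roadway_width / walk_speed + safety_margin` (5.5 s at the defaults).
#'
#' @param street A [street_config()].
#' @return The threshold gap duration in seconds.
#' @export
crossable_gap_threshold <- function(street) {
  stopifnot(inherits(street, "street_config"))
  street$roadway_width / street$walk_speed + street$safety_margin
}

#' Sample an inter-vehicle gap sequence
#'
#' Gaps are drawn from a two-component mixture around the crossing threshold:
#' with probability `crossable_fraction` a gap is supra-threshold
#' (threshold + exponential, mean `supra_mean`), otherwise sub-threshold
#' (uniform between `sub_min` and the threshold). Each component lies strictly
#' on its side of the threshold, so the expected crossable proportion equals
#' `crossable_fraction` exactly.
#'
#' @param street A [street_config()].
#' @param horizon Generate gaps until their cumulative duration reaches this
#'   many seconds (ignored when `n` is given).
#' @param n Generate exactly `n` gaps.
#' @param seed Optional integer seed; when `NULL` the caller's RNG stream is
#'   used.
#' @param supra_mean Mean excess (s) of crossable gaps above the threshold.
#' @param sub_min Minimum sub-threshold gap, s.
#' @return Numeric vector of gap durations in seconds.
#' @export
#' @examples
#' g <- sample_gap_sequence(street_config(), n = 1000, seed = 1)
#' mean(g > crossable_gap_threshold(street_config()))  # near 0.5
sample_gap_sequence <- function(street, horizon = NULL, n = NULL, seed = NULL,
                                supra_mean = 2.5, sub_min = 1.5) {
  stopifnot(inherits(street, "street_config"))
  thr <- crossable_gap_threshold(street)
  if (sub_min >= thr) sub_min <- thr / 2
  draw <- function(k) {
    crossable <- runif(k) < street$crossable_fraction
    ifelse(crossable, thr + rexp(k, rate = 1 / supra_mean),
           runif(k, sub_min, thr))
  }
  local_seed(seed, {
    if (!is.null(n)) {
      stopifnot(n >= 0)
      draw(n)
    } else {
      stopifnot(!is.null(horizon), horizon > 0)
      # draw in chunks until the cumulative span covers the horizon
      out <- numeric(0)
      while (sum(out) < horizon) {
        k <- max(8L, ceiling((horizon - sum(out)) / thr))
        out <- c(out, draw(k))
      }
      out[seq_len(which(cumsum(out) >= horizon)[1])]
    }
  })
}

# Idealized crossability classification of gaps (strict threshold).
is_crossable <- function(gaps, street) {
  gaps > crossable_gap_threshold(street)
}
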