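#' Generate a synthetic participant cohort
#'
#' Draws true processing-speed scores on the 0-19 clinical scale from a normal
#' distribution (rounded to whole scale points and clipped to 1-19 so the
#' relative-accuracy metric is defined), and standardizes them within the
#' cohort into the latent trait `latent_z` that drives all simulated behavior.
#'
#' @param n Cohort size.
#' @param score_mean,score_sd Score distribution parameters (defaults 13 and 3).
#' @param seed Integer seed; the same seed always yields the same cohort.
#' @param age_mean,age_sd Age distribution in years (defaults match a young
#'   healthy adult cohort).
#' @return A data frame with one row per participant and columns
#'   `participant_id`, `age`, `true_score`, `latent_z`.
#' @export
#' @examples
#' cohort <- build_cohort(50, seed = 1)
#' range(cohort$true_score)
build_cohort <- function(n, score_mean = 13, score_sd = 3, seed = 1L,
                         age_mean = 23.1, age_sd = 1.7) {
  if (n < 0) stop("cohort size must be non-negative")
  if (score_sd <= 0) stop("score_sd must be positive")
  n <- as.integer(n)
  if (n == 0L) {
    return(data.frame(participant_id = character(), age = integer(),
                      true_score = numeric(), latent_z = numeric()))
  }
  local_seed(seed, {
    score <- round(pmin(19, pmax(1, rnorm(n, score_mean, score_sd))))
    age <- as.integer(round(pmin(28, pmax(20, rnorm(n, age_mean, age_sd)))))
    z <- if (n >= 2 && sd(score) > 0) (score - mean(score)) / sd(score)
         else rep(0, n)
    data.frame(participant_id = sprintf("P%03d", seq_len(n)),
               age = age, true_score = as.numeric(score), latent_z = z)
  })
}
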