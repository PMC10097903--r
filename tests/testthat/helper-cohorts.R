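# Shared simulated cohorts, built once per test run. The (n, seed) pairs are
# the fixed study conditions used by the property suites.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort_features <- function(n, seed) {
  key <- sprintf("n%d_s%d", n, seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort_features(n, seed = seed)
  .cohort_cache[[key]]
}

cohort50 <- function() cached_cohort_features(50, 5)
cohort200 <- function() cached_cohort_features(200, 11)
cohort500 <- function() cached_cohort_features(500, 42)

cached_rfe_eval <- function() {
  if (is.null(.cohort_cache$rfe50))
    .cohort_cache$rfe50 <- loso_evaluate(cohort50(), model_spec("lasso", seed = 2),
                                         mode = "rfe", rfe_k = 10)
  .cohort_cache$rfe50
}

# A small complete session log for structural tests.
cached_session <- function() {
  if (is.null(.cohort_cache$session)) {
    cohort <- build_cohort(3, seed = 1)
    .cohort_cache$session <- simulate_session(cohort[1, ], seed = 10)
  }
  .cohort_cache$session
}

# Hand-built micro fixture bundle (written to a temp dir once).
cached_fixtures <- function() {
  if (is.null(.cohort_cache$fixtures)) {
    dir <- file.path(tempdir(), "dualspeed-fixtures")
    .cohort_cache$fixtures <- make_fixtures(dir)
  }
  .cohort_cache$fixtures
}
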