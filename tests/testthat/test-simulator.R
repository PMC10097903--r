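test_that("cohort generation respects size, score range and determinism", {
  cohort <- build_cohort(50, seed = 1)
  expect_equal(nrow(cohort), 50)
  expect_true(all(cohort$true_score >= 1 & cohort$true_score <= 19))
  expect_equal(mean(cohort$latent_z), 0, tolerance = 1e-12)
  expect_equal(sd(cohort$latent_z), 1, tolerance = 1e-12)
  expect_identical(cohort, build_cohort(50, seed = 1))
  expect_false(identical(cohort, build_cohort(50, seed = 2)))
  expect_equal(nrow(build_cohort(0)), 0)
  expect_error(build_cohort(-1), "non-negative")
  expect_error(build_cohort(10, score_sd = 0), "positive")
})

test_that("crossable gap threshold follows the whole-roadway kinematics", {
  expect_equal(crossable_gap_threshold(street_config()), 6 / 1.5 + 1.5)
  expect_equal(crossable_gap_threshold(street_config(walk_speed = 3)),
               6 / 3 + 1.5)
  expect_equal(crossable_gap_threshold(
    street_config(roadway_width = 0, safety_margin = 0)), 0)
})

test_that("gap mixture hits the designed crossable fraction", {
  street <- street_config()
  thr <- crossable_gap_threshold(street)
  g <- sample_gap_sequence(street, n = 10000, seed = 2)
  ci_half <- qnorm(0.995) * sqrt(0.5 * 0.5 / 10000)
  expect_gt(mean(g > thr), 0.5 - ci_half)
  expect_lt(mean(g > thr), 0.5 + ci_half)

  q <- sample_gap_sequence(street_config(crossable_fraction = 0.25),
                           n = 10000, seed = 3)
  ci_half <- qnorm(0.995) * sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(q > thr) - 0.25), ci_half)

  all_cross <- sample_gap_sequence(street_config(crossable_fraction = 1),
                                   n = 500, seed = 4)
  expect_true(all(all_cross > thr))

  h <- sample_gap_sequence(street, horizon = 300, seed = 5)
  expect_gte(sum(h), 300)
  expect_lt(sum(h[-length(h)]), 300)
})

test_that("stroop stream has the exact schedule and a monotone trait effect", {
  task <- task_config()
  model <- behavior_model()
  ev <- simulate_stroop_stream(task, "color", list(latent_z = 0), model,
                               seed = 1)
  expect_equal(nrow(ev), 72)
  expect_equal(ev$onset, seq(0, 142, by = 2))
  expect_equal(max(ev$onset) + task$stim_duration, 144)
  expect_error(simulate_stroop_stream(task, "shape", list(latent_z = 0),
                                      model), "unknown")

  noiseless <- behavior_model(rt_sd = 1e-12, rt_session_sd = 0)
  rts <- vapply(c(-2, -1, 0, 1, 2), function(z) {
    mean(simulate_stroop_stream(task, "color", list(latent_z = z), noiseless,
                                seed = 7)$rt, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rts) < 0))
  # same stream seed: accuracy is non-decreasing in the trait
  acc <- vapply(c(-2, 0, 2), function(z) {
    sum(simulate_stroop_stream(task, "color", list(latent_z = z), model,
                               seed = 7)$correct)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))

  # extreme trait, no noise: everything correct, RT at the motor floor
  fast <- simulate_stroop_stream(task, "color", list(latent_z = 50),
                                 noiseless, seed = 1)
  expect_true(all(fast$correct))
  expect_true(all(fast$rt == noiseless$rt_floor))

  # interference shows the Stroop effect relative to color at equal trait
  slow <- simulate_stroop_stream(task, "interference", list(latent_z = 0),
                                 noiseless, seed = 3)
  base <- simulate_stroop_stream(task, "color", list(latent_z = 0),
                                 noiseless, seed = 3)
  expect_gt(mean(slow$rt, na.rm = TRUE), mean(base$rt, na.rm = TRUE))
})

test_that("a session has three full blocks with conserved schedule", {
  log <- cached_session()
  expect_s3_class(log, "session_log")
  expect_length(log$blocks, 3)
  for (b in log$blocks) {
    expect_equal(b$duration, 144)
    expect_equal(nrow(b$stroop), 72)
    expect_equal(nrow(b$kinematics), 144 * 50)
    expect_equal(diff(b$kinematics$t)[1], 1 / 50)
    expect_lte(max(b$attempts$t_end), 144)
    expect_true(all(b$attempts$t_end > b$attempts$t_start))
  }
})

test_that("sessions are deterministic given the seed", {
  cohort <- build_cohort(1, seed = 3)
  a <- simulate_session(cohort[1, ], seed = 21)
  b <- simulate_session(cohort[1, ], seed = 21)
  expect_identical(a, b)
  expect_false(identical(a, simulate_session(cohort[1, ], seed = 22)))
})

test_that("simulator outcome labels agree with the crossing classifier", {
  log <- cached_session()
  for (b in log$blocks) {
    done <- b$attempts[b$attempts$outcome != "truncated", ]
    for (k in seq_len(nrow(done)))
      expect_equal(classify_crossing(done[k, ], log$street$safety_margin),
                   done$outcome[k])
  }
})

test_that("walker speed stays near the fixed walking speed", {
  log <- cached_session()
  for (b in log$blocks) {
    speed <- sqrt(b$kinematics$vx^2 + b$kinematics$vy^2)
    expect_lte(max(speed), log$street$walk_speed + 1.0)
    expect_true(all(abs(b$head$yaw) <= 180))
  }
})

test_that("an idealized decision rule yields only safe completed crossings", {
  m <- behavior_model(gap_perception_sd = 0, gap_bias = 0, gap_eff_base = 1e4,
                      reaction_base = 1e-6, reaction_sd = 0,
                      reaction_floor = 1e-6)
  log <- simulate_session(list(participant_id = "X", true_score = 13,
                               latent_z = 0), model = m, seed = 3)
  oc <- unlist(lapply(log$blocks, function(b) b$attempts$outcome))
  expect_true(all(oc %in% c("safe", "truncated")))
  expect_gt(sum(oc == "safe"), 0)
})
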