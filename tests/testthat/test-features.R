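test_that("time to collision is T2 - T1, minimized over lanes", {
  expect_equal(compute_ttc(list(lane_exit_times = 10, vehicle_arrival_times = 10)), 0)
  expect_equal(compute_ttc(list(lane_exit_times = 10.0,
                                vehicle_arrival_times = 13.2)), 3.2)
  expect_equal(compute_ttc(list(lane_exit_times = c(5, 8),
                                vehicle_arrival_times = c(7, 9.2))), 1.2)
  expect_error(compute_ttc(list(outcome = "truncated", t_exit = 1,
                                t_arrival = 2)), "truncated")
})

test_that("safe crossings need strictly more than the safety margin", {
  mk <- function(ttc) list(t_exit = 10, t_arrival = 10 + ttc)
  expect_equal(classify_crossing(mk(3.0)), "safe")
  expect_equal(classify_crossing(mk(1.5)), "unsafe")  # exactly at the margin
  expect_equal(classify_crossing(mk(0)), "unsafe")
  expect_equal(classify_crossing(mk(2), safety_margin = 2.5), "unsafe")
})

test_that("trajectory dispersion matches the printed formula", {
  expect_equal(compute_sdx(rep(2.5, 10)), 0)
  expect_equal(compute_sdx(c(0, 1)), sqrt(0.5))
  set.seed(4); xs <- rnorm(1000, 0, 0.2)
  expect_equal(compute_sdx(xs), 0.2, tolerance = 0.05)
  # brute-force re-evaluation of the formula
  expect_equal(compute_sdx(xs), sqrt(sum((xs - mean(xs))^2) / (length(xs) - 1)))
  expect_error(compute_sdx(1), "two samples")
})

test_that("trajectory entropy is binned Shannon entropy in bits", {
  expect_equal(compute_etpx(rep(0.05, 20)), 0)
  expect_equal(compute_etpx(c(0.01, 0.11, 0.21, 0.31)), 2)
  expect_equal(compute_etpx(c(0.01, 0.02, 0.11, 0.21)),
               -(0.5 * log2(0.5) + 0.25 * log2(0.25) + 0.25 * log2(0.25)))
  expect_error(compute_etpx(numeric(0)), "one sample")
})

test_that("velocity mean and dispersion match direct formula evaluation", {
  expect_equal(compute_mv(rep(1.5, 7)), 1.5)
  expect_equal(compute_mv(c(0, 3)), 1.5)
  expect_equal(compute_mv(c(-2, -1, 1, 2)), 0)
  expect_equal(compute_sdv(rep(1.2, 9)), 0)
  expect_equal(compute_sdv(c(0, 3)), sqrt(4.5))
  set.seed(9); vs <- runif(200, 0, 2)
  mv <- sum(vs) / length(vs)
  expect_equal(compute_sdv(vs), sqrt(sum((vs - mv)^2) / (length(vs) - 1)))
  expect_error(compute_sdv(0.3), "two samples")
})

test_that("attention matrix accumulates one count per head sample", {
  z <- accumulate_attention(data.frame(yaw = numeric(), pitch = numeric()))
  expect_equal(dim(z), c(180, 360))
  expect_equal(sum(z), 0)
  pt <- accumulate_attention(data.frame(yaw = rep(45.2, 10),
                                        pitch = rep(-10.7, 10)))
  expect_equal(sum(pt), 10)
  expect_equal(max(pt), 10)  # a single occupied cell
  set.seed(2)
  hd <- data.frame(yaw = runif(500, -180, 179.9), pitch = runif(500, -89, 89))
  expect_equal(sum(accumulate_attention(hd)), 500)
})

test_that("attention dispersion is the printed sum of squared entries", {
  expect_equal(compute_fn(matrix(0, 180, 360)), 0)
  a <- matrix(0, 180, 360); a[10, 20] <- 2
  expect_equal(compute_fn(a), 4)
  a[10, 21] <- 1; a[11, 20] <- 2
  expect_equal(compute_fn(a), 9)
  expect_equal(compute_fn(a, frobenius = TRUE), 3)
  # monotone non-decreasing in any single cell count
  b <- a; b[50, 50] <- b[50, 50] + 1
  expect_gte(compute_fn(b), compute_fn(a))
})

test_that("head turns count threshold excursions with hysteresis", {
  expect_equal(count_head_turns(rep(0, 100)), 0)
  expect_equal(count_head_turns(c(0, 45, 0, -45, 0)), 2)
  expect_equal(count_head_turns(rep(c(29, -29), 20)), 0)
  # must return below threshold before a new excursion counts
  expect_equal(count_head_turns(c(0, 40, 50, 60, 40, 31, 0, 35)), 2)
  expect_equal(count_head_turns(numeric(0)), 0L)
})

test_that("stroop performance counts timeouts incorrect and excludes their RT", {
  uniform <- data.frame(response = rep("match", 72), correct = TRUE, rt = 1.0)
  expect_equal(stroop_performance(uniform), list(cnst = 72L, rtst = 1.0))
  mixed <- data.frame(
    response = c("match", "timeout", "mismatch", "match", "timeout"),
    correct = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    rt = c(0.5, NA, 1.1, 0.9, NA))
  expect_equal(stroop_performance(mixed), list(cnst = 2L, rtst = mean(c(0.5, 1.1, 0.9))))
  timeouts <- data.frame(response = rep("timeout", 3), correct = FALSE,
                         rt = NA_real_)
  res <- stroop_performance(timeouts)
  expect_equal(res$cnst, 0L)
  expect_true(is.na(res$rtst))
  expect_error(stroop_performance(data.frame()), "non-empty")
})

test_that("crossing summaries count, average and bound attempt times", {
  att <- data.frame(
    t_start = c(0, 10, 20, 30), t_exit = c(4, 14, 24, 34),
    t_arrival = c(6.5, 15.5, 26.2, 35), t_end = c(4.5, 14.5, 24.5, 34.5),
    tsc = c(4.5, 4.5, 4.5, 4.5),
    outcome = c("safe", "unsafe", "safe", "unsafe"))
  cs <- crossing_summaries(att)
  expect_equal(cs$nsc, 2L)    # TTCs 2.5 and 2.2 safe; 1.5 (exact) and 1.0 not
  expect_equal(cs$nuc, 2L)
  expect_equal(cs$na_cross, 4L)
  expect_equal(cs$na_cross, cs$nsc + cs$nuc)
  expect_equal(cs$ttc, mean(c(2.5, 2.2)))
  single <- crossing_summaries(data.frame(t_start = 0, t_exit = 4,
                                          t_arrival = 7, t_end = 4.4,
                                          tsc = 4.4, outcome = "safe"))
  expect_equal(single$tsc, single$tsc_max)
  expect_equal(single$tsc, single$tsc_min)
  empty <- crossing_summaries(data.frame(t_start = numeric(),
                                         t_exit = numeric(),
                                         t_arrival = numeric(),
                                         t_end = numeric(), tsc = numeric(),
                                         outcome = character()))
  expect_equal(empty$na_cross, 0L)
  expect_true(is.na(empty$tsc) && is.na(empty$ttc))
})

test_that("the fixture log reproduces every hand-derived feature value", {
  fx <- cached_fixtures()
  fv <- assemble_feature_vector(fx$log)
  expect_length(fv, 68)
  expect_identical(names(fv), feature_names())
  for (i in seq_len(nrow(fx$expected))) {
    q <- fx$expected$quantity[i]
    for (suffix in c("_DT1", "_DT2", "_DT3", "_MEAN"))
      expect_equal(unname(fv[paste0(q, suffix)]), fx$expected$value[i],
                   tolerance = 1e-9, label = paste0(q, suffix))
  }
  # identical blocks: the mean slot equals each per-task slot
  expect_equal(unname(fv[paste0(fx$expected$quantity, "_MEAN")]),
               unname(fv[paste0(fx$expected$quantity, "_DT2")]))
})

test_that("feature vectors are complete and internally consistent on simulation", {
  fv <- assemble_feature_vector(cached_session())
  expect_length(fv, 68)
  for (s in c("_DT1", "_DT2", "_DT3", "_MEAN"))
    expect_equal(unname(fv[paste0("NA", s)]),
                 unname(fv[paste0("NSC", s)] + fv[paste0("NUC", s)]))
  broken <- cached_session()
  broken$blocks <- broken$blocks[1:2]
  expect_error(assemble_feature_vector(broken), "incomplete")
})

test_that("cohort imputation fills undefined slots with the column median", {
  tbl <- data.frame(participant_id = c("a", "b", "c"),
                    true_score = c(10, 12, 14))
  for (f in feature_names()) tbl[[f]] <- c(1, 2, 3)
  tbl$TTC_DT1 <- c(NA, 2, 4)
  out <- impute_feature_table(tbl)
  expect_equal(out$TTC_DT1, c(3, 2, 4))
  expect_equal(attr(out, "imputed")[["TTC_DT1"]], 1L)
})
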