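test_that("error and agreement metrics match their printed formulas", {
  y <- c(10, 10); yh <- c(9, 12)
  expect_equal(metric_mae(y, y), 0)
  expect_equal(metric_mae(y, yh), 1.5)
  set.seed(3)
  a <- runif(100, 1, 19); b <- a + rnorm(100)
  loop_mae <- 0
  for (i in seq_along(a)) loop_mae <- loop_mae + abs(b[i] - a[i])
  expect_equal(metric_mae(a, b), loop_mae / 100, tolerance = 1e-12)
  expect_error(metric_mae(a, b[1:10]), "length mismatch")

  expect_equal(metric_acc(c(10), c(9)), 0.9)
  expect_equal(metric_acc(a, a), 1)
  loop_acc <- 0
  for (i in seq_along(a)) loop_acc <- loop_acc + abs(a[i] - b[i]) / a[i]
  expect_equal(metric_acc(a, b), 1 - loop_acc / 100, tolerance = 1e-12)
  expect_error(metric_acc(c(0, 1), c(1, 1)), "zero true scores")

  expect_equal(metric_cc(a, 2 * a + 3), 1)
  expect_equal(metric_cc(a, -a), -1)
  expect_equal(metric_cc(a, b), pearson_with_p(a, b)$r, tolerance = 1e-12)
  expect_error(metric_cc(a, rep(1, 100)), "zero variance")
})

test_that("Bland-Altman limits follow bias +/- 1.96 SD of the differences", {
  y <- c(10, 12, 14)
  ba0 <- bland_altman(y, y)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$lo, 0)
  expect_equal(ba0$hi, 0)
  expect_equal(ba0$fraction_inside, 1)
  ba <- bland_altman(c(10, 10), c(11, 9))   # d = +1, -1
  expect_equal(ba$bias, 0)
  expect_equal(ba$hi, 1.96 * sqrt(2))
  expect_equal(ba$lo, -1.96 * sqrt(2))
  set.seed(5)
  d <- rnorm(20000)
  ba_big <- bland_altman(rep(0, 20000), d)
  expect_equal(ba_big$fraction_inside, 0.95, tolerance = 0.01)
  expect_error(bland_altman(1, 2), "two pairs")
})

test_that("recursive elimination recovers planted signals and respects k", {
  set.seed(1)
  X <- matrix(rnorm(300 * 8), 300, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- 2 * X[, 2] - 3 * X[, 5] + X[, 7]
  expect_equal(rfe_select(X, y, k = 3, model_spec("lasso")),
               c("f2", "f5", "f7"))
  expect_equal(rfe_select(X, y, k = 3, model_spec("svr")),
               c("f2", "f5", "f7"))
  expect_equal(rfe_select(X, y, k = 8, model_spec("lasso")), colnames(X))
  expect_error(rfe_select(X, y, k = 0), "positive")
  expect_error(rfe_select(X, y, k = 9), "exceeds")
  # deterministic given the spec seed
  expect_identical(rfe_select(X, y, k = 4, model_spec("lasso", seed = 7)),
                   rfe_select(X, y, k = 4, model_spec("lasso", seed = 7)))
})

test_that("fit_predict handles degenerate and noiseless cases", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("v", 1:5)))
  expect_equal(fit_predict(model_spec("lasso"), X, rep(7, 60), X[1:3, ]),
               rep(7, 3))
  y <- 3 + X %*% c(1, -2, 0.5, 0, 1)
  pred <- fit_predict(model_spec("lasso"), X, as.numeric(y), X)
  expect_lt(metric_mae(as.numeric(y), pred), 0.1)
  expect_gt(metric_cc(as.numeric(y), pred), 0.999)
  expect_error(fit_predict(model_spec("lasso"), X, c(y[-1], NA), X),
               "non-finite")
  for (kind in c("svr", "xgboost")) {
    p <- fit_predict(model_spec(kind), X, as.numeric(y), X)
    expect_gt(metric_cc(as.numeric(y), p), 0.95)
  }
})

test_that("LOSO evaluation has one fold per participant and no leakage", {
  tbl <- cohort50()[1:12, ]
  ev <- loso_evaluate(tbl, model_spec("lasso", seed = 4),
                      keep_fold_details = TRUE)
  expect_s3_class(ev, "eval_result")
  expect_equal(nrow(ev$predictions), 12)
  X <- as.matrix(tbl[, feature_names()])
  for (i in c(1, 5, 12)) {
    sc <- ev$fold_details[[i]]$scaling
    expect_equal(sc$center, colMeans(X[-i, ]), tolerance = 1e-12)
    expect_equal(sc$scale, apply(X[-i, ], 2, sd), tolerance = 1e-12)
  }
  expect_error(loso_evaluate(tbl[1:2, ], model_spec("lasso")), "at least 3")
  ev3 <- loso_evaluate(cohort50()[1:3, ], model_spec("lasso"))
  expect_equal(nrow(ev3$predictions), 3)
})

test_that("selection frequency ranks features by fold count with stable ties", {
  folds <- list(c("RTST_DT1", "CNST_DT3"), c("RTST_DT1", "HT_DT2"),
                c("RTST_DT1", "CNST_DT3"))
  sf <- selection_frequency(folds)
  expect_equal(sf$feature[1], "RTST_DT1")
  expect_equal(sf$count[1], 3)
  expect_equal(sf$fraction[1], 1)
  expect_equal(sf[sf$feature == "CNST_DT3", ]$count, 2)
  expect_false("NSC_DT1" %in% sf$feature)
  # tie broken by stable feature order (CNST before HT in the table order)
  tied <- selection_frequency(list(c("CNST_DT1", "HT_DT1")))
  expect_equal(tied$feature, c("CNST_DT1", "HT_DT1"))
  expect_error(selection_frequency(list()), "at least one fold")
})

test_that("paired feature-set comparison matches the t-test formula", {
  a <- c(1, 2, 3, 4); b <- a
  res <- compare_feature_sets(a, b)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(compare_feature_sets(a, a + 2), "degenerate")
  expect_error(compare_feature_sets(a, b[1:2]), "length mismatch")
  set.seed(6)
  ea <- runif(30); eb <- ea + rnorm(30, 0.1, 0.2)
  res <- compare_feature_sets(ea, eb)
  d <- ea - eb
  t_hand <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 29), tolerance = 1e-12)
})

test_that("per-dual-task evaluation restricts to 17 columns per block", {
  tbl <- cohort50()[1:15, ]
  res <- per_dual_task_eval(tbl, model_spec("lasso", seed = 9))
  expect_named(res, c("dt1", "dt2", "dt3", "combined"))
  for (b in 1:3) {
    expect_length(res[[paste0("dt", b)]]$feature_set, 17)
    expect_true(all(grepl(paste0("_DT", b, "$"),
                          res[[paste0("dt", b)]]$feature_set)))
  }
  expect_length(res$combined$feature_set, 68)
})
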