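#' Regression model specification
#'
#' Describes one of the three score regressors and its hyperparameter search:
#' LASSO (L1-regularized linear regression; penalty chosen by inner
#' cross-validation), SVR (epsilon support vector regression, radial kernel;
#' cost C chosen by inner cross-validation) or XGBoost (gradient boosted
#' trees; small fixed-seed grid). All hyperparameter selection happens inside
#' the training data of each outer fold.
#'
#' @param kind `"lasso"`, `"svr"` or `"xgboost"`.
#' @param grid Named list of hyperparameter candidates. Defaults: SVR
#'   `C = c(0.1, 1, 10, 100)`; XGBoost a single configuration
#'   (`max_depth = 3`, `eta = 0.1`, `nrounds = 150`); LASSO uses the internal
#'   `cv.glmnet` lambda path.
#' @param inner_cv_folds Folds of the inner cross-validation (default 5).
#' @param seed Seed for all stochastic components (fold assignment, trees).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("lasso", "svr", "xgboost"), grid = NULL,
                       inner_cv_folds = 5, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      lasso = list(),
      svr = list(C = c(0.1, 1, 10, 100)),
      xgboost = list(max_depth = 3, eta = 0.1, nrounds = 150))
  }
  structure(list(kind = kind, grid = grid,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# Train-fold standardization (z-score); constant columns get unit scale.
std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
std_apply <- function(X, s) scale(X, center = s$center, scale = s$scale)

#' Fit a regressor on training data and predict test rows
#'
#' Standardization (for LASSO/SVR) and all hyperparameter selection use the
#' training rows only; trees consume raw features. A constant training target
#' yields a constant prediction.
#'
#' @param spec A [model_spec()].
#' @param X_train,X_test Numeric matrices (or data frames) with identical
#'   columns.
#' @param y_train Numeric training targets.
#' @param details If `TRUE`, return a list with `pred` plus the fold
#'   preprocessing statistics and chosen hyperparameters.
#' @return Numeric predictions for the test rows (or the detail list).
#' @export
fit_predict <- function(spec, X_train, y_train, X_test, details = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  X_train <- as.matrix(X_train)
  X_test <- matrix(as.matrix(X_test), ncol = ncol(X_train),
                   dimnames = list(NULL, colnames(X_train)))
  if (!all(is.finite(X_train)) || !all(is.finite(y_train)))
    stop("non-finite values in training input")
  if (sd(y_train) == 0) {
    pred <- rep(y_train[1], nrow(X_test))
    return(if (details) list(pred = pred, scaling = NULL, hyper = NULL)
           else pred)
  }
  out <- switch(spec$kind,
    lasso = fit_lasso(spec, X_train, y_train, X_test),
    svr = fit_svr(spec, X_train, y_train, X_test),
    xgboost = fit_xgb(spec, X_train, y_train, X_test))
  if (details) out else out$pred
}

fit_lasso <- function(spec, X_train, y_train, X_test) {
  s <- std_fit(X_train)
  Xs <- std_apply(X_train, s)
  # keep at least 3 observations per inner fold
  k <- min(spec$inner_cv_folds, floor(nrow(Xs) / 3))
  if (k >= 3) {
    cv <- local_seed(spec$seed, {
      foldid <- sample(rep_len(seq_len(k), nrow(Xs)))
      glmnet::cv.glmnet(Xs, y_train, alpha = 1, foldid = foldid,
                        standardize = FALSE)
    })
    fit <- cv
    lam <- cv$lambda.min
  } else {
    # too few rows for inner CV: fall back to the least-penalized path point
    fit <- glmnet::glmnet(Xs, y_train, alpha = 1, standardize = FALSE)
    lam <- min(fit$lambda)
  }
  pred <- as.numeric(predict(fit, newx = std_apply(X_test, s), s = lam))
  list(pred = pred, scaling = s, hyper = list(lambda = lam))
}

fit_svr <- function(spec, X_train, y_train, X_test) {
  s <- std_fit(X_train)
  Xs <- std_apply(X_train, s)
  Cs <- spec$grid$C %||% 1
  C_best <- Cs[1]
  if (length(Cs) > 1) {
    cv_mse <- local_seed(spec$seed, {
      foldid <- sample(rep_len(seq_len(spec$inner_cv_folds), nrow(Xs)))
      vapply(Cs, function(C) {
        se <- 0
        for (f in seq_len(spec$inner_cv_folds)) {
          tr <- foldid != f
          if (sum(tr) < 2 || sum(!tr) == 0) next
          m <- e1071::svm(Xs[tr, , drop = FALSE], y_train[tr],
                          type = "eps-regression", kernel = "radial",
                          cost = C, scale = FALSE)
          p <- predict(m, Xs[!tr, , drop = FALSE])
          se <- se + sum((p - y_train[!tr])^2)
        }
        se
      }, numeric(1))
    })
    C_best <- Cs[which.min(cv_mse)]
  }
  m <- e1071::svm(Xs, y_train, type = "eps-regression", kernel = "radial",
                  cost = C_best, scale = FALSE)
  list(pred = as.numeric(predict(m, std_apply(X_test, s))),
       scaling = s, hyper = list(C = C_best))
}

fit_xgb <- function(spec, X_train, y_train, X_test) {
  g <- spec$grid
  combos <- expand.grid(max_depth = g$max_depth %||% 3, eta = g$eta %||% 0.1,
                        nrounds = g$nrounds %||% 150)
  pick <- combos[1, ]
  if (nrow(combos) > 1) {
    cv_mse <- local_seed(spec$seed, {
      foldid <- sample(rep_len(seq_len(spec$inner_cv_folds), nrow(X_train)))
      apply(combos, 1, function(cmb) {
        se <- 0
        for (f in seq_len(spec$inner_cv_folds)) {
          tr <- foldid != f
          m <- xgb_train(X_train[tr, , drop = FALSE], y_train[tr], cmb, spec$seed)
          p <- predict(m, xgboost::xgb.DMatrix(X_train[!tr, , drop = FALSE]))
          se <- se + sum((p - y_train[!tr])^2)
        }
        se
      })
    })
    pick <- combos[which.min(cv_mse), ]
  }
  m <- xgb_train(X_train, y_train, pick, spec$seed)
  list(pred = as.numeric(predict(m, xgboost::xgb.DMatrix(X_test))),
       scaling = NULL, hyper = as.list(pick), model = m)
}

xgb_train <- function(X, y, cmb, seed) {
  local_seed(seed, xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  max_depth = as.integer(cmb[["max_depth"]]),
                  eta = as.numeric(cmb[["eta"]]), nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = as.integer(cmb[["nrounds"]]), verbose = 0))
}

# Per-feature weights used by recursive feature elimination.
rfe_weights <- function(spec, X, y, lambda = NULL) {
  s <- std_fit(X)
  Xs <- std_apply(X, s)
  switch(spec$kind,
    lasso = {
      fit <- glmnet::glmnet(Xs, y, alpha = 1, lambda = lambda,
                            standardize = FALSE)
      abs(as.numeric(coef(fit))[-1])
    },
    svr = {
      m <- e1071::svm(Xs, y, type = "eps-regression", kernel = "linear",
                      scale = FALSE)
      abs(as.numeric(crossprod(m$coefs, m$SV)))
    },
    xgboost = {
      m <- xgb_train(X, y, list(max_depth = spec$grid$max_depth %||% 3,
                                eta = spec$grid$eta %||% 0.1,
                                nrounds = spec$grid$nrounds %||% 150),
                     spec$seed)
      imp <- xgboost::xgb.importance(model = m)
      w <- setNames(rep(0, ncol(X)), colnames(X))
      w[imp$Feature] <- imp$Gain
      unname(w)
    })
}

#' Recursive feature elimination
#'
#' Starting from all columns, repeatedly fits the estimator, assigns each
#' feature a weight (absolute standardized coefficient for LASSO, absolute
#' linear-SVR weight, gain importance for XGBoost) and removes the single
#' lowest-weight feature, until exactly `k` survive. Ties are broken by stable
#' column order. For LASSO the penalty is chosen once per call by inner
#' cross-validation on the full feature set and held fixed during elimination.
#'
#' @param X Feature matrix or data frame with column names.
#' @param y Numeric targets.
#' @param k Number of features to retain (default 10).
#' @param spec A [model_spec()].
#' @return Character vector of the `k` surviving feature names, in original
#'   column order.
#' @export
rfe_select <- function(X, y, k = 10, spec = model_spec("lasso")) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (k <= 0) stop("k must be positive")
  if (k > ncol(X)) stop("k exceeds the number of features")
  lambda <- NULL
  if (spec$kind == "lasso") {
    s <- std_fit(X)
    kf <- min(spec$inner_cv_folds, floor(nrow(X) / 3))
    lambda <- if (kf >= 3) {
      cv <- local_seed(spec$seed, {
        foldid <- sample(rep_len(seq_len(kf), nrow(X)))
        glmnet::cv.glmnet(std_apply(X, s), y, alpha = 1, foldid = foldid,
                          standardize = FALSE)
      })
      cv$lambda.min
    } else {
      min(glmnet::glmnet(std_apply(X, s), y, alpha = 1,
                         standardize = FALSE)$lambda)
    }
  }
  current <- colnames(X)
  while (length(current) > k) {
    w <- rfe_weights(spec, X[, current, drop = FALSE], y, lambda = lambda)
    current <- current[-which.min(w)]
  }
  colnames(X)[colnames(X) %in% current]
}

#' Mean absolute error
#'
#' `MAE = mean(|y_hat - y|)` on the score scale.
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return MAE.
#' @export
metric_mae <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (!length(y)) stop("empty input")
  mean(abs(y_hat - y))
}

#' Relative accuracy
#'
#' `ACC = 1 - mean(|y - y_hat| / y)`. Requires strictly positive true scores;
#' although nominally close to 1 for good predictions, the quantity is
#' unbounded below for poor ones.
#'
#' @inheritParams metric_mae
#' @return ACC.
#' @export
metric_acc <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (any(y == 0)) stop("relative accuracy undefined for zero true scores")
  1 - mean(abs(y - y_hat) / y)
}

#' Correlation coefficient between true and predicted scores
#'
#' `CC = cov(y, y_hat) / (sd(y) * sd(y_hat))`, the Pearson correlation; it is
#' invariant under positive affine transforms of the predictions and lies in
#' [-1, 1] (negative for anti-correlated predictions).
#'
#' @inheritParams metric_mae
#' @return CC.
#' @export
metric_cc <- function(y, y_hat) {
  if (sd(y) == 0 || sd(y_hat) == 0) stop("zero variance input")
  cov(y, y_hat) / (sd(y) * sd(y_hat))
}

#' @importFrom stats cov
NULL

#' Bland-Altman agreement of predictions with true scores
#'
#' Differences `d = y_hat - y`; bias is `mean(d)`, the 95% limits of agreement
#' are `bias +/- 1.96 * sd(d)`, and `fraction_inside` is the share of points
#' within the limits.
#'
#' @inheritParams metric_mae
#' @return List with `bias`, `lo`, `hi`, `fraction_inside`.
#' @export
bland_altman <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least two pairs")
  d <- y_hat - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, lo = bias - 1.96 * s, hi = bias + 1.96 * s,
       fraction_inside = mean(d >= bias - 1.96 * s & d <= bias + 1.96 * s))
}

#' Leave-one-subject-out evaluation of a score regressor
#'
#' One outer fold per participant: the model is trained on all other
#' participants and predicts the held-out one. Feature standardization,
#' hyperparameter selection and (in `"rfe"` mode) recursive feature
#' elimination are all re-run strictly inside each training fold, so no
#' held-out information leaks into preprocessing.
#'
#' @param tbl Feature table with `participant_id`, `true_score` and feature
#'   columns (at least 3 rows).
#' @param spec A [model_spec()].
#' @param mode Feature subset: `"all"` (68 features), `"stroop_only"` (CNST
#'   and RTST slots), `"behavior_only"` (the rest), or `"rfe"` (per-fold
#'   recursive elimination to `rfe_k` features).
#' @param rfe_k Subset size for `"rfe"` mode (default 10).
#' @param columns Optional explicit feature-column subset overriding `mode`.
#' @param keep_fold_details If `TRUE`, store per-fold preprocessing statistics
#'   and hyperparameters.
#' @return An `eval_result`: predictions per participant, `mae`, `acc`, `cc`,
#'   `bland_altman`, per-fold absolute errors, and in `"rfe"` mode the list of
#'   per-fold selected features.
#' @export
loso_evaluate <- function(tbl, spec = model_spec("lasso"),
                          mode = c("all", "stroop_only", "behavior_only", "rfe"),
                          rfe_k = 10, columns = NULL,
                          keep_fold_details = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(tbl)
  if (n < 3) stop("leave-one-subject-out needs at least 3 participants")
  cols <- columns %||% switch(mode,
    all = , rfe = intersect(feature_names(), names(tbl)),
    stroop_only = intersect(stroop_feature_names(), names(tbl)),
    behavior_only = intersect(behavior_feature_names(), names(tbl)))
  X <- as.matrix(tbl[, cols, drop = FALSE])
  y <- tbl$true_score
  preds <- numeric(n)
  fold_features <- if (mode == "rfe") vector("list", n) else NULL
  fold_details <- if (keep_fold_details) vector("list", n) else NULL
  for (i in seq_len(n)) {
    fold_spec <- spec
    fold_spec$seed <- spec$seed + i
    sel <- cols
    if (mode == "rfe") {
      sel <- rfe_select(X[-i, , drop = FALSE], y[-i], k = rfe_k,
                        spec = fold_spec)
      fold_features[[i]] <- sel
    }
    res <- fit_predict(fold_spec, X[-i, sel, drop = FALSE], y[-i],
                       X[i, sel, drop = FALSE], details = TRUE)
    preds[i] <- res$pred
    if (keep_fold_details)
      fold_details[[i]] <- list(scaling = res$scaling, hyper = res$hyper)
  }
  structure(list(
    predictions = data.frame(participant_id = tbl$participant_id,
                             y = y, y_hat = preds),
    mae = metric_mae(y, preds), acc = metric_acc(y, preds),
    cc = metric_cc(y, preds), bland_altman = bland_altman(y, preds),
    abs_errors = abs(preds - y), fold_features = fold_features,
    fold_details = fold_details, feature_set = cols, mode = mode,
    kind = spec$kind),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf("LOSO-CV evaluation (%s, %s features, %d folds)\n",
              x$kind, x$mode, nrow(x$predictions)))
  cat(sprintf("  MAE = %.3f  ACC = %.3f  CC = %.3f\n", x$mae, x$acc, x$cc))
  cat(sprintf("  Bland-Altman: bias %.3f, limits [%.3f, %.3f], %.0f%% inside\n",
              ba$bias, ba$lo, ba$hi, 100 * ba$fraction_inside))
  invisible(x)
}

#' Selection frequency of features across folds
#'
#' Counts in how many folds each feature was retained, ranked by descending
#' count with ties broken by stable feature order.
#'
#' @param fold_subsets List of character vectors (per-fold selected features),
#'   e.g. the `fold_features` element of an `"rfe"`-mode [loso_evaluate()]
#'   result.
#' @return Data frame with `feature`, `count`, `fraction`.
#' @export
selection_frequency <- function(fold_subsets) {
  if (!length(fold_subsets)) stop("need at least one fold")
  all_feats <- unique(unlist(fold_subsets))
  order_ref <- intersect(feature_names(), all_feats)
  order_ref <- c(order_ref, setdiff(all_feats, order_ref))
  counts <- vapply(order_ref, function(f)
    sum(vapply(fold_subsets, function(s) f %in% s, logical(1))), integer(1))
  out <- data.frame(feature = order_ref, count = counts,
                    fraction = counts / length(fold_subsets))
  out <- out[order(-out$count), ]
  rownames(out) <- NULL
  out
}

#' Paired comparison of two feature sets' per-subject errors
#'
#' Two-sided paired t-test on the per-participant absolute-error differences
#' of two evaluations of the same cohort.
#'
#' @param errors_a,errors_b Equal-length per-subject absolute errors, paired
#'   by participant.
#' @return List with `t`, `p`, `mean_diff` (a minus b).
#' @export
compare_feature_sets <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) stop("length mismatch")
  if (length(errors_a) < 2) stop("need at least two pairs")
  d <- errors_a - errors_b
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, mean_diff = 0))
    stop("degenerate paired differences: constant non-zero difference")
  }
  tt <- t.test(errors_a, errors_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d))
}

#' Evaluate each dual-task block separately and combined
#'
#' Restricts the feature table to one dual-task's 17 feature slots per run,
#' plus a combined run on all 68 features.
#'
#' @param tbl Feature table.
#' @param spec A [model_spec()].
#' @return List with elements `dt1`, `dt2`, `dt3`, `combined`, each an
#'   `eval_result`.
#' @export
per_dual_task_eval <- function(tbl, spec = model_spec("lasso")) {
  out <- lapply(1:3, function(b)
    loso_evaluate(tbl, spec, columns = intersect(dual_task_feature_names(b),
                                                 names(tbl))))
  names(out) <- paste0("dt", 1:3)
  out$combined <- loso_evaluate(tbl, spec, mode = "all")
  out
}
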