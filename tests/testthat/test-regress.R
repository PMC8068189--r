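test_that("make_splits partitions the compound set into disjoint covering triples", {
  ids <- sprintf("c%02d", 1:24)
  plan <- make_splits(ids, seed = 7)
  expect_length(plan$test, 8)
  expect_setequal(unlist(plan$test), ids)
  expect_equal(anyDuplicated(unlist(plan$test)), 0)
  for (s in 1:8) {
    expect_length(plan$test[[s]], 3)
    expect_setequal(plan$train[[s]], setdiff(ids, plan$test[[s]]))
  }
  expect_identical(make_splits(ids, seed = 7), plan)        # determinism
  # small case: brute-force partition properties
  p2 <- make_splits(letters[1:6], seed = 3, group_size = 3)
  expect_length(p2$test, 2)
  expect_setequal(unlist(p2$test), letters[1:6])
  expect_error(make_splits(letters[1:7], seed = 1), "group_size")
})

test_that("evaluate_metrics matches hand computation and handles edge cases", {
  m <- evaluate_metrics(c(1, 2, 3), c(1, 2, 5))
  expect_equal(m$rmse, sqrt(4 / 3))
  expect_equal(evaluate_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(rmse = 0, r = 1))
  expect_equal(evaluate_metrics(c(3, 2, 1), c(1, 2, 3))$r, -1)
  con <- evaluate_metrics(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(con$r))
  expect_gt(con$rmse, 0)
})

test_that("MLR recovers exact linear coefficients and SVM defaults are fixed", {
  x <- matrix(seq(0, 2, length.out = 12), 12, 1, dimnames = list(NULL, "x"))
  y <- 3 * x[, 1] + 1
  m <- fit_model(model_spec("mlr"), x, y)
  co <- m$fit$coef_fit$coef
  # coefficients are on the min-max normalized scale: slope 3 * range(x)
  expect_equal(unname(co["x"]), 3 * diff(range(x)), tolerance = 1e-9)
  expect_equal(unname(co["(Intercept)"]), 1, tolerance = 1e-9)
  expect_equal(predict(m, x), y, tolerance = 1e-9)

  s <- model_spec("svm")
  expect_equal(s$C, 1.0)
  expect_equal(s$exponent, 2.0)
})

test_that("SVR with the normalized quadratic kernel matches a dual QP oracle", {
  set.seed(5)
  n <- 5
  X <- matrix(runif(n * 2, 0.1, 1), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(1.0, 2.0, 1.5, 0.5, 2.5)
  spec <- model_spec("svm")
  m <- fit_model(spec, X, y)
  Xq <- matrix(runif(8, 0.1, 1), 4, 2, dimnames = list(NULL, c("a", "b")))
  pred_impl <- predict(m, Xq)

  # independent oracle: solve the epsilon-SVR dual with a generic
  # interior-point QP solver on the same normalized features and kernel
  st <- qsrrisk:::minmax_stats(X)
  Z <- qsrrisk:::minmax_apply(X, st)
  Zq <- qsrrisk:::minmax_apply(Xq, st)
  kf <- qsrrisk:::make_npoly_kernel(2)
  K <- outer(1:n, 1:n, Vectorize(function(i, j) kf(Z[i, ], Z[j, ])))
  eps <- spec$epsilon; C <- spec$C
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  sol <- kernlab::ipop(c(eps - y, eps + y), H,
                       matrix(c(rep(1, n), rep(-1, n)), 1), b = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0, sigf = 9)
  x <- kernlab::primal(sol)
  beta <- x[1:n] - x[(n + 1):(2 * n)]
  b0s <- c(); tol <- 1e-6
  for (i in 1:n) {
    if (x[i] > tol && x[i] < C - tol) b0s <- c(b0s, y[i] - eps - sum(beta * K[, i]))
    if (x[n + i] > tol && x[n + i] < C - tol) b0s <- c(b0s, y[i] + eps - sum(beta * K[, i]))
  }
  pred_oracle <- vapply(1:nrow(Zq), function(q) {
    sum(beta * vapply(1:n, function(i) kf(Z[i, ], Zq[q, ]), numeric(1))) +
      mean(b0s)
  }, numeric(1))
  expect_equal(pred_impl, pred_oracle, tolerance = 1e-4)
})

test_that("normalization maps training features to [0,1] without clipping tests", {
  set.seed(10)
  X <- matrix(rnorm(40, 5, 3), 20, 2, dimnames = list(NULL, c("u", "v")))
  m <- fit_model(model_spec("mlr"), X, rnorm(20))
  Z <- qsrrisk:::minmax_apply(X, m$stats)
  expect_true(all(Z >= 0 & Z <= 1))
  Xout <- matrix(c(100, -100), 1, 2, dimnames = list(NULL, c("u", "v")))
  Zout <- qsrrisk:::minmax_apply(Xout, m$stats)
  expect_gt(Zout[1, 1], 1)       # extrapolated, not clipped
  expect_lt(Zout[1, 2], 0)
  # zero-variance feature at train time: normalized to 0 with a warning
  Xz <- cbind(X, w = rep(4, 20))
  expect_warning(mz <- fit_model(model_spec("mlr"), Xz, rnorm(20)),
                 "zero-variance")
  expect_equal(unname(qsrrisk:::minmax_apply(Xz, mz$stats)[, "w"]),
               rep(0, 20))
})

test_that("predictions are invariant to feature column order for all algorithms", {
  set.seed(6)
  n <- 18
  X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, c("b", "d", "a", "c")))
  y <- 2 * X[, "a"] - X[, "c"] + rnorm(n, sd = 0.05) + 3
  Xq <- matrix(runif(12), 3, 4, dimnames = list(NULL, c("b", "d", "a", "c")))
  perm <- c("c", "a", "d", "b")
  for (alg in c("svm", "gpr", "mlr", "rf", "pls")) {
    m1 <- fit_model(model_spec(alg), X, y)
    m2 <- fit_model(model_spec(alg), X[, perm], y)
    expect_equal(predict(m1, Xq), predict(m2, Xq[, perm]),
                 tolerance = 1e-8, label = alg)
  }
})

test_that("PLS factor count from LOO never exceeds min(n - 1, p)", {
  set.seed(12)
  for (case in list(c(n = 8, p = 3), c(n = 6, p = 10))) {
    n <- case["n"]; p <- case["p"]
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rnorm(n)
    m <- fit_model(model_spec("pls"), X, y)
    expect_lte(m$fit$ncomp, min(n - 1, p))
  }
})

test_that("noiseless external validation recovers retention exactly with MLR", {
  sim <- generate_study(synthetic_spec(n_compounds = 12, p_descriptors = 20,
                                       n_informative = 3, n_blocks = 2,
                                       sigma = 0, seed = 31))
  study <- sim$study
  plan <- make_splits(study$compounds$id, seed = 5)
  val <- run_validation(study, plan, model_spec("mlr"), sim$truth$informative)
  expect_equal(nrow(val$metrics), 6)          # one row per screening condition
  expect_true(all(val$metrics$rmse < 1e-6))
  expect_true(all(val$metrics$r > 1 - 1e-9))
  expect_equal(nrow(val$pooled), 12 * 6)      # every compound tested once per condition
  # self-consistency: per-condition metrics equal recomputation from pooled pairs
  for (ci in unique(val$pooled$condition)) {
    d <- val$pooled[val$pooled$condition == ci, ]
    m <- evaluate_metrics(d$predicted, d$observed)
    expect_equal(val$metrics$rmse[val$metrics$condition == ci], m$rmse)
  }
})

test_that("validation skips compounds missing a retention value, with warning", {
  sim <- tiny_study(n = 6, seed = 13)
  study <- sim$study
  drop_row <- study$retention$compound_id == "cmp03" &
    study$retention$condition_id == "exp2"
  study$retention <- study$retention[!drop_row, ]
  plan <- make_splits(study$compounds$id, seed = 2, group_size = 3)
  expect_warning(
    val <- run_validation(study, plan, model_spec("mlr"),
                          sim$truth$informative),
    "cmp03")
  pooled2 <- val$pooled[val$pooled$condition == "exp2", ]
  expect_false("cmp03" %in% pooled2$compound)
})
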