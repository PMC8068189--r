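# Retention regression: five algorithms behind one fit/predict surface, the
# 8 x leave-3-out split protocol, and external validation metrics.

# --- ordinary least squares with least-norm fallback -----------------------

ols_fit <- function(X, y) {
  Xa <- cbind(`(Intercept)` = 1, as.matrix(X))
  qx <- qr(Xa)
  if (qx$rank < ncol(Xa)) {
    warning("rank-deficient linear fit; using minimum-norm solution")
    beta <- as.vector(MASS::ginv(Xa) %*% y)
  } else {
    beta <- qr.coef(qx, y)
  }
  names(beta) <- colnames(Xa)
  list(coef = beta)
}

ols_predict <- function(fit, X) {
  as.vector(cbind(1, as.matrix(X)) %*% fit$coef)
}

# --- split plan ------------------------------------------------------------

#' Leave-`group_size`-out split plan
#'
#' Randomly partitions the compound set into `n / group_size` disjoint test
#' groups (default triples); each training set is the complement of its
#' group, so with 24 compounds there are 8 pairs of a 3-compound external
#' test set and a 21-compound training set.
#'
#' @param compound_ids character vector of unique compound ids.
#' @param seed integer; the plan is deterministic given the seed.
#' @param group_size test-set size per split (default 3).
#' @return object of class `qsrr_splits`: list with `test` (list of id
#'   triples), `train` (complements) and `seed`.
#' @export
make_splits <- function(compound_ids, seed = 1, group_size = 3) {
  n <- length(compound_ids)
  if (anyDuplicated(compound_ids)) qstop("make_splits: duplicate compound ids")
  if (n %% group_size != 0) {
    qstop(paste("make_splits: %d compounds are not divisible into groups of %d;",
                "override group_size"), n, group_size)
  }
  perm <- with_seed(seed, sample(compound_ids))
  groups <- split(perm, rep(seq_len(n / group_size), each = group_size))
  names(groups) <- NULL
  structure(list(test = groups,
                 train = lapply(groups, function(g) setdiff(compound_ids, g)),
                 seed = as.integer(seed)),
            class = "qsrr_splits")
}

# --- model specification ---------------------------------------------------

#' Regression algorithm specification
#'
#' The five supported algorithms with their fixed settings:
#' \describe{
#'   \item{svm}{epsilon-SVR, complexity C = 1, normalized polynomial kernel
#'     with exponent 2 on min-max normalized features, epsilon = 1e-3.}
#'   \item{gpr}{Gaussian process regression, same kernel, noise variance 1
#'     on normalized targets, no hyperparameter tuning.}
#'   \item{mlr}{multiple linear regression with backward attribute
#'     elimination (drop the smallest standardized coefficient while AIC
#'     improves).}
#'   \item{rf}{random forest, 100 trees, `floor(log2 p) + 1` candidate
#'     features per split.}
#'   \item{pls}{partial least squares; factor count chosen by leave-one-out
#'     cross-validation, never exceeding `min(n - 1, p)`.}
#' }
#'
#' @param algorithm one of `"svm"`, `"gpr"`, `"mlr"`, `"rf"`, `"pls"`.
#' @param C,exponent,epsilon SVR settings.
#' @param noise GPR noise variance on normalized targets.
#' @param ntree,seed random-forest settings.
#' @param max_factors upper cap for PLS factor search (default 10).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("svm", "gpr", "mlr", "rf", "pls"),
                       C = 1.0, exponent = 2.0, epsilon = 1e-3,
                       noise = 1.0, ntree = 100, seed = 1, max_factors = 10) {
  algorithm <- match.arg(algorithm)
  stopifnot(C > 0, exponent > 0, epsilon > 0, noise > 0, ntree >= 1)
  structure(list(algorithm = algorithm, C = C, exponent = exponent,
                 epsilon = epsilon, noise = noise, ntree = as.integer(ntree),
                 seed = as.integer(seed), max_factors = as.integer(max_factors)),
            class = "model_spec")
}

# Normalized polynomial kernel K'(x,z) = K(x,z)/sqrt(K(x,x)K(z,z)) with
# K(x,z) = <x,z>^p, defined as 0 when either self-kernel vanishes.
make_npoly_kernel <- function(p) {
  k <- function(x, y) {
    kxy <- sum(x * y)^p
    kxx <- sum(x * x)^p
    kyy <- sum(y * y)^p
    if (kxx == 0 || kyy == 0) return(0)
    kxy / sqrt(kxx * kyy)
  }
  class(k) <- "kernel"
  k
}

# min-max normalization statistics frozen from training data
minmax_stats <- function(X) {
  rng <- apply(X, 2, range)
  list(min = rng[1, ], span = rng[2, ] - rng[1, ])
}

minmax_apply <- function(X, stats) {
  span <- stats$span
  zero <- span == 0
  if (any(zero)) span[zero] <- 1   # zero-variance feature maps to 0
  Z <- sweep(sweep(X, 2, stats$min, "-"), 2, span, "/")
  Z[, zero] <- 0
  Z
}

# --- fit / predict ---------------------------------------------------------

#' Fit a retention regression model
#'
#' Features are ordered canonically (lexicographically) at fit time so
#' predictions are invariant to the column order of the input, and min-max
#' normalization statistics are frozen from the training data only. Test
#' features outside the training range are extrapolated, not clipped.
#'
#' @param spec a [model_spec()].
#' @param X_train numeric matrix (rows = training compounds, columns =
#'   selected descriptors; named).
#' @param y_train numeric retention times (min).
#' @return object of class `qsrr_model`.
#' @export
fit_model <- function(spec, X_train, y_train) {
  stopifnot(inherits(spec, "model_spec"))
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2) qstop("fit_model: need at least 2 training rows")
  if (is.null(colnames(X_train))) qstop("fit_model: features must be named")
  stopifnot(nrow(X_train) == length(y_train))
  feats <- sort(colnames(X_train))
  X <- X_train[, feats, drop = FALSE]
  stats <- minmax_stats(X)
  if (any(stats$span == 0)) {
    warning("zero-variance feature(s) at train time; normalized value set to 0")
  }
  Z <- minmax_apply(X, stats)
  fit <- switch(spec$algorithm,
    svm = {
      kern <- make_npoly_kernel(spec$exponent)
      kernlab::ksvm(Z, y_train, type = "eps-svr", kernel = kern,
                    C = spec$C, epsilon = spec$epsilon, scaled = FALSE)
    },
    gpr = {
      kern <- make_npoly_kernel(spec$exponent)
      ymu <- mean(y_train); ysd <- sd(y_train)
      if (!is.finite(ysd) || ysd == 0) ysd <- 1
      g <- kernlab::gausspr(Z, (y_train - ymu) / ysd, type = "regression",
                            kernel = kern, var = spec$noise, scaled = FALSE)
      list(gp = g, ymu = ymu, ysd = ysd)
    },
    mlr = mlr_backward_fit(Z, y_train),
    rf = with_seed(spec$seed, {
      mtry <- max(1, min(ncol(Z), floor(log2(ncol(Z))) + 1))
      randomForest::randomForest(x = Z, y = y_train, ntree = spec$ntree,
                                 mtry = mtry)
    }),
    pls = pls_loo_fit(Z, y_train, max_factors = spec$max_factors)
  )
  structure(list(spec = spec, features = feats, stats = stats, fit = fit),
            class = "qsrr_model")
}

# MLR with backward attribute elimination: repeatedly drop the attribute
# with the smallest absolute standardized coefficient while AIC improves.
mlr_backward_fit <- function(Z, y) {
  active <- colnames(Z)
  aic_of <- function(cols) {
    f <- ols_fit(Z[, cols, drop = FALSE], y)
    rss <- sum((y - ols_predict(f, Z[, cols, drop = FALSE]))^2)
    n <- length(y)
    list(fit = f, aic = n * log(max(rss, 1e-300) / n) + 2 * (length(cols) + 1))
  }
  cur <- aic_of(active)
  while (length(active) > 1) {
    sds <- apply(Z[, active, drop = FALSE], 2, sd)
    sds[sds == 0] <- 1
    std_coef <- abs(cur$fit$coef[active] * sds)
    std_coef[is.na(std_coef)] <- 0
    cand <- active[-which.min(std_coef)]
    nxt <- aic_of(cand)
    if (nxt$aic < cur$aic) {
      active <- cand
      cur <- nxt
    } else break
  }
  list(coef_fit = cur$fit, active = active)
}

# PLS with leave-one-out selection of the factor count.
pls_loo_fit <- function(Z, y, max_factors = 10) {
  n <- nrow(Z); p <- ncol(Z)
  kmax <- max(1, min(n - 2, p, max_factors))  # n-2: LOO folds have n-1 rows
  press <- rep(NA_real_, kmax)
  for (k in seq_len(kmax)) {
    e <- numeric(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      f <- tryCatch(
        mixOmics::pls(Z[-i, , drop = FALSE], y[-i], ncomp = k,
                      mode = "regression", scale = FALSE),
        error = function(cnd) NULL)
      if (is.null(f)) { ok <- FALSE; break }
      pr <- predict(f, Z[i, , drop = FALSE])$predict[1, 1, k]
      e[i] <- pr - y[i]
    }
    if (ok) press[k] <- sum(e^2)
  }
  if (all(is.na(press))) qstop("PLS failed for every factor count")
  ncomp <- which.min(press)
  fit <- mixOmics::pls(Z, y, ncomp = ncomp, mode = "regression", scale = FALSE)
  list(pls = fit, ncomp = ncomp)
}

#' Predict retention times from a fitted model
#'
#' @param object a `qsrr_model`.
#' @param newdata numeric matrix carrying (at least) the model's feature
#'   columns, in any order.
#' @param ... unused.
#' @return numeric vector of predicted retention times.
#' @method predict qsrr_model
#' @export
predict.qsrr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    qstop("predict: missing feature(s): %s", paste(miss, collapse = ", "))
  }
  Z <- minmax_apply(newdata[, object$features, drop = FALSE], object$stats)
  out <- switch(object$spec$algorithm,
    svm = as.vector(kernlab::predict(object$fit, Z)),
    gpr = as.vector(kernlab::predict(object$fit$gp, Z)) * object$fit$ysd +
      object$fit$ymu,
    mlr = ols_predict(object$fit$coef_fit,
                      Z[, object$fit$active, drop = FALSE]),
    rf = as.vector(predict(object$fit, Z)),
    pls = as.vector(predict(object$fit$pls, Z)$predict[, 1, object$fit$ncomp])
  )
  unname(out)
}

# --- metrics and external validation ---------------------------------------

#' RMSE and Pearson correlation of predictions
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return list with `rmse` and `r` (`NA` when either vector is constant,
#'   with the reason attached as attribute `r_undefined`).
#' @export
evaluate_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 1)
  rmse <- sqrt(mean((predicted - observed)^2))
  r <- NA_real_
  if (length(observed) >= 2 && sd(observed) > 0 && sd(predicted) > 0) {
    r <- cor(predicted, observed)
  }
  out <- list(rmse = rmse, r = r)
  if (is.na(r)) attr(out, "r_undefined") <- "constant predictions or observations"
  out
}

#' External validation over the split plan and all screening conditions
#'
#' For every (split, condition) pair a model is trained on the 21-compound
#' training set's retention times at that condition and used to predict the
#' held-out triple. Test predictions are pooled per condition and summarised
#' as RMSE and R, reproducing the screening-condition validation table; the
#' pooled pairs support a predicted-vs-observed scatter.
#'
#' @param study a `qsrr_study`.
#' @param plan a `qsrr_splits`.
#' @param spec a [model_spec()].
#' @param features character vector of descriptor names to use for every
#'   split, or a list of one vector per split.
#' @return list with `metrics` (data.frame condition/rmse/r/n; pooling over
#'   all test triples per condition, recorded in attribute `pooling`),
#'   `pooled` (data.frame condition/split/compound/observed/predicted).
#' @export
run_validation <- function(study, plan, spec, features) {
  stopifnot(inherits(plan, "qsrr_splits"))
  M <- retention_matrix(study)
  X_all <- study$descriptors
  nsplit <- length(plan$train)
  if (!is.list(features)) features <- rep(list(features), nsplit)
  if (length(features) != nsplit) {
    qstop("run_validation: need one feature set per split (%d)", nsplit)
  }
  pooled <- NULL
  for (ci in study$conditions$condition_id) {
    for (s in seq_len(nsplit)) {
      tr_ids <- intersect(plan$train[[s]], rownames(X_all))
      te_ids <- intersect(plan$test[[s]], rownames(X_all))
      ytr <- M[tr_ids, ci]
      if (anyNA(ytr)) {
        drop <- tr_ids[is.na(ytr)]
        warning(sprintf("skipping training compound(s) without retention at %s: %s",
                        ci, paste(drop, collapse = ", ")))
        tr_ids <- setdiff(tr_ids, drop)
        ytr <- M[tr_ids, ci]
      }
      model <- fit_model(spec, X_all[tr_ids, features[[s]], drop = FALSE], ytr)
      yte <- M[te_ids, ci]
      if (anyNA(yte)) {
        drop <- te_ids[is.na(yte)]
        warning(sprintf("skipping test compound(s) without retention at %s: %s",
                        ci, paste(drop, collapse = ", ")))
        te_ids <- setdiff(te_ids, drop)
        yte <- M[te_ids, ci]
      }
      if (!length(te_ids)) next
      pr <- predict(model, X_all[te_ids, features[[s]], drop = FALSE])
      pooled <- rbind(pooled, data.frame(
        condition = ci, split = s, compound = te_ids,
        observed = unname(yte), predicted = pr, stringsAsFactors = FALSE))
    }
  }
  metrics <- do.call(rbind, lapply(split(pooled, pooled$condition), function(d) {
    m <- evaluate_metrics(d$predicted, d$observed)
    data.frame(condition = d$condition[1], rmse = m$rmse, r = m$r, n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  metrics <- metrics[match(study$conditions$condition_id, metrics$condition), ]
  rownames(metrics) <- NULL
  attr(metrics, "pooling") <- "all test triples pooled per condition before computing RMSE/R"
  list(metrics = metrics, pooled = pooled)
}
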