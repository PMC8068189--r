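# Wrapper feature selection: a generational genetic/evolutionary search over
# descriptor subsets whose fitness is the 7-fold cross-validated RMSE of an
# ordinary multiple linear regression on the subset. Repeated runs are
# aggregated into a consensus selection-frequency ranking.

#' Evolutionary-search parameters
#'
#' Defaults are the full-scale settings used for descriptor selection:
#' 1000 generations, population 100, 2% per-bit mutation, 6% crossover.
#'
#' @param generations number of generations (>= 1).
#' @param population_size individuals per generation (>= 1).
#' @param p_mutation per-bit flip probability.
#' @param p_crossover probability a mating pair undergoes single-point
#'   crossover.
#' @param seed base seed; all randomness in a run flows from it.
#' @param elitism number of best individuals copied unchanged (default 1).
#' @param init_density expected fraction of bits set at initialisation;
#'   sparse (0.05) so early linear fits on ~21 rows are well posed.
#' @return list of class `es_params`.
#' @export
es_params <- function(generations = 1000, population_size = 100,
                      p_mutation = 0.02, p_crossover = 0.06, seed = 1,
                      elitism = 1, init_density = 0.05) {
  stopifnot(generations >= 1, population_size >= 1,
            p_mutation >= 0, p_mutation <= 1,
            p_crossover >= 0, p_crossover <= 1,
            elitism >= 0, init_density > 0, init_density <= 1)
  structure(list(generations = as.integer(generations),
                 population_size = as.integer(population_size),
                 p_mutation = p_mutation, p_crossover = p_crossover,
                 seed = as.integer(seed), elitism = as.integer(elitism),
                 init_density = init_density),
            class = "es_params")
}

#' Cross-validated RMSE of a linear model on a descriptor subset
#'
#' The wrapper fitness: rows are shuffled once (driven by `seed`), split
#' into `folds` nearly equal folds, and an ordinary least-squares model with
#' intercept is fit on each training complement. Rank-deficient subsets fall
#' back to the minimum-norm solution with a warning rather than failing, so
#' the search can traverse oversized subsets.
#'
#' @param X numeric matrix (rows = compounds) restricted to the subset.
#' @param y numeric response (retention times).
#' @param folds number of folds (>= 2, <= rows). With 21 rows and 7 folds
#'   every fold holds exactly 3 compounds.
#' @param seed integer controlling the fold shuffle (the only randomness).
#' @return non-negative RMSE across the pooled held-out predictions.
#' @export
cv_rmse_mlr <- function(X, y, folds = 7, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (ncol(X) < 1) qstop("cv_rmse_mlr: empty descriptor subset")
  if (folds < 2) qstop("cv_rmse_mlr: folds must be >= 2")
  if (n < folds) qstop("cv_rmse_mlr: fewer rows (%d) than folds (%d)", n, folds)
  perm <- with_seed(seed, sample.int(n))
  fold_id <- rep_len(seq_len(folds), n)[order(perm)]  # balanced, shuffled
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- ols_fit(X[!test, , drop = FALSE], y[!test])
    pred[test] <- ols_predict(fit, X[test, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

#' Evolutionary search over descriptor subsets
#'
#' Generational GA: tournament selection (size 2), single-point crossover
#' with probability `p_crossover` per pair, independent per-bit mutation
#' with probability `p_mutation`, elitism. A chromosome emptied by the
#' operators is repaired by setting one random bit. Fitness (CV RMSE,
#' lower is better) is cached per subset; its fold shuffle is seeded from
#' `(params$seed, subset hash)` so a subset's fitness is a pure function of
#' the subset within a run.
#'
#' @param X pruned numeric descriptor matrix.
#' @param y numeric response.
#' @param params an [es_params()] object.
#' @param folds CV folds for the fitness (default 7).
#' @return list of class `es_result`: `subset` (selected column names),
#'   `bits` (logical vector), `fitness`, and `history` (best fitness per
#'   generation; non-increasing under elitism).
#' @export
evolutionary_search <- function(X, y, params = es_params(), folds = 7) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 0) qstop("evolutionary_search: descriptor matrix has zero columns")
  stopifnot(inherits(params, "es_params"), nrow(X) == length(y))

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(bits) {
    idx <- which(bits)
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- suppressWarnings(
      cv_rmse_mlr(X[, idx, drop = FALSE], y, folds = folds,
                  seed = hash_index_set(idx, params$seed)))
    cache[[key]] <- f
    f
  }

  with_seed(params$seed, {
    P <- params$population_size
    pop <- lapply(seq_len(P), function(i) {
      b <- runif(p) < params$init_density
      if (!any(b)) b[sample.int(p, 1)] <- TRUE
      b
    })
    fit <- vapply(pop, fitness_of, numeric(1))
    history <- numeric(params$generations)
    repair <- function(b) {
      if (!any(b)) b[sample.int(p, 1)] <- TRUE
      b
    }
    for (g in seq_len(params$generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(min(params$elitism, P))]]
      # tournament selection, size 2
      pick <- function() {
        ij <- sample.int(P, 2, replace = TRUE)
        if (fit[ij[1]] <= fit[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
      }
      children <- vector("list", P)
      i <- 1
      while (i <= P) {
        a <- pick(); b <- pick()
        if (runif(1) < params$p_crossover && p > 1) {
          cut <- sample.int(p - 1, 1)
          tmp <- a
          a <- c(a[1:cut], b[(cut + 1):p])
          b <- c(b[1:cut], tmp[(cut + 1):p])
        }
        a <- repair(xor(a, runif(p) < params$p_mutation))
        children[[i]] <- a
        if (i + 1 <= P) {
          b <- repair(xor(b, runif(p) < params$p_mutation))
          children[[i + 1]] <- b
        }
        i <- i + 2
      }
      if (length(elite)) children[seq_along(elite)] <- elite
      pop <- children
      fit <- vapply(pop, fitness_of, numeric(1))
      history[g] <- min(fit)
    }
    best <- which.min(fit)
    structure(list(subset = colnames(X)[pop[[best]]],
                   bits = pop[[best]],
                   fitness = fit[best],
                   history = history),
              class = "es_result")
  })
}

#' Consensus ranking of descriptors across search runs
#'
#' Counts how often each descriptor appears in the selected subsets of
#' repeated runs and returns the top `k` by frequency, ties broken
#' lexicographically by descriptor name.
#'
#' @param runs list of character vectors (selected subsets) or of
#'   `es_result` objects.
#' @param k maximum ranking length (default 30). When fewer distinct
#'   descriptors were seen, all are returned with a warning.
#' @return data.frame of class `consensus_ranking` with columns
#'   `descriptor`, `frequency` (integer, <= length(runs)), sorted by
#'   decreasing frequency.
#' @export
consensus_select <- function(runs, k = 30) {
  if (!length(runs)) qstop("consensus_select: no runs supplied")
  subsets <- lapply(runs, function(r) {
    if (inherits(r, "es_result")) unique(r$subset) else unique(as.character(r))
  })
  tab <- table(unlist(subsets))
  df <- data.frame(descriptor = names(tab),
                   frequency = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$descriptor), , drop = FALSE]
  if (k > nrow(df)) {
    warning(sprintf("requested top %d but only %d distinct descriptors seen",
                    k, nrow(df)))
    k <- nrow(df)
  }
  df <- df[seq_len(k), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("consensus_ranking", class(df))
  df
}

#' Repeated evolutionary search over all training sets
#'
#' Drives the full selection schedule: for every training set of the split
#' plan and every requested repeat, one evolutionary search is run on that
#' training set (response = retention at `condition`, or the mean retention
#' when `condition` is `NULL`), and all selected subsets are pooled into a
#' consensus ranking. With descriptor families tagged on the matrix, the
#' schedule can additionally be run per family combination by subsetting
#' `X` beforehand.
#'
#' @param X pruned descriptor matrix (all study compounds).
#' @param y_full named response vector over all compounds.
#' @param plan a `qsrr_splits` object from [make_splits()].
#' @param params an [es_params()]; each run derives its seed from
#'   `params$seed`, the split index and the repeat index.
#' @param repeats searches per training set (default 3).
#' @param k consensus ranking length (default 30).
#' @param folds CV folds for the fitness (default 7; must not exceed the
#'   training-set size).
#' @return list with `runs` (list of `es_result`), `ranking`
#'   (consensus data.frame) and `schedule` (data.frame split/repeat/seed).
#' @export
consensus_over_splits <- function(X, y_full, plan, params = es_params(),
                                  repeats = 3, k = 30, folds = 7) {
  stopifnot(inherits(plan, "qsrr_splits"))
  runs <- list()
  sched <- NULL
  for (s in seq_along(plan$train)) {
    train_ids <- plan$train[[s]]
    for (r in seq_len(repeats)) {
      run_seed <- hash_index_set(c(s * 1000L, r), params$seed)
      pp <- params; pp$seed <- run_seed
      res <- evolutionary_search(X[train_ids, , drop = FALSE],
                                 y_full[train_ids], pp, folds = folds)
      runs[[length(runs) + 1]] <- res
      sched <- rbind(sched, data.frame(split = s, repeat_no = r,
                                       seed = run_seed,
                                       fitness = res$fitness))
    }
  }
  list(runs = runs, ranking = consensus_select(runs, k = k), schedule = sched)
}
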