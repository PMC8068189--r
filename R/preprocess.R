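# Descriptor-matrix pruning and dataset similarity characterisation.
#
# Software descriptor generators emit thousands of columns, many constant or
# mutually redundant; regression and wrapper selection both need the matrix
# pruned first. The two filters below are deliberately simple and fully
# deterministic so a study can be re-run to the byte.

#' Remove (near-)zero-variance descriptors
#'
#' @param X numeric matrix, compounds x descriptors.
#' @param tol variance tolerance; a column is dropped when `var(col) <= tol`.
#'   Default 0: exact zero variance only.
#' @return list with `matrix` (retained columns, order preserved) and
#'   `removed` (character vector of dropped column names).
#' @export
filter_zero_variance <- function(X, tol = 0) {
  stopifnot(is.matrix(X), is.numeric(X), tol >= 0)
  v <- apply(X, 2, var)
  drop <- v <= tol
  if (all(drop)) qstop("no descriptors survive variance filter")
  if (any(drop)) {
    qlog("preprocess", "variance filter removed %d/%d descriptor(s)",
         sum(drop), ncol(X))
  }
  list(matrix = X[, !drop, drop = FALSE], removed = colnames(X)[drop])
}

#' Remove highly correlated descriptors, keeping the best retention correlate
#'
#' Builds the graph whose edges join descriptor pairs with absolute Pearson
#' correlation strictly above `threshold`, then processes each connected
#' component greedily: keep the column with the largest absolute correlation
#' to the retention vector (ties broken by lexicographic column name), drop
#' its neighbours, and repeat on what remains of the component. The retained
#' set therefore contains no pair above the threshold and every dropped
#' column is mapped to the survivor that displaced it.
#'
#' @param X numeric matrix, compounds x descriptors (variance-filtered).
#' @param retention_vector numeric vector aligned with `rownames(X)`; by
#'   convention the mean retention time of each compound across the
#'   screening conditions.
#' @param threshold absolute-correlation threshold in (0, 1); the comparison
#'   is strict, so a pair at exactly the threshold is retained.
#' @return list with `matrix` (survivors, input column order), `removed`
#'   (data.frame removed/kept_as/abs_r_retention), and `survivors`.
#' @export
filter_correlated <- function(X, retention_vector, threshold = 0.85) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (threshold <= 0 || threshold >= 1) qstop("threshold must lie in (0, 1)")
  if (length(retention_vector) != nrow(X)) {
    qstop("retention_vector length (%d) does not match matrix rows (%d)",
          length(retention_vector), nrow(X))
  }
  p <- ncol(X)
  nm <- colnames(X)
  C <- abs(suppressWarnings(cor(X)))
  C[is.na(C)] <- 0              # zero-variance guard; shouldn't occur post-filter
  diag(C) <- 0
  adj <- C > threshold
  r_y <- abs(suppressWarnings(cor(X, retention_vector)))[, 1]
  r_y[is.na(r_y)] <- 0

  keep <- logical(p)
  removed_from <- removed_to <- character(0)
  unassigned <- rep(TRUE, p)
  # connected components by BFS over the redundancy graph
  for (s in seq_len(p)) {
    if (!unassigned[s]) next
    comp <- integer(0); queue <- s; unassigned[s] <- FALSE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; comp <- c(comp, v)
      nb <- which(adj[v, ] & unassigned)
      unassigned[nb] <- FALSE
      queue <- c(queue, nb)
    }
    # greedy survivor selection inside the component
    active <- comp
    while (length(active)) {
      ord <- order(-r_y[active], nm[active])
      win <- active[ord[1]]
      keep[win] <- TRUE
      victims <- active[adj[win, active]]
      removed_from <- c(removed_from, nm[victims])
      removed_to <- c(removed_to, rep(nm[win], length(victims)))
      active <- setdiff(active, c(win, victims))
    }
  }
  report <- data.frame(removed = removed_from, kept_as = removed_to,
                       abs_r_retention = unname(r_y[match(removed_from, nm)]),
                       stringsAsFactors = FALSE)
  report <- report[order(report$removed), , drop = FALSE]
  rownames(report) <- NULL
  if (nrow(report)) {
    qlog("preprocess", "correlation filter removed %d/%d descriptor(s) at |r| > %g",
         nrow(report), p, threshold)
  }
  list(matrix = X[, keep, drop = FALSE], removed = report,
       survivors = nm[keep])
}

#' Mean retention time per compound
#'
#' Default retention reference for the correlation filter: the mean measured
#' retention time of each descriptor-matrix compound across all screening
#' conditions.
#'
#' @param study a `qsrr_study`.
#' @return named numeric vector aligned with the descriptor-matrix rows.
#' @export
mean_retention <- function(study) {
  M <- retention_matrix(study)
  m <- rowMeans(M, na.rm = TRUE)
  m[rownames(study$descriptors)]
}

#' Tanimoto (Jaccard) similarity of two index sets
#'
#' Set-level kernel underlying fingerprint similarity, exposed for direct
#' testing: |A n B| / |A u B|.
#'
#' @param a,b vectors of set members (e.g. on-bit indices).
#' @return similarity in \[0, 1\]; 1 for two empty sets by convention.
#' @export
tanimoto_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Pairwise Tanimoto similarity of the compound set
#'
#' Computes hashed 2048-bit atom-pair fingerprints from SMILES (via
#' ChemmineR/ChemmineOB) and the full pairwise Tanimoto matrix, plus the
#' fraction of off-diagonal pairs above a similarity cut. A congeneric
#' series suitable for a local retention model typically shows most pairs
#' above 0.8.
#'
#' @param compounds data.frame with columns `id` and `smiles` (all parseable).
#' @param nbits fingerprint length (default 2048).
#' @param cutoff similarity cut for the summary fraction (default 0.8).
#' @return list of class `qsrr_similarity`: `matrix` (symmetric, unit
#'   diagonal), `frac_above`, `cutoff`.
#' @export
describe_similarity <- function(compounds, nbits = 2048, cutoff = 0.8) {
  stopifnot(is.data.frame(compounds), all(c("id", "smiles") %in% names(compounds)))
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    qstop("describe_similarity requires ChemmineR and ChemmineOB")
  }
  if (anyNA(compounds$smiles)) {
    qstop("compound(s) without SMILES: %s",
          paste(compounds$id[is.na(compounds$smiles)], collapse = ", "))
  }
  smi <- compounds$smiles
  names(smi) <- compounds$id
  sdf <- tryCatch(ChemmineR::smiles2sdf(smi), error = function(e) {
    qstop("SMILES parsing failed: %s", conditionMessage(e))
  })
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    qstop("unparseable structure for compound(s): %s",
          paste(compounds$id[!ok], collapse = ", "))
  }
  ap <- ChemmineR::sdf2ap(sdf)
  # reference atom-pair vocabulary shipped with ChemmineR; loaded explicitly
  # so the namespace need not be attached
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  fp <- ChemmineR::desc2fp(ap, descnames = utils::head(e$apfp, nbits),
                           type = "FPset")
  n <- length(smi)
  S <- matrix(1, n, n, dimnames = list(compounds$id, compounds$id))
  for (i in seq_len(n)) {
    S[i, ] <- ChemmineR::fpSim(fp[i], fp, method = "Tanimoto", sorted = FALSE)
  }
  S <- (S + t(S)) / 2              # guard against last-bit asymmetry
  diag(S) <- 1
  off <- S[upper.tri(S)]
  res <- list(matrix = S,
              frac_above = if (length(off)) mean(off > cutoff) else NA_real_,
              cutoff = cutoff)
  class(res) <- "qsrr_similarity"
  res
}

#' @export
print.qsrr_similarity <- function(x, ...) {
  cat(sprintf("qsrr_similarity: %d compounds; %.1f%% of pairs above %.2f\n",
              nrow(x$matrix), 100 * x$frac_above, x$cutoff))
  invisible(x)
}

#' Run the full descriptor preprocessing stage
#'
#' Variance filter followed by the correlation filter against the mean
#' retention time.
#'
#' @param study a `qsrr_study`.
#' @param variance_tol,threshold see [filter_zero_variance()] and
#'   [filter_correlated()]; `threshold = NULL` uses the study config.
#' @return list with `matrix`, `variance_removed`, `correlation_removed`.
#' @export
preprocess_study <- function(study, variance_tol = 0, threshold = NULL) {
  threshold <- threshold %||% study$config$correlation_threshold
  zv <- filter_zero_variance(study$descriptors, tol = variance_tol)
  y <- mean_retention(study)
  if (anyNA(y)) {
    qstop("compound(s) in descriptor matrix without retention data: %s",
          paste(rownames(study$descriptors)[is.na(y)], collapse = ", "))
  }
  fc <- filter_correlated(zv$matrix, y, threshold = threshold)
  list(matrix = fc$matrix, variance_removed = zv$removed,
       correlation_removed = fc$removed)
}
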