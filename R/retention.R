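# Two-factor retention surfaces and resolution mapping.
#
# Each compound's gradient retention is summarised as
#   ln k(tG, u) = (a0 + a1*u + a2*u^2) + (b0 + b1*u + b2*u^2) * tG,
# with u = 1/T (T in Kelvin): linear in gradient time, quadratic in
# reciprocal temperature. A 2 (tG) x 3 (T) screening design determines the
# six coefficients exactly (no least-squares residual exists by
# construction), and the surface interpolates the design points to machine
# precision.

#' Retention time to retention factor (log scale) and back
#'
#' `lnk_from_tr` converts a retention time to the natural log of the
#' retention factor k = (tR - t0)/t0; `tr_from_lnk` inverts it.
#'
#' @param tr retention time(s), min; must exceed `t0`.
#' @param lnk natural-log retention factor(s).
#' @param t0 column dead time, min (> 0).
#' @return numeric vector.
#' @export
lnk_from_tr <- function(tr, t0) {
  if (t0 <= 0) qstop("t0 must be > 0")
  if (any(tr <= t0)) qstop("non-retained peak: tR <= t0 (tR = %g, t0 = %g)",
                           min(tr), t0)
  log((tr - t0) / t0)
}

#' @rdname lnk_from_tr
#' @export
tr_from_lnk <- function(lnk, t0) {
  if (t0 <= 0) qstop("t0 must be > 0")
  t0 * (1 + exp(lnk))
}

# design row of the surface model for (tG, u = 1/T_K)
surface_row <- function(tg, u) {
  cbind(1, u, u^2, tg, tg * u, tg * u^2)
}

#' Fit a compound's retention surface from the screening design
#'
#' Requires exactly one retention record per design condition, with the
#' design spanning at least 2 distinct gradient times and 3 distinct
#' temperatures (e.g. tG in {15, 45} min x T in {20, 40, 60} degC). The six
#' coefficients are obtained by solving the 6 x 6 linear system exactly.
#'
#' @param compound_id compound identifier (kept on the result).
#' @param tr named or ordered numeric vector of retention times (min), one
#'   per row of `conditions`.
#' @param conditions data.frame with `tg_min` and `temp_k` (and optionally
#'   `condition_id`) — the rows the retention values correspond to.
#' @param t0 column dead time (min).
#' @return object of class `retention_surface`: coefficients
#'   `a0,a1,a2,b0,b1,b2`, fitted ranges, `t0`.
#' @export
fit_retention_surface <- function(compound_id, tr, conditions, t0) {
  stopifnot(is.numeric(tr))
  if (length(tr) != nrow(conditions)) {
    qstop("surface fit for '%s': %d retention values for %d design conditions",
          compound_id, length(tr), nrow(conditions))
  }
  if (anyNA(tr)) {
    bad <- conditions$condition_id[is.na(tr)] %||% which(is.na(tr))
    qstop("surface fit for '%s': missing design cell(s): %s",
          compound_id, paste(bad, collapse = ", "))
  }
  tg <- conditions$tg_min
  u <- 1 / conditions$temp_k
  if (length(unique(tg)) < 2 || length(unique(u)) < 3) {
    qstop("surface fit for '%s': design must span >= 2 gradient times and >= 3 temperatures",
          compound_id)
  }
  D <- surface_row(tg, u)
  if (nrow(D) != 6) {
    qstop("surface fit for '%s': need exactly the 6 design conditions, got %d",
          compound_id, nrow(D))
  }
  lnk <- lnk_from_tr(tr, t0)
  cf <- tryCatch(solve(D, lnk), error = function(e) {
    qstop("surface fit for '%s': singular design", compound_id)
  })
  names(cf) <- c("a0", "a1", "a2", "b0", "b1", "b2")
  structure(list(compound = compound_id, coef = cf,
                 tg_range = range(tg), temp_k_range = range(conditions$temp_k),
                 t0 = t0),
            class = "retention_surface")
}

#' Fit retention surfaces for every compound in a study
#'
#' @param study a `qsrr_study` whose conditions form the 2 x 3 screening
#'   design.
#' @param retention optional replacement retention matrix (compounds x
#'   conditions), e.g. QSRR-predicted values; defaults to the experimental
#'   [retention_matrix()].
#' @param source provenance tag recorded on the result: `"experimental"`,
#'   `"qsrr"` or `"hybrid"`.
#' @return object of class `surface_set`: named list of
#'   `retention_surface` plus the tag.
#' @export
fit_surfaces <- function(study, retention = NULL, source = "experimental") {
  M <- retention %||% retention_matrix(study)
  M <- M[rowSums(is.na(M)) == 0, , drop = FALSE]
  if (!nrow(M)) qstop("no compound has a complete design row")
  surfaces <- lapply(rownames(M), function(id) {
    fit_retention_surface(id, M[id, study$conditions$condition_id],
                          study$conditions, study$config$t0)
  })
  names(surfaces) <- rownames(M)
  structure(list(surfaces = surfaces, source = source,
                 t0 = study$config$t0), class = "surface_set")
}

predict_lnk <- function(surface, tg, temp_c) {
  u <- 1 / celsius_to_kelvin(temp_c)
  as.vector(surface_row(tg, u) %*% surface$coef)
}

#' Predict retention time from a fitted surface
#'
#' @param surface a `retention_surface`.
#' @param tg gradient time (min).
#' @param temp_c column temperature (degC).
#' @param allow_extrapolation permit (tG, T) outside the fitted design
#'   ranges (default FALSE: out-of-range is an error).
#' @return retention time (min), always > t0.
#' @export
predict_retention <- function(surface, tg, temp_c, allow_extrapolation = FALSE) {
  stopifnot(inherits(surface, "retention_surface"))
  temp_k <- celsius_to_kelvin(temp_c)
  inside <- tg >= surface$tg_range[1] - 1e-9 & tg <= surface$tg_range[2] + 1e-9 &
    temp_k >= surface$temp_k_range[1] - 1e-9 & temp_k <= surface$temp_k_range[2] + 1e-9
  if (!allow_extrapolation && !all(inside)) {
    qstop("(tG = %g, T = %g) outside fitted ranges; pass allow_extrapolation = TRUE",
          tg[!inside][1], temp_c[!inside][1])
  }
  tr_from_lnk(predict_lnk(surface, tg, temp_c), surface$t0)
}

#' Resolution between two peaks
#'
#' Rs = |tR_i - tR_j| / peak_width, the USP formula specialised to a shared
#' baseline width.
#'
#' @param tr_i,tr_j retention times (min).
#' @param peak_width mean baseline peak width (min).
#' @return non-negative, symmetric resolution.
#' @export
pairwise_resolution <- function(tr_i, tr_j, peak_width) {
  if (peak_width <= 0) qstop("peak_width must be > 0")
  abs(tr_i - tr_j) / peak_width
}

#' Critical-pair resolution map over the (tG, T) plane
#'
#' Evaluates every surface on a rectangular grid and records, per cell, the
#' minimum pairwise resolution over all compound pairs ("overall
#' chromatogram resolution" in the critical-pair sense). Optionally retains
#' the full per-pair resolution tensor.
#'
#' @param surface_set a `surface_set` with >= 2 compounds.
#' @param config a `qsrr_config` (grid, peak width).
#' @param keep_pairs retain the per-pair tensor (pairs x tG x T).
#' @param allow_extrapolation evaluate outside the fitted ranges.
#' @return object of class `resolution_map`: `tg` (grid), `temp_c` (grid),
#'   `min_rs` (matrix tG x T), `source`, optionally `pair_rs`.
#' @export
build_resolution_map <- function(surface_set, config = qsrr_config(),
                                 keep_pairs = FALSE,
                                 allow_extrapolation = FALSE) {
  stopifnot(inherits(surface_set, "surface_set"))
  surfaces <- surface_set$surfaces
  if (length(surfaces) < 2) qstop("resolution undefined for a single compound")
  g <- config$grid
  tg_grid <- seq(g$tg[1], g$tg[2], length.out = g$tg[3])
  t_grid <- seq(g$temp[1], g$temp[2], length.out = g$temp[3])
  n <- length(surfaces)
  ids <- names(surfaces)
  pair_idx <- combn(n, 2)
  npair <- ncol(pair_idx)
  min_rs <- matrix(NA_real_, length(tg_grid), length(t_grid),
                   dimnames = list(tG = NULL, T = NULL))
  pair_rs <- if (keep_pairs) {
    array(NA_real_, dim = c(npair, length(tg_grid), length(t_grid)),
          dimnames = list(pair = paste(ids[pair_idx[1, ]], ids[pair_idx[2, ]],
                                       sep = "|"), NULL, NULL))
  } else NULL
  for (i in seq_along(tg_grid)) {
    for (j in seq_along(t_grid)) {
      tr <- vapply(surfaces, predict_retention, numeric(1),
                   tg = tg_grid[i], temp_c = t_grid[j],
                   allow_extrapolation = allow_extrapolation)
      rs <- pairwise_resolution(tr[pair_idx[1, ]], tr[pair_idx[2, ]],
                                config$peak_width)
      min_rs[i, j] <- min(rs)
      if (keep_pairs) pair_rs[, i, j] <- rs
    }
  }
  structure(list(tg = tg_grid, temp_c = t_grid, min_rs = min_rs,
                 pair_rs = pair_rs, source = surface_set$source,
                 peak_width = config$peak_width),
            class = "resolution_map")
}

#' Long-format view of a resolution map
#'
#' @param map a `resolution_map`.
#' @return data.frame with columns `tg_min`, `temp_c`, `min_rs`.
#' @export
resolution_map_table <- function(map) {
  stopifnot(inherits(map, "resolution_map"))
  data.frame(tg_min = rep(map$tg, times = length(map$temp_c)),
             temp_c = rep(map$temp_c, each = length(map$tg)),
             min_rs = as.vector(map$min_rs))
}

#' Select the robust centre point of a resolution map
#'
#' The centre point is the grid cell whose worst critical-pair resolution
#' over its neighbourhood (a (2r+1) x (2r+1) window, truncated at the map
#' edge) is maximal — i.e. the condition where overall resolution is both
#' high and least affected by small changes in tG or T. Ties are broken by
#' the cell's own resolution, then by lexicographic (tG, T).
#'
#' @param map a `resolution_map`.
#' @param radius neighbourhood radius in cells (default 1: 3 x 3 window).
#' @return list with `tg`, `temp_c`, `robustness` (neighbourhood minimum)
#'   and `value` (the cell's own critical-pair resolution), or `NULL` (with
#'   a warning) when the map is identically zero.
#' @export
select_center_point <- function(map, radius = 1) {
  stopifnot(inherits(map, "resolution_map"), radius >= 0)
  M <- map$min_rs
  if (all(M == 0)) {
    warning("resolution map is identically zero; no centre point")
    return(NULL)
  }
  nr <- nrow(M); nc <- ncol(M)
  rob <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- max(1, i - radius):min(nr, i + radius)
      jj <- max(1, j - radius):min(nc, j + radius)
      rob[i, j] <- min(M[ii, jj])
    }
  }
  # robustness first, then own value, then lexicographic (tG, T)
  best <- which(rob == max(rob), arr.ind = TRUE)
  if (nrow(best) > 1) {
    vals <- M[best]
    best <- best[vals == max(vals), , drop = FALSE]
  }
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(tg = map$tg[best[1]], temp_c = map$temp_c[best[2]],
       robustness = rob[best[1], best[2]], value = M[best[1], best[2]])
}

#' Retention times of all compounds at one condition
#'
#' @param surface_set a `surface_set`.
#' @param tg,temp_c the condition.
#' @param allow_extrapolation see [predict_retention()].
#' @return named numeric vector of retention times (min).
#' @export
retention_at <- function(surface_set, tg, temp_c, allow_extrapolation = FALSE) {
  stopifnot(inherits(surface_set, "surface_set"))
  vapply(surface_set$surfaces, predict_retention, numeric(1),
         tg = tg, temp_c = temp_c, allow_extrapolation = allow_extrapolation)
}
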