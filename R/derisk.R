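# Co-elution de-risking: the resolution coefficient, combinatorial
# separability of hypothetical mixtures, hybrid retention sources, and
# agreement between experimental and QSRR-derived retention models.

#' Resolution coefficient of a mixture
#'
#' For a mixture with pairwise resolutions Rs_ij, each pair contributes the
#' factor exp(-(Rs_limit / Rs_capped - 1)) with Rs_capped = min(Rs_ij,
#' Rs_limit), and RC is the product over all pairs. A pair at or above the
#' limit contributes exactly 1, so RC = 1 iff every pair is baseline
#' separated; a co-eluting pair (Rs = 0) drives RC to 0; everything else
#' falls strictly between.
#'
#' @param pairwise_rs non-negative vector of pairwise resolutions.
#' @param rs_limit minimal satisfactory resolution (default 1.25).
#' @return RC in \[0, 1\]; a singleton mixture (no pairs) returns 1 with a
#'   warning.
#' @export
resolution_coefficient <- function(pairwise_rs, rs_limit = 1.25) {
  if (rs_limit <= 0) qstop("rs_limit must be > 0")
  if (!length(pairwise_rs)) {
    warning("singleton mixture: RC = 1 by convention")
    return(1)
  }
  if (any(pairwise_rs < 0)) qstop("resolutions must be >= 0")
  capped <- pmin(pairwise_rs, rs_limit)
  # Rs = 0 gives rs_limit/0 = Inf, exp(-Inf) = 0: the co-elution limit
  prod(exp(-(rs_limit / capped - 1)))
}

# adjacency bitmasks of the "separated" graph: edge when Rs >= rs_limit
separation_masks <- function(rt, peak_width, rs_limit) {
  n <- length(rt)
  if (n > 30) qstop("separability analysis supports at most 30 compounds")
  ord <- seq_len(n)
  masks <- integer(n)
  for (i in seq_len(n)) {
    rs <- pairwise_resolution(rt[i], rt, peak_width)
    sep <- rs >= rs_limit
    sep[i] <- FALSE
    masks[i] <- sum(bitwShiftL(1L, which(sep) - 1L))
  }
  masks
}

#' Count fully separable mixtures of each size
#'
#' A candidate mixture has RC = 1 exactly when every pair resolves at or
#' above `rs_limit`, i.e. when it forms a clique in the graph whose edges
#' are the separated pairs. Counts are obtained by pruned clique
#' enumeration (each branch dies as soon as no compatible compound
#' remains), which handles the full 24-compound, sizes 2..10 census
#' (~3.5 M candidate subsets) in well under a second.
#'
#' @param rt named numeric vector of retention times at one condition (min).
#' @param sizes mixture sizes to census (default 2:10).
#' @param config a `qsrr_config` (peak width, rs_limit).
#' @return data.frame with `size`, `separable` (count of RC = 1 subsets)
#'   and `total` (= choose(n, size)).
#' @export
count_separable_subsets <- function(rt, sizes = 2:10, config = qsrr_config()) {
  n <- length(rt)
  sizes <- as.integer(sizes)
  if (any(sizes < 2) || any(sizes > n)) {
    qstop("sizes must lie in [2, %d]", n)
  }
  masks <- separation_masks(rt, config$peak_width, config$rs_limit)
  counts <- clique_counts_cpp(masks, max(sizes))
  data.frame(size = sizes, separable = counts[sizes],
             total = choose(n, sizes))
}

#' Agreement between two retention models on mixture separability
#'
#' For every mixture size, counts the mixtures that both retention sources
#' (typically experimental vs QSRR-predicted) declare baseline separated
#' (RC = 1 under both), and expresses it as a percentage of either the
#' mixtures the experimental source separates (`denominator =
#' "exp-separated"`) or of all C(n, k) mixtures (`"all"`). Both counts are
#' always returned; the convention only selects the reported percentage.
#'
#' @param rt_exp,rt_model named retention-time vectors over the same
#'   compounds at the same condition (min).
#' @param sizes mixture sizes (default 2:10).
#' @param denominator `"exp-separated"` (default) or `"all"`.
#' @param config a `qsrr_config`.
#' @return data.frame of class `agreement_curve`: `size`, `both`,
#'   `exp_separated`, `model_separated`, `total`, `pct`; the convention is
#'   recorded in attribute `denominator`.
#' @export
model_agreement_curve <- function(rt_exp, rt_model, sizes = 2:10,
                                  denominator = c("exp-separated", "all"),
                                  config = qsrr_config()) {
  denominator <- match.arg(denominator)
  if (is.null(names(rt_exp)) || is.null(names(rt_model))) {
    qstop("retention vectors must be named by compound id")
  }
  if (!setequal(names(rt_exp), names(rt_model))) {
    qstop("compound mismatch between retention sources")
  }
  rt_model <- rt_model[names(rt_exp)]
  n <- length(rt_exp)
  sizes <- as.integer(sizes)
  m_exp <- separation_masks(rt_exp, config$peak_width, config$rs_limit)
  m_mod <- separation_masks(rt_model, config$peak_width, config$rs_limit)
  m_both <- bitwAnd(m_exp, m_mod)
  kmax <- max(sizes)
  c_exp <- clique_counts_cpp(m_exp, kmax)
  c_mod <- clique_counts_cpp(m_mod, kmax)
  c_both <- clique_counts_cpp(m_both, kmax)
  den <- if (denominator == "exp-separated") c_exp[sizes] else choose(n, sizes)
  pct <- ifelse(den > 0, 100 * c_both[sizes] / den, NA_real_)
  out <- data.frame(size = sizes, both = c_both[sizes],
                    exp_separated = c_exp[sizes],
                    model_separated = c_mod[sizes],
                    total = choose(n, sizes), pct = pct)
  attr(out, "denominator") <- denominator
  class(out) <- c("agreement_curve", class(out))
  out
}

#' Replace a fraction of model retention times with experimental values
#'
#' Emulates the practical situation where measured retention times are
#' available for part of the sample set: a random `round(fraction * n)`
#' compounds carry the experimental value, the rest keep the model value.
#'
#' @param rt_model,rt_exp named retention vectors over the same compounds.
#' @param fraction fraction of compounds to replace, in \[0, 1\] (0.2 of a
#'   24-compound set replaces exactly 5).
#' @param seed integer; the replaced set is deterministic given the seed.
#' @return list with `rt` (hybrid vector) and `replaced` (compound ids).
#' @export
hybrid_replacement <- function(rt_model, rt_exp, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!setequal(names(rt_exp), names(rt_model))) {
    qstop("compound mismatch between retention sources")
  }
  rt_exp <- rt_exp[names(rt_model)]
  m <- round(fraction * length(rt_model))
  replaced <- if (m > 0) {
    with_seed(seed, sample(names(rt_model), m))
  } else character(0)
  rt <- rt_model
  rt[replaced] <- rt_exp[replaced]
  list(rt = rt, replaced = sort(replaced))
}

#' Pairwise agreement of resolution coefficients between two models
#'
#' Computes the single-pair RC under both retention sources for every
#' compound pair, excluding pairs whose experimental resolution exceeds
#' `rs_exclude` (those separate under any plausible prediction error), and
#' bins the absolute RC differences. The first bin \[0, 0.1\] is the
#' "within +/- 0.1" agreement fraction.
#'
#' @param rt_exp,rt_model named retention vectors over the same compounds.
#' @param config a `qsrr_config` (peak width, rs_limit, rs_exclude).
#' @param breaks histogram breakpoints on |RC_model - RC_exp| (default
#'   0, 0.1, ..., 1).
#' @return list of class `rc_agreement`: `histogram` (data.frame interval /
#'   count / pct), `pairs` (per-pair detail), `n_excluded`.
#' @export
pairwise_rc_agreement <- function(rt_exp, rt_model, config = qsrr_config(),
                                  breaks = seq(0, 1, by = 0.1)) {
  if (!setequal(names(rt_exp), names(rt_model))) {
    qstop("compound mismatch between retention sources")
  }
  rt_model <- rt_model[names(rt_exp)]
  n <- length(rt_exp)
  pr <- combn(n, 2)
  rs_exp <- pairwise_resolution(rt_exp[pr[1, ]], rt_exp[pr[2, ]],
                                config$peak_width)
  rs_mod <- pairwise_resolution(rt_model[pr[1, ]], rt_model[pr[2, ]],
                                config$peak_width)
  keep <- rs_exp <= config$rs_exclude
  n_excluded <- sum(!keep)
  if (!any(keep)) {
    warning("no pairs remain after the resolution-exclusion rule")
    hist <- data.frame(interval = character(0), count = integer(0),
                       pct = numeric(0))
    return(structure(list(histogram = hist,
                          pairs = data.frame(), n_excluded = n_excluded),
                     class = "rc_agreement"))
  }
  rc1 <- function(rs) exp(-(config$rs_limit / pmin(rs, config$rs_limit) - 1))
  rc_exp <- rc1(rs_exp[keep])
  rc_mod <- rc1(rs_mod[keep])
  d <- abs(rc_mod - rc_exp)
  bin <- cut(d, breaks = breaks, include.lowest = TRUE, right = TRUE)
  tab <- table(bin)
  hist <- data.frame(interval = names(tab), count = as.integer(tab),
                     pct = 100 * as.integer(tab) / sum(tab),
                     stringsAsFactors = FALSE)
  pairs <- data.frame(
    i = names(rt_exp)[pr[1, keep]], j = names(rt_exp)[pr[2, keep]],
    rs_exp = unname(rs_exp[keep]), rs_model = unname(rs_mod[keep]),
    rc_exp = unname(rc_exp), rc_model = unname(rc_mod),
    abs_diff = unname(d), stringsAsFactors = FALSE)
  structure(list(histogram = hist, pairs = pairs, n_excluded = n_excluded),
            class = "rc_agreement")
}

#' @export
print.rc_agreement <- function(x, ...) {
  within <- if (nrow(x$histogram)) x$histogram$pct[1] else NA_real_
  cat(sprintf("rc_agreement: %d pairs (%d excluded); %.1f%% within +/-0.1\n",
              sum(x$histogram$count), x$n_excluded, within))
  invisible(x)
}
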