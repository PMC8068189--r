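#' Study configuration
#'
#' Assembles and validates the tunable parameters shared across the pipeline.
#' Defaults reflect routine small-molecule reversed-phase practice on a
#' 2.1 x 100 mm column at 0.4 mL/min.
#'
#' @param t0 column dead time in minutes (elution time of an unretained
#'   marker). Required for every conversion between retention time and the
#'   retention factor k = (tR - t0)/t0. Default 0.55 min.
#' @param peak_width mean baseline peak width in minutes used in the
#'   resolution formula Rs = |dtR| / width. Default 0.1 min.
#' @param rs_limit minimal satisfactory resolution between two components;
#'   pairs at or above it are treated as baseline separated. Default 1.25.
#' @param rs_exclude pairwise-resolution ceiling above which pairs are
#'   excluded from the pairwise risk-agreement analysis (such pairs separate
#'   under any plausible prediction error). Default 20.
#' @param correlation_threshold absolute Pearson correlation above which two
#'   descriptors are considered redundant. Default 0.85.
#' @param cv_folds folds for cross-validated model fitness. Default 7.
#' @param seed base random seed.
#' @param grid resolution-map grid specification: a list with `tg = c(min,
#'   max, n)` in minutes and `temp = c(min, max, n)` in degrees Celsius.
#' @return a validated list of class `qsrr_config`.
#' @export
qsrr_config <- function(t0 = 0.55, peak_width = 0.1, rs_limit = 1.25,
                        rs_exclude = 20, correlation_threshold = 0.85,
                        cv_folds = 7, seed = 1,
                        grid = list(tg = c(15, 45, 61), temp = c(20, 60, 41))) {
  cfg <- list(t0 = t0, peak_width = peak_width, rs_limit = rs_limit,
              rs_exclude = rs_exclude,
              correlation_threshold = correlation_threshold,
              cv_folds = as.integer(cv_folds), seed = as.integer(seed),
              grid = grid)
  validate_config(cfg)
  class(cfg) <- "qsrr_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$t0 <= 0) qstop("config: t0 must be > 0 (got %g)", cfg$t0)
  if (cfg$peak_width <= 0) qstop("config: peak_width must be > 0")
  if (cfg$rs_limit <= 0) qstop("config: rs_limit must be > 0")
  if (cfg$rs_exclude <= cfg$rs_limit) {
    qstop("config: rs_exclude (%g) must exceed rs_limit (%g)",
          cfg$rs_exclude, cfg$rs_limit)
  }
  if (cfg$correlation_threshold <= 0 || cfg$correlation_threshold >= 1) {
    qstop("config: correlation_threshold must lie in (0, 1)")
  }
  if (cfg$cv_folds < 2) qstop("config: cv_folds must be >= 2")
  for (ax in c("tg", "temp")) {
    g <- cfg$grid[[ax]]
    if (length(g) != 3 || g[2] <= g[1] || g[3] < 2) {
      qstop("config: grid$%s must be c(min, max, n) with max > min, n >= 2", ax)
    }
  }
  invisible(cfg)
}

#' Read a YAML configuration file
#'
#' Unspecified fields fall back to the [qsrr_config()] defaults; unknown
#' fields are rejected so typos do not silently revert to defaults.
#'
#' @param path path to a YAML file.
#' @return a `qsrr_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) qstop("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(qsrr_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) qstop("config: unknown field(s): %s", paste(bad, collapse = ", "))
  if (!is.null(raw$grid)) {
    raw$grid <- lapply(raw$grid, as.numeric)
  }
  do.call(qsrr_config, raw)
}
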