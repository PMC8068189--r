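# Synthetic study generator.
#
# Emulates the statistical structure the pipeline assumes — a congeneric set
# of ~24 compounds screened over a 2 (gradient time) x 3 (temperature)
# design — without any proprietary data: descriptor matrices with planted
# correlation blocks (exercising the |r| > 0.85 filter) and a small
# informative subset, retention times that are exactly linear in the
# informative descriptors at each condition, and observation noise applied
# on the ln k scale. The true per-compound retention surface is the exact
# 6 x 6 solve of the noiseless design points, so it is exactly linear in tG
# and quadratic in 1/T by construction.

#' The default 2 x 3 screening design
#'
#' Six full-gradient screening conditions: tG in \{15, 45\} min crossed with
#' column temperature in \{20, 40, 60\} degC, 5 to 95 %B.
#'
#' @return conditions data.frame in the standard layout.
#' @export
default_design <- function() {
  df <- data.frame(
    condition_id = paste0("exp", 1:6),
    temperature_c = c(20, 20, 40, 40, 60, 60),
    tg_min = c(15, 45, 15, 45, 15, 45),
    pctb_start = 5, pctb_end = 95,
    stringsAsFactors = FALSE)
  df$temp_k <- celsius_to_kelvin(df$temperature_c)
  df
}

#' Synthetic study specification
#'
#' @param n_compounds compounds in the set (default 24: a main component
#'   plus 23 related substances).
#' @param p_descriptors descriptor columns (default 300).
#' @param n_informative descriptors that truly drive retention (default 8).
#' @param coef_scale retention spread (min) contributed by the informative
#'   descriptors at the long gradient; controls how far apart the
#'   congeneric series elutes. Default 1.8 min.
#' @param rho within-block descriptor correlation for the planted redundant
#'   blocks (default 0.9, above the 0.85 pruning threshold).
#' @param n_blocks,block_size redundant-block layout (default 6 blocks of 3).
#' @param sigma observation noise SD on the ln k scale (default 0.05, which
#'   places synthetic external-validation RMSE in the tenths-of-a-minute
#'   range typical of gradient screening data).
#' @param t0 column dead time (min).
#' @param design conditions data.frame (default [default_design()]).
#' @param seed integer; every random draw flows from it.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 24, p_descriptors = 300,
                           n_informative = 8, coef_scale = 1.8, rho = 0.9,
                           n_blocks = 6, block_size = 3, sigma = 0.05,
                           t0 = 0.55, design = default_design(), seed = 1) {
  stopifnot(n_informative <= p_descriptors, sigma >= 0, t0 > 0,
            rho >= 0, rho < 1, n_compounds >= 2,
            n_blocks * block_size + n_informative <= p_descriptors)
  if (length(unique(design$tg_min)) < 2 ||
      length(unique(design$temperature_c)) < 3) {
    qstop("design must span >= 2 gradient times and >= 3 temperatures")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 p_descriptors = as.integer(p_descriptors),
                 n_informative = as.integer(n_informative),
                 coef_scale = coef_scale, rho = rho,
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 sigma = sigma, t0 = t0, design = design,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic study with known ground truth
#'
#' Descriptors are standard normal: `n_blocks` blocks of `block_size`
#' columns share a latent factor (pairwise correlation `rho`), the rest are
#' independent; the informative subset is drawn from the independent
#' columns. At each design condition c the true retention time is
#' `centre_c + w_c' x` (linear in the informative descriptors, with the
#' spread scaled by gradient time and mildly by temperature); the observed
#' retention factor is the true one perturbed by `exp(N(0, sigma))`.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_study`: `study` (a `qsrr_study`) and
#'   `truth` (informative descriptor names, per-condition centres and
#'   weights, true `surface_set`, sigma).
#' @export
generate_study <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds; p <- spec$p_descriptors
  design <- spec$design
  with_seed(spec$seed, {
    ids <- sprintf("cmp%02d", seq_len(n))
    dnames <- sprintf("d%03d", seq_len(p))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(ids, dnames))
    # planted redundant blocks: x = sqrt(rho) z + sqrt(1-rho) e
    block_cols <- integer(0)
    for (b in seq_len(spec$n_blocks)) {
      cols <- (b - 1) * spec$block_size + seq_len(spec$block_size)
      z <- rnorm(n)
      X[, cols] <- sqrt(spec$rho) * z +
        sqrt(1 - spec$rho) * matrix(rnorm(n * spec$block_size), n)
      block_cols <- c(block_cols, cols)
    }
    free_cols <- setdiff(seq_len(p), block_cols)
    informative <- sort(sample(free_cols, spec$n_informative))
    # descriptor family tags, mimicking a multi-generator provenance mix
    fam <- rep("dragon", p)
    fam[seq_len(p) %% 10 == 0] <- "moe"
    fam[seq_len(p) %% 25 == 0] <- "volsurf"
    names(fam) <- dnames
    attr(X, "family") <- fam

    w0 <- runif(spec$n_informative, 0.4, 1) *
      sample(c(-1, 1), spec$n_informative, replace = TRUE)
    w0 <- w0 / sqrt(sum(w0^2))

    centres <- numeric(nrow(design)); weights <- list()
    TR <- matrix(NA_real_, n, nrow(design),
                 dimnames = list(ids, design$condition_id))
    for (ci in seq_len(nrow(design))) {
      tg <- design$tg_min[ci]; tc <- design$temperature_c[ci]
      spread <- spec$coef_scale * (tg / 45) * (1 + 0.08 * (40 - tc) / 20)
      centre <- spec$t0 + (0.34 - 0.0015 * (tc - 40)) * tg
      w <- spread * w0
      TR[, ci] <- centre + X[, informative, drop = FALSE] %*% w
      centres[ci] <- centre; weights[[design$condition_id[ci]]] <- w
    }
    if (any(TR <= 1.2 * spec$t0)) {
      qstop("generated retention times approach t0; reduce coef_scale")
    }
    # observation noise on the ln k scale
    k_true <- (TR - spec$t0) / spec$t0
    eps <- matrix(rnorm(length(TR), 0, spec$sigma), nrow(TR))
    TR_obs <- spec$t0 * (1 + k_true * exp(eps))

    retention <- data.frame(
      compound_id = rep(ids, times = nrow(design)),
      condition_id = rep(design$condition_id, each = n),
      tr_min = as.vector(TR_obs), stringsAsFactors = FALSE)
    cfg <- qsrr_config(t0 = spec$t0, seed = spec$seed)
    study <- structure(list(
      compounds = data.frame(id = ids, smiles = NA_character_,
                             stringsAsFactors = FALSE),
      conditions = design, descriptors = X, retention = retention,
      config = cfg), class = "qsrr_study")

    true_surfaces <- lapply(ids, function(id) {
      fit_retention_surface(id, TR[id, ], design, spec$t0)
    })
    names(true_surfaces) <- ids
    truth <- list(informative = dnames[informative],
                  centres = centres, weights = weights,
                  surfaces = structure(list(surfaces = true_surfaces,
                                            source = "truth",
                                            t0 = spec$t0),
                                       class = "surface_set"),
                  tr_true = TR, sigma = spec$sigma)
    structure(list(study = study, truth = truth, spec = spec),
              class = "synthetic_study")
  })
}

#' Synthetic congeneric SMILES series
#'
#' A homologous N-alkyl phthalimide series for exercising the fingerprint
#' similarity summary. These structures are synthetic stand-ins and carry
#' no relation to any measured compound set.
#'
#' @param n series length.
#' @return character vector of SMILES, named cmp01..cmpNN.
#' @export
synthetic_smiles_series <- function(n = 24) {
  stopifnot(n >= 1, n <= 40)
  smi <- vapply(seq_len(n), function(i) {
    paste0("O=C1c2ccccc2C(=O)N1", strrep("C", i))
  }, character(1))
  names(smi) <- sprintf("cmp%02d", seq_len(n))
  smi
}

#' Gradient retention time under linear solvent strength
#'
#' Closed-form elution time for a linear gradient from organic fraction
#' `phi0` to `phi1` over `tG` minutes, with retention following
#' `k(phi) = k0 * exp(-S (phi - phi0))`. Used to generate physically
#' flavoured fixtures; it matches numerical integration of the migration
#' equation to < 1e-6 min.
#'
#' @param k0 retention factor at `phi0` (> 0).
#' @param S solvent-strength slope (natural-log units per unit phi).
#' @param phi0,phi1 start/end organic fraction (0..1).
#' @param tG gradient time (min, > 0).
#' @param t0 column dead time (min).
#' @param dwell gradient dwell time (min) before the ramp reaches the
#'   column.
#' @return retention time (min). Compounds still retained when the ramp
#'   ends elute isocratically at `phi1`, with a warning.
#' @export
lss_gradient_tr <- function(k0, S, phi0, phi1, tG, t0, dwell = 0) {
  stopifnot(k0 > 0, tG > 0, t0 > 0, dwell >= 0, phi1 >= phi0)
  b <- S * (phi1 - phi0) * t0 / tG
  if (abs(b) < 1e-12) {
    return(t0 * (1 + k0))          # isocratic limit (S = 0 or flat ramp)
  }
  r <- 1 - dwell / (t0 * k0)       # migration fraction left when ramp arrives
  if (r <= 0) {
    return(t0 + t0 * k0)           # elutes before the gradient reaches it
  }
  tau <- (t0 / b) * log1p(b * k0 * r)
  if (tau <= tG) {
    return(t0 + dwell + tau)
  }
  # still retained at gradient end: finish isocratically at phi1
  migrated <- expm1(b * tG / t0) / (b * k0)
  r2 <- r - migrated
  k1 <- k0 * exp(-S * (phi1 - phi0))
  warning("compound elutes after gradient end; computed isocratically at phi1")
  t0 + dwell + tG + r2 * t0 * k1
}
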