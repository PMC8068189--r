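test_that("retention time <-> ln k conversion round-trips and guards the boundary", {
  expect_equal(lnk_from_tr(1.5, t0 = 0.5), log(2))
  expect_equal(tr_from_lnk(lnk_from_tr(3.7, 0.55), 0.55), 3.7, tolerance = 1e-12)
  expect_equal(tr_from_lnk(0, t0 = 0.5), 1.0)     # k = 1 -> tR = 2 t0
  expect_error(lnk_from_tr(0.5, t0 = 0.5), "non-retained")
  expect_error(lnk_from_tr(0.4, t0 = 0.5), "non-retained")
  expect_error(lnk_from_tr(1, t0 = 0), "t0 must be > 0")
})

test_that("surface fit solves the 6 x 6 design exactly and recovers planted coefficients", {
  design <- default_design()
  t0 <- 0.55
  set.seed(14)
  for (rep in 1:5) {
    cf <- c(a0 = runif(1, 0, 2), a1 = rnorm(1, 0, 200), a2 = rnorm(1, 0, 1e4),
            b0 = runif(1, -0.05, 0.05), b1 = rnorm(1, 0, 5), b2 = rnorm(1, 0, 500))
    u <- 1 / design$temp_k
    lnk <- (cf[1] + cf[2] * u + cf[3] * u^2) +
      (cf[4] + cf[5] * u + cf[6] * u^2) * design$tg_min
    tr <- tr_from_lnk(lnk, t0)
    s <- fit_retention_surface("x", tr, design, t0)
    expect_equal(unname(s$coef), unname(cf), tolerance = 1e-6)
    # interpolation exactness at every design point
    res <- vapply(1:6, function(i) {
      predict_lnk_i <- log((predict_retention(s, design$tg_min[i],
                                              design$temperature_c[i]) - t0) / t0)
      abs(predict_lnk_i - lnk[i])
    }, numeric(1))
    expect_lt(max(res), 1e-9)
  }
})

test_that("constant ln k collapses to the intercept-only surface", {
  design <- default_design()
  tr <- rep(tr_from_lnk(0.8, 0.55), 6)
  s <- fit_retention_surface("flat", tr, design, 0.55)
  expect_equal(unname(s$coef["a0"]), 0.8, tolerance = 1e-9)
  expect_lt(max(abs(s$coef[-1])), 1e-9)
})

test_that("surface fit validates its design", {
  design <- default_design()
  tr <- seq(2, 7, length.out = 6)
  expect_error(fit_retention_surface("x", tr[1:5], design, 0.55),
               "5 retention values")
  tr_na <- tr; tr_na[3] <- NA
  expect_error(fit_retention_surface("x", tr_na, design, 0.55),
               "missing design cell")
  flat <- design; flat$tg_min <- 15
  expect_error(fit_retention_surface("x", tr, flat, 0.55), "span")
})

test_that("prediction interpolates design points and guards extrapolation", {
  sim <- tiny_study(n = 4, seed = 17)
  study <- sim$study
  ss <- fit_surfaces(study)
  M <- retention_matrix(study)
  s <- ss$surfaces[["cmp01"]]
  expect_equal(predict_retention(s, 15, 40), M["cmp01", "exp3"],
               tolerance = 1e-9)
  # off-design value equals an independent polynomial evaluation
  u <- 1 / (273.15 + 40)
  lnk <- sum(s$coef * c(1, u, u^2, 30, 30 * u, 30 * u^2))
  expect_equal(predict_retention(s, 30, 40), 0.55 * (1 + exp(lnk)),
               tolerance = 1e-12)
  expect_error(predict_retention(s, 12, 40), "allow_extrapolation")
  expect_gt(predict_retention(s, 12, 40, allow_extrapolation = TRUE), 0.55)
})

test_that("pairwise resolution is the symmetric scaled peak gap", {
  expect_equal(pairwise_resolution(5, 5, 0.1), 0)
  expect_equal(pairwise_resolution(5.125, 5, 0.1), 1.25)
  set.seed(3)
  a <- runif(10, 1, 20); b <- runif(10, 1, 20)
  expect_equal(pairwise_resolution(a, b, 0.1), pairwise_resolution(b, a, 0.1))
  expect_error(pairwise_resolution(1, 2, 0), "peak_width")
})

test_that("resolution map cells equal the per-cell critical-pair recomputation", {
  sim <- tiny_study(n = 5, seed = 23)
  study <- sim$study
  ss <- fit_surfaces(study)
  cfg <- qsrr_config(t0 = study$config$t0,
                     grid = list(tg = c(15, 45, 7), temp = c(20, 60, 5)))
  map <- build_resolution_map(ss, cfg, keep_pairs = TRUE)
  # direct oracle: recompute every cell from predicted retention times
  for (i in seq_along(map$tg)) {
    for (j in seq_along(map$temp_c)) {
      tr <- vapply(ss$surfaces, predict_retention, numeric(1),
                   tg = map$tg[i], temp_c = map$temp_c[j])
      pr <- combn(length(tr), 2)
      rs <- abs(tr[pr[1, ]] - tr[pr[2, ]]) / cfg$peak_width
      expect_equal(map$min_rs[i, j], min(rs))
      expect_equal(map$min_rs[i, j], min(map$pair_rs[, i, j]))
    }
  }
  expect_true(all(map$min_rs >= 0))
})

test_that("identical surfaces co-elute everywhere and a single surface errors", {
  sim <- tiny_study(n = 3, seed = 2)
  ss <- fit_surfaces(sim$study)
  ss$surfaces <- list(a = ss$surfaces[[1]], b = ss$surfaces[[1]])
  ss$surfaces$b$compound <- "b"
  cfg <- qsrr_config(grid = list(tg = c(15, 45, 5), temp = c(20, 60, 4)))
  map <- build_resolution_map(ss, cfg)
  expect_true(all(map$min_rs == 0))
  ss1 <- ss; ss1$surfaces <- ss$surfaces[1]
  expect_error(build_resolution_map(ss1, cfg), "single compound")
  # provenance tag carried onto the map for the two-source comparison
  ss2 <- fit_surfaces(sim$study, source = "qsrr")
  expect_equal(build_resolution_map(ss2, cfg)$source, "qsrr")
})

test_that("centre point prefers a robust plateau over an isolated spike", {
  # synthetic map: equal maxima, one on a plateau, one as a spike
  map <- structure(list(tg = seq(15, 45, length.out = 9),
                        temp_c = seq(20, 60, length.out = 9),
                        min_rs = matrix(0.5, 9, 9), pair_rs = NULL,
                        source = "experimental", peak_width = 0.1),
                   class = "resolution_map")
  map$min_rs[2:4, 2:4] <- 2.0          # wide plateau
  map$min_rs[7, 7] <- 2.0              # isolated spike
  ctr <- select_center_point(map, radius = 1)
  expect_equal(ctr$tg, map$tg[3])
  expect_equal(ctr$temp_c, map$temp_c[3])
  # brute-force neighbourhood-min oracle agrees
  rob <- matrix(NA, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    rob[i, j] <- min(map$min_rs[max(1, i - 1):min(9, i + 1),
                                max(1, j - 1):min(9, j + 1)])
  }
  expect_equal(ctr$robustness, max(rob))
  # single strict maximum on a flat map: that cell wins
  m2 <- map; m2$min_rs <- matrix(1, 9, 9); m2$min_rs[5, 6] <- 3
  ctr2 <- select_center_point(m2, radius = 1)
  expect_equal(c(ctr2$tg, ctr2$temp_c), c(m2$tg[5], m2$temp_c[6]))
  # identically zero map: warned null
  m3 <- map; m3$min_rs[] <- 0
  expect_warning(expect_null(select_center_point(m3)), "identically zero")
})
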