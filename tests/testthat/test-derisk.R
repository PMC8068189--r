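test_that("resolution coefficient reproduces its analytic values", {
  expect_equal(resolution_coefficient(c(1.25, 2, 50), rs_limit = 1.25), 1)
  expect_equal(resolution_coefficient(c(3, 0, 2), rs_limit = 1.25), 0)
  expect_equal(resolution_coefficient(0.625, rs_limit = 1.25), exp(-1))
  # two partially resolved pairs multiply
  expect_equal(resolution_coefficient(c(0.625, 0.625), 1.25), exp(-2))
  expect_warning(rc <- resolution_coefficient(numeric(0)), "singleton")
  expect_equal(rc, 1)
  expect_error(resolution_coefficient(-1), ">= 0")
})

test_that("RC is monotone in pairwise resolution and in mixture growth", {
  set.seed(19)
  for (i in 1:20) {
    rs <- runif(5, 0, 3)
    j <- sample(5, 1)
    rs_up <- rs; rs_up[j] <- rs[j] + runif(1, 0, 1)
    expect_gte(resolution_coefficient(rs_up, 1.25),
               resolution_coefficient(rs, 1.25))
    # adding a pair (a compound always adds pairs) never increases RC
    expect_lte(resolution_coefficient(c(rs, runif(1, 0, 3)), 1.25),
               resolution_coefficient(rs, 1.25))
  }
})

test_that("clique-based subset counts equal exhaustive enumeration", {
  cfg <- qsrr_config()
  # complete graph: every subset separable
  rt_wide <- seq(1, by = 0.5, length.out = 8)
  names(rt_wide) <- paste0("c", 1:8)
  out <- count_separable_subsets(rt_wide, 2:8, cfg)
  expect_equal(out$separable, choose(8, 2:8))
  # random mixed graphs, several seeds
  for (s in 1:6) {
    rt <- random_rt(8, seed = 100 + s, spread = 0.4)
    got <- count_separable_subsets(rt, 2:8, cfg)
    expect_equal(got$separable, unname(bf_count_separable(rt, 2:8, cfg)),
                 label = paste("seed", s))
    expect_equal(got$total, choose(8, 2:8))
  }
  expect_error(count_separable_subsets(rt_wide, sizes = 1:3, cfg), "sizes")
  expect_error(count_separable_subsets(rt_wide, sizes = 2:9, cfg), "sizes")
})

test_that("agreement curve: identical sources give 100%, fixtures match enumeration", {
  cfg <- qsrr_config()
  rt <- random_rt(6, seed = 55, spread = 0.5)
  cur <- model_agreement_curve(rt, rt, sizes = 2:6, config = cfg)
  expect_true(all(cur$pct[cur$exp_separated > 0] == 100))
  # disputed pair: model collapses one experimental gap
  rt_m <- rt
  rt_m["c02"] <- rt["c01"] + 0.05       # Rs = 0.5 under the model
  cur2 <- model_agreement_curve(rt, rt_m, sizes = 2:6, config = cfg)
  bf <- bf_both_separated(rt, rt_m, 2:6, cfg)
  expect_equal(cur2$both, unname(bf))
  expect_equal(cur2$exp_separated,
               unname(bf_count_separable(rt, 2:6, cfg)))
  # denominator conventions: "all" percentage never exceeds "exp-separated"
  cur3 <- model_agreement_curve(rt, rt_m, sizes = 2:6, denominator = "all",
                                config = cfg)
  expect_equal(attr(cur3, "denominator"), "all")
  both_def <- !is.na(cur2$pct) & !is.na(cur3$pct)
  expect_true(all(cur3$pct[both_def] <= cur2$pct[both_def] + 1e-12))
  expect_error(model_agreement_curve(rt, rt_m[-1], config = cfg), "mismatch")
})

test_that("hybrid replacement swaps exactly round(fraction * n) compounds, reproducibly", {
  rt_exp <- random_rt(24, seed = 7)
  rt_mod <- rt_exp + rnorm(24, 0, 0.2)
  names(rt_mod) <- names(rt_exp)
  h0 <- hybrid_replacement(rt_mod, rt_exp, fraction = 0)
  expect_identical(h0$rt, rt_mod)
  h <- hybrid_replacement(rt_mod, rt_exp, fraction = 0.2, seed = 3)
  expect_length(h$replaced, 5)                   # 20% of 24
  expect_equal(h$rt[h$replaced], rt_exp[h$replaced])
  keep <- setdiff(names(rt_mod), h$replaced)
  expect_equal(h$rt[keep], rt_mod[keep])
  h2 <- hybrid_replacement(rt_mod, rt_exp, fraction = 0.2, seed = 3)
  expect_identical(h$replaced, h2$replaced)
  # full replacement makes the agreement curve identically 100%
  h1 <- hybrid_replacement(rt_mod, rt_exp, fraction = 1)
  cur <- model_agreement_curve(rt_exp, h1$rt, sizes = 2:6)
  expect_true(all(cur$pct[cur$exp_separated > 0] == 100))
})

test_that("pairwise RC agreement bins match a direct per-pair computation", {
  cfg <- qsrr_config()
  # 4-compound fixture engineered for RC differences {0, ~0.05, ~0.3}
  rt_e <- c(a = 1.0, b = 1.2, c = 3.0, d = 9.0)
  rt_m <- c(a = 1.0, b = 1.17, c = 3.4, d = 9.0)
  out <- pairwise_rc_agreement(rt_e, rt_m, cfg)
  rc1 <- function(rs) exp(-(cfg$rs_limit / pmin(rs, cfg$rs_limit) - 1))
  pr <- combn(4, 2)
  rs_e <- abs(rt_e[pr[1, ]] - rt_e[pr[2, ]]) / cfg$peak_width
  rs_m <- abs(rt_m[pr[1, ]] - rt_m[pr[2, ]]) / cfg$peak_width
  keep <- rs_e <= cfg$rs_exclude
  d <- abs(rc1(rs_m[keep]) - rc1(rs_e[keep]))
  expect_equal(sum(out$histogram$count), sum(keep))
  expect_equal(out$n_excluded, sum(!keep))
  expect_equal(out$histogram$count[1], sum(d <= 0.1))
  expect_equal(sort(out$pairs$abs_diff), sort(unname(d)))
  # identical sources: everything in the first interval
  same <- pairwise_rc_agreement(rt_e, rt_e, cfg)
  expect_equal(same$histogram$pct[1], 100)
})

test_that("exclusion rule uses the experimental source and can empty the pair set", {
  cfg <- qsrr_config(rs_exclude = 2)
  rt_e <- c(a = 1, b = 10)        # Rs_exp = 90 > 2: excluded
  rt_m <- c(a = 1, b = 1.05)      # model would disagree wildly, but excluded
  expect_warning(out <- pairwise_rc_agreement(rt_e, rt_m, cfg), "no pairs")
  expect_equal(nrow(out$histogram), 0)
  expect_equal(out$n_excluded, 1)
})
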