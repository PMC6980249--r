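fake_results <- function(p_by_block, test = "SKATO",
                         block_size = 1e4) {
  n <- length(p_by_block)
  data.frame(block = seq_len(n),
             block_start = (seq_len(n) - 1) * block_size,
             block_end = seq_len(n) * block_size,
             test = test, p = p_by_block,
             n_variants = 5L,
             status = ifelse(is.na(p_by_block), "no_rare_variants", "ok"))
}

test_that("power and FPR are the significant fractions with binomial SE", {
  res <- fake_results(c(1e-10, 1e-10, 0.5, 0.9, NA))
  pw <- estimate_power(res, causal_blocks = 1:2,
                       alpha = c(SKATO = 2.5e-6))
  expect_equal(pw$power, 1)
  expect_equal(pw$fpr, 0)
  expect_equal(pw$n_null_trials, 2)   # the NA block is excluded

  # an untestable causal block counts as a miss
  pw2 <- estimate_power(fake_results(c(1e-10, NA, 0.5)), 1:2,
                        alpha = c(SKATO = 2.5e-6))
  expect_equal(pw2$power, 0.5)

  # m = 200 trials with 50 hits: power 0.25, SE = sqrt(.25*.75/200)
  hits <- rep(c(1e-9, 0.5), c(50, 150))
  res4 <- lapply(1:20, function(r)
    fake_results(hits[(10 * (r - 1) + 1):(10 * r)]))
  pw4 <- estimate_power(res4, causal_blocks = 1:10, alpha = 2.5e-6)
  expect_equal(pw4$power, 0.25)
  expect_equal(pw4$power_se, sqrt(0.25 * 0.75 / 200))
})

test_that("conditional power reproduces hand-computed strata", {
  # 10 causal blocks; primary significant on 1-6, conditioning on 1-4
  # and 7-8 (disjoint overlap pattern)
  prim <- fake_results(c(rep(1e-9, 6), rep(0.5, 4)))
  cond <- fake_results(c(rep(1e-10, 4), 0.5, 0.5, 1e-10, 1e-10, 0.5, 0.5),
                       test = "GWAS-min")
  cp <- conditional_power(prim, cond, causal_blocks = 1:10,
                          test = "SKATO", conditioning_test = "GWAS-min",
                          alpha = 2.5e-6, conditioning_alpha = 5e-8)
  expect_equal(cp$power[cp$stratum == "given_hit"], 4 / 6)
  expect_equal(cp$power[cp$stratum == "given_no_hit"], 2 / 4)
  expect_equal(cp$power[cp$stratum == "marginal"], 6 / 10)

  # conditioning significant everywhere: conditional equals marginal
  all_hit <- fake_results(rep(1e-10, 10), test = "GWAS-min")
  cp2 <- conditional_power(prim, all_hit, 1:10)
  expect_equal(cp2$power[cp2$stratum == "given_hit"],
               cp2$power[cp2$stratum == "marginal"])
  expect_true(cp2$empty[cp2$stratum == "given_no_hit"])
})

test_that("power-per-individual slopes follow two-point arithmetic", {
  expect_equal(
    power_vs_n_slope(data.frame(n = c(2500, 20000),
                                power = c(0.10, 0.45))),
    0.35 / 17500)
  expect_equal(
    power_vs_n_slope(data.frame(n = c(1000, 2000, 3000),
                                power = c(0.2, 0.2, 0.2))), 0)
  expect_error(power_vs_n_slope(data.frame(n = 5000, power = 0.3)),
               "two distinct")
})

test_that("discovery windows interpolate the half-maximum crossing", {
  # block midpoints fall at distances 0 (blocks 4-6, adjacent midpoints
  # are 5 kb from the causal boundary), 15 kb (blocks 3 and 7) and
  # 25 kb (blocks 2 and 8) from causal block 5; with fractions
  # 0.8 / 0.8 / 0.3 on those bins the 0.4 crossing interpolates to 18 kb
  causal <- 5
  reps <- lapply(1:40, function(r) {
    p <- rep(1, 9)
    p[4:6] <- ifelse(r / 40 <= 0.8, 1e-9, 1)
    p[c(3, 7)] <- ifelse(r / 40 <= 0.8, 1e-9, 1)
    p[c(2, 8)] <- ifelse(r / 40 <= 0.3, 1e-9, 1)
    fake_results(p)
  })
  wp <- discovery_window(reps, causal_blocks = causal, block_size = 1e4,
                         alpha = 2.5e-6, bin_width = 1e4)
  expect_equal(wp$fraction[wp$distance == 0], 0.8)
  expect_equal(attr(wp, "fwhm"),
               1e4 + (0.8 - 0.4) / (0.8 - 0.3) * 1e4, tolerance = 1e-8)
  wp2 <- discovery_window(reps, causal_blocks = causal,
                          block_size = 1e4, bin_width = 1e4,
                          double_sided = TRUE)
  expect_equal(attr(wp2, "fwhm"), 2 * attr(wp, "fwhm"),
               tolerance = 1e-8)

  # a flat-zero profile beyond the causal block: the 0-distance bin
  # pools the causal block (0.8) with its silent neighbours (blocks 4
  # and 6, midpoints 5 kb away), and the crossing lands mid-bin
  reps0 <- lapply(1:10, function(r) {
    p <- rep(1, 9)
    p[5] <- ifelse(r <= 8, 1e-9, 1)
    fake_results(p)
  })
  wp0 <- discovery_window(reps0, causal_blocks = 5, block_size = 1e4)
  f <- wp0$fraction
  expect_equal(f[wp0$distance == 0], 0.8 / 3, tolerance = 1e-12)
  expect_equal(attr(wp0, "fwhm"), 5000, tolerance = 1e-8)

  # zero power at distance zero: FWHM undefined
  repsz <- lapply(1:5, function(r) fake_results(rep(1, 9)))
  wpz <- discovery_window(repsz, causal_blocks = 5, block_size = 1e4)
  expect_true(is.na(attr(wpz, "fwhm")))
})

test_that("rank-sum comparison matches exact enumeration on toy tables", {
  out <- compare_tests(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(out$p, 1 / 20)
  same <- compare_tests(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_gt(same$p, 0.99)
  expect_error(compare_tests(numeric(0), 1), "empty")
})
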