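toy_pool <- function() {
  fitness_variant_table(
    s = c(0.02, 0.02, 0.02, 0.02, 0.05, 0.05, 0.1, 0.1, 0.2, 0.3,
          0.001, 0.002, 0.003, 0.004, 0.005, 0.006, 0.007, 0.008,
          0.009, 0.011),
    count = c(1L, 1L, 1L, 2L, 1L, 3L, 1L, 2L, 1L, 1L,
              5L, 10L, 20L, 50L, 100L, 200L, 1L, 2L, 3L, 4L),
    n_chrom = 600L)
}

test_that("effect sizes follow the rho/tau mapping exactly at rho = 1", {
  pool <- toy_pool()
  z1 <- effect_size(0.02, pool, architecture_params(1, 1), seed = 1)
  expect_equal(abs(z1), 0.02)
  z2 <- effect_size(0.04, pool, architecture_params(1, 0.5), seed = 2)
  expect_equal(abs(z2), 0.2)
  expect_error(architecture_params(1.2, 1), "rho")
})

test_that("the rho mixture decomposes as its Monte-Carlo oracle predicts", {
  pool <- toy_pool()
  s0 <- 0.02
  tau <- 1
  n <- 1e5
  z <- effect_size(rep(s0, n), pool, architecture_params(0.5, tau),
                   seed = 3)
  # |z| = s0 with prob 0.5 + 0.5 * P(pool draw == s0)
  p_pool <- mean(pool$s == s0)
  expected <- 0.5 + 0.5 * p_pool
  obs <- mean(abs(z) == s0^tau)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(obs - expected), 3 * se)
  # signs are balanced
  expect_lt(abs(mean(sign(z))), 3 / sqrt(n))
})

test_that("causal blocks are sampled and matched by allele count", {
  panel <- fx_panel()
  pool <- fx_pool_panel()
  params <- architecture_params(1, 1, n_causal_loci = 10)
  eff <- assign_effects(panel, pool, params, block_size = 1e4, seed = 11)
  blocks <- attr(eff, "causal_blocks")
  expect_equal(nrow(blocks), 10)
  expect_true(all(blocks$block >= 1 & blocks$block <= 30))
  # every causal variant lies inside a causal block
  expect_true(all((floor(eff$pos / 1e4) + 1) %in% blocks$block))
  # z = +/- s^tau for tau = 1
  expect_equal(abs(eff$z), eff$s, tolerance = 1e-12)
  # effect vector is zero outside causal sites
  z <- effect_vector(eff)
  expect_length(z, length(panel$pos))
  expect_true(all(z[-eff$site] == 0))
})

test_that("singleton matching draws only from pool variants of equal count", {
  pool <- toy_pool()
  for (i in 1:40) {
    s <- rvpower:::match_pool_s(1L, pool)
    expect_true(s %in% pool$s[pool$count == 1L])
  }
  # exact-match absent: nearest count within the window is used
  expect_true(rvpower:::match_pool_s(11L, pool) %in%
                pool$s[pool$count == 10L])
  expect_error(rvpower:::match_pool_s(400L, pool), "matching window")
})

test_that("null architectures produce pure-noise traits", {
  panel <- fx_panel()
  pool <- fx_pool_panel()
  eff <- assign_effects(panel, pool,
                        architecture_params(1, 1, n_causal_loci = 0),
                        block_size = 1e4, seed = 12)
  expect_equal(nrow(eff), 0)
  expect_error(simulate_trait(panel, eff, h2 = 0.5), "zero variance")
})

test_that("h2 = 1 removes environmental noise entirely", {
  trait <- fx_trait()
  eff <- attr(trait, "effects")
  t1 <- simulate_trait(fx_panel(), eff, h2 = 1)
  expect_true(all(t1$eps == 0))
  expect_equal(t1$Y, t1$G)
})

test_that("realised heritability is recovered in expectation", {
  panel <- fx_panel()
  eff <- attr(fx_trait(), "effects")
  h2 <- vapply(1:200, function(i) {
    tr <- simulate_trait(panel, eff, h2 = 0.2, seed = 1000 + i)
    var(tr$G) / var(tr$Y)
  }, 0)
  expect_gt(mean(h2), 0.18)
  expect_lt(mean(h2), 0.22)
})

test_that("dichotomization thresholds at the prevalence with index ties", {
  trait <- fx_trait()
  lab <- dichotomize(trait, 0.25)
  expect_equal(sum(lab), round(0.25 * nrow(trait)))
  expect_gte(min(trait$Y[lab == 1]), max(trait$Y[lab == 0]) - 1e-12)
  expect_error(dichotomize(trait, 1e-9), "empty")
  # all-tied phenotypes: the first round(P n) indices become cases
  tied <- trait
  tied$Y <- rep(1, nrow(tied))
  lab2 <- dichotomize(tied, 0.25)
  k <- round(0.25 * nrow(tied))
  expect_equal(which(lab2 == 1L), seq_len(k))
})

test_that("V_x normalisation, monotonicity and rho-linearity hold", {
  pool <- fx_pool_panel()
  sfs <- compute_sfs(fx_panel()$counts, fx_panel()$n_hap)
  params <- architecture_params(0.5, 0.5)
  v1 <- variance_explained(pool, sfs, params, x = 1)
  expect_equal(v1$ratio, 1)
  xs <- c(0.001, 0.01, 0.05, 0.2, 1)
  ratios <- vapply(xs, function(x)
    variance_explained(pool, sfs, params, x)$ratio, 0)
  expect_true(all(diff(ratios) >= 0))
  # linear-mixture identity to 1e-12 on a fixed pool
  vr <- function(rho) variance_explained(
    pool, sfs, architecture_params(rho, 0.5), 0.01)$ratio
  expect_equal(vr(0.37), 0.37 * vr(1) + 0.63 * vr(0), tolerance = 1e-12)
  expect_error(variance_explained(pool, sfs, params, x = 0), "x must")
  expect_error(
    variance_explained(fx_pool_raw(), sfs, params, 0.01),
    "chromosome counts differ")
})

test_that("V_0.01 increases with rho and with tau on a fixed pool", {
  pool <- fx_acc_pool()
  sfs <- fx_acc_sfs()
  v <- function(rho, tau) variance_explained(
    pool, sfs, architecture_params(rho, tau), 0.01)$ratio
  for (tau in c(0.5, 1)) {
    vals <- vapply(c(0.5, 0.8, 0.9, 1), v, 0, tau = tau)
    expect_true(all(diff(vals) > 0))
  }
  for (rho in c(0.5, 1)) {
    expect_gt(v(rho, 1), v(rho, 0.5))
  }
})

test_that("the cumulative variance curve agrees with point evaluations", {
  pool <- fx_pool_panel()
  sfs <- compute_sfs(fx_panel()$counts, fx_panel()$n_hap)
  params <- architecture_params(0.8, 0.5)
  curve <- cumulative_variance_curve(pool, sfs, params,
                                     x_grid = c(0.01, 0.1, 1))
  pts <- vapply(c(0.01, 0.1, 1), function(x)
    variance_explained(pool, sfs, params, x)$ratio, 0)
  expect_equal(curve$ratio, pts, tolerance = 1e-12)
})

test_that("effect assignments serialise to TSV", {
  eff <- attr(fx_trait(), "effects")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_effects_tsv(eff, path)
  back <- read.table(path, header = TRUE)
  expect_equal(nrow(back), nrow(eff))
  expect_named(back, c("pos", "count", "s", "z", "block_id"))
})
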