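test_that("the intercept-only null has its closed form and score identity", {
  y <- rep(c(1L, 0L), c(25, 75))
  null <- fit_null(y)
  expect_equal(null$mu, 0.25)
  expect_lt(abs(sum(null$resid)), 1e-10)
  expect_error(fit_null(rep(1L, 10)), "cases and controls")
  expect_error(fit_null(c(0, 2)), "binary")
})

test_that("mixture tail probabilities match chi-square closed forms", {
  expect_equal(as.numeric(davies_pvalue(1, qchisq(0.95, 1))), 0.05,
               tolerance = 1e-4)
  expect_equal(as.numeric(davies_pvalue(c(1, 1), qchisq(0.95, 2))), 0.05,
               tolerance = 1e-4)
  expect_equal(as.numeric(davies_pvalue(rep(1, 5), qchisq(0.99, 5))),
               0.01, tolerance = 1e-4)
  expect_equal(as.numeric(davies_pvalue(c(1, 1), 0)), 1)
  expect_error(davies_pvalue(c(0, 0), 1), "positive eigenvalue")
})

test_that("mixture tails match the exact exponential-mixture form", {
  # pairs of equal weights are scaled chi-square(2): an exponential
  # mixture with a closed-form survival function
  lam <- c(2, 2, 1, 1)
  exact <- function(q) 2 * exp(-q / 4) - exp(-q / 2)
  for (q in c(1, 5, 12, 25)) {
    expect_equal(as.numeric(davies_pvalue(lam, q)), exact(q),
                 tolerance = 1e-6)
  }
})

test_that("deep-tail p-values remain positive, ordered and finite", {
  lam <- c(1.3, 0.8, 0.5, 0.2)
  qs <- c(50, 80, 120, 200)
  ps <- vapply(qs, function(q) as.numeric(davies_pvalue(lam, q)), 0)
  expect_true(all(ps > 0))
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[4], 1e-15)
})

test_that("the single-variant scan equals Pearson chi-square on 2x2 tables", {
  # cases: 100 carriers / 100 non-carriers; controls: 50 / 150
  g <- rep(c(1, 0, 1, 0), c(100, 100, 50, 150))
  y <- rep(c(1, 0), c(200, 200))
  sc <- gwas_logistic(matrix(g, ncol = 1), y, maf_min = 0)
  chisq <- suppressWarnings(
    chisq.test(table(g, y), correct = FALSE)$p.value)
  expect_lt(abs(sc$p - chisq) / chisq, 0.1)
})

test_that("the single-variant scan is calibrated under the null", {
  set.seed(91)
  n <- 300
  g <- rbinom(n, 2, 0.2)
  n_rep <- 10000
  Y <- matrix(rbinom(n * n_rep, 1, 0.3), nrow = n)
  mu <- colMeans(Y)
  u <- as.vector(crossprod(Y, g)) - mu * n * mean(g)
  v <- mu * (1 - mu) * (sum(g^2) - sum(g)^2 / n)
  ps <- pchisq(u^2 / v, df = 1, lower.tail = FALSE)
  # same statistic as gwas_logistic, verified on one replicate
  expect_equal(ps[1],
               gwas_logistic(matrix(g, ncol = 1), Y[, 1], maf_min = 0)$p,
               tolerance = 1e-12)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("MAF filtering excludes low-frequency and constant variants", {
  set.seed(12)
  n <- 400
  G <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.002), rep(1, n))
  y <- rbinom(n, 1, 0.25)
  res <- suppressMessages(gwas_logistic(G, y, maf_min = 0.01))
  expect_equal(res$site, 1L)
})

test_that("single-variant SKAT reduces to the marginal score test", {
  set.seed(13)
  n <- 500
  y <- rbinom(n, 1, 0.3)
  g <- matrix(rbinom(n, 2, 0.08), ncol = 1)
  p_skat <- as.numeric(skat(g, fit_null(y), weights = 2.7))
  p_score <- gwas_logistic(g, y, maf_min = 0)$p
  expect_equal(p_skat, p_score, tolerance = 1e-6)
})

test_that("SKAT agrees with its permutation oracle near p = 0.05", {
  # construct a block whose analytic p lands in the moderate range the
  # oracle comparison targets
  set.seed(37)
  n <- 200
  w <- rep(1, 5)
  repeat {
    y <- rep(c(1L, 0L), each = 100)
    G <- matrix(rbinom(n * 5, 2, 0.04), ncol = 5)
    carriers <- which(rowSums(G) > 0)
    y[carriers[seq_len(min(8, length(carriers)))]] <- 1L
    null <- fit_null(y)
    p_dav <- as.numeric(skat(G, null, w))
    if (p_dav > 0.01 && p_dav < 0.2) break
  }
  r <- null$resid
  q0 <- sum((as.vector(crossprod(G, r)) * w)^2)
  set.seed(38)
  qp <- vapply(1:1e5, function(i) {
    rp <- r[sample.int(n)]
    sum((as.vector(crossprod(G, rp)) * w)^2)
  }, 0)
  p_perm <- mean(qp >= q0 - 1e-12)
  expect_gt(p_dav, 0.005)   # the oracle comparison targets moderate p
  expect_lt(abs(p_dav - p_perm), 0.01)
})

test_that("SKAT-O degenerates exactly to SKAT and to the burden test", {
  set.seed(14)
  n <- 400
  y <- rbinom(n, 1, 0.25)
  null <- fit_null(y)
  G <- matrix(rbinom(n * 6, 2, 0.03), ncol = 6)
  w <- beta_maf_weights(pmin(colMeans(G) / 2, 1 - colMeans(G) / 2))
  expect_equal(skat_o(G, null, w, rho_grid = 0),
               as.numeric(skat(G, null, w)), tolerance = 1e-12)
  # weighted burden score test, computed directly
  b <- rowSums(sweep(G, 2, w, "*"))
  u_b <- sum(b * null$resid)
  v_b <- null$v * (sum(b^2) - sum(b)^2 / length(b))
  p_burden <- pchisq(u_b^2 / v_b, df = 1, lower.tail = FALSE)
  expect_equal(skat_o(G, null, w, rho_grid = 1), p_burden,
               tolerance = 1e-12)
})

test_that("SKAT-O stays within its min-p bounds and matches a permutation oracle", {
  set.seed(15)
  n <- 150
  y <- rep(c(1L, 0L), c(50, 100))
  null <- fit_null(y)
  G <- matrix(rbinom(n * 4, 2, 0.06), ncol = 4)
  w <- rep(1, 4)
  grid <- c(0, 0.25, 1)
  p_each <- c(skat_o(G, null, w, rho_grid = 0),
              skat_o(G, null, w, rho_grid = 0.25),
              skat_o(G, null, w, rho_grid = 1))
  p_o <- skat_o(G, null, w, rho_grid = grid)
  expect_gte(p_o, min(p_each) - 1e-12)
  expect_lte(p_o, length(grid) * min(p_each) + 1e-12)

  # permutation oracle for the min-p statistic
  stat_minp <- function(yy) {
    nn <- fit_null(yy)
    min(vapply(grid, function(r)
      skat_o(G, nn, w, rho_grid = r), 0))
  }
  t_obs <- min(p_each)
  set.seed(16)
  tp <- vapply(1:800, function(i) stat_minp(sample(y)), 0)
  p_perm <- mean(tp <= t_obs + 1e-12)
  expect_lt(abs(p_o - p_perm), 0.05)
})

test_that("KBAC handles degenerate inputs and matches exhaustive enumeration", {
  expect_equal(as.numeric(kbac(matrix(0, 10, 2), rep(0:1, 5), seed = 1)),
               1)
  # n = 10 toy: compare the adaptive Monte-Carlo p with the exact p
  # over all C(10, 5) case assignments
  G <- matrix(c(1, 0, 0, 1, 0, 2, 0, 0, 0, 0,
                0, 1, 0, 0, 0, 0, 0, 0, 1, 0), ncol = 2)
  y <- c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L)
  stat <- function(yy) {
    carriers <- rowSums(G) > 0
    key <- apply(G, 1, paste, collapse = ",")
    pats <- split(seq_len(10)[carriers], key[carriers])
    n_a <- sum(yy)
    n_u <- 10 - n_a
    sum(vapply(pats, function(idx) {
      a <- sum(yy[idx])
      phyper(a, n_a, n_u, length(idx)) *
        (a / n_a - (length(idx) - a) / n_u)
    }, 0))
  }
  obs <- stat(y)
  combos <- combn(10, sum(y))
  exact <- mean(apply(combos, 2, function(idx) {
    yy <- integer(10)
    yy[idx] <- 1L
    stat(yy) >= obs - 1e-12
  }))
  p_mc <- as.numeric(kbac(G, y, max_perm = 2e5, alpha_stop = 0, seed = 7))
  expect_lt(abs(p_mc - exact), 3 * sqrt(exact * (1 - exact) / 2e5) + 1e-3)
})

test_that("KBAC's adaptive permutation stops early on clear nulls", {
  set.seed(17)
  G <- matrix(rbinom(2000 * 8, 2, 0.003), ncol = 8)
  y <- rbinom(2000, 1, 0.25)
  p <- kbac(G, y, max_perm = 1e6, alpha_stop = 0.05, seed = 5)
  expect_lt(attr(p, "n_perm"), 1e5)
})

test_that("block runs tile the region, filter rare variants and are reproducible", {
  panel <- fx_panel()
  trait <- fx_trait()
  coh <- sample_cohort(trait, cohort_spec("extremes", 150, seed = 31))
  res <- run_blocks(panel, coh, tests = c("SKAT", "SKATO", "GWAS"),
                    block_size = 1e4, seed = 77)
  n_blocks <- floor(panel$region_length / 1e4)
  expect_setequal(unique(res$block), seq_len(n_blocks))
  expect_setequal(unique(res$test), c("SKAT", "SKATO", "GWAS-min"))
  expect_true(all(res$p[res$status == "ok"] > 0 &
                    res$p[res$status == "ok"] <= 1))
  expect_true(all(is.na(res$p[res$status == "no_rare_variants"])))
  expect_true(all(res$block_end - res$block_start == 1e4))
  res2 <- run_blocks(panel, coh, tests = c("SKAT", "SKATO", "GWAS"),
                     block_size = 1e4, seed = 77)
  expect_identical(res$p, res2$p)
  empty <- run_blocks(panel, coh, tests = character(0))
  expect_equal(nrow(empty), 0)
})
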