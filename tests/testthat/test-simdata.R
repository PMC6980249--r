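test_that("neutral panels respect their structural invariants", {
  panel <- fx_panel()
  expect_s3_class(panel, "haplotype_panel")
  expect_equal(panel$n_hap, 600L)
  expect_true(all(diff(panel$pos) > 0))
  expect_identical(panel$counts, as.integer(colSums(panel$H)))
  expect_true(all(panel$counts > 0 & panel$counts < panel$n_hap))
})

test_that("panels are byte-identical under identical seeds and differ otherwise", {
  m <- tennessen_model()
  a <- simulate_neutral_panel(m, 5e4, 1e-8, n_samples = 20, seed = 7)
  b <- simulate_neutral_panel(m, 5e4, 1e-8, n_samples = 20, seed = 7)
  c <- simulate_neutral_panel(m, 5e4, 1e-8, n_samples = 20, seed = 8)
  expect_identical(a$H, b$H)
  expect_identical(a$pos, b$pos)
  expect_false(identical(a$H, c$H) && identical(a$pos, c$pos))
})

test_that("zero mutation rate yields a variant-free panel", {
  p <- simulate_neutral_panel(constant_model(1000), 1e4, 0,
                              n_samples = 2, population = "POP",
                              seed = 1)
  expect_length(p$pos, 0)
})

test_that("segregating sites match the Watterson expectation at constant size", {
  n_ind <- 25
  N <- 5000
  L <- 5e4
  mu <- 1e-8
  reps <- simulate_neutral_counts(constant_model(N), L, mu,
                                  n_samples = n_ind, population = "POP",
                                  seed = 42, n_reps = 80)
  s_obs <- vapply(reps, length, 0L)
  theta <- 4 * N * mu * L
  a_n <- sum(1 / seq_len(2 * n_ind - 1))
  b_n <- sum(1 / seq_len(2 * n_ind - 1)^2)
  expected <- theta * a_n
  se_mean <- sqrt((theta * a_n + theta^2 * b_n) / length(s_obs))
  expect_lt(abs(mean(s_obs) - expected), 3 * se_mean)
})

test_that("recent growth inflates the singleton fraction over constant size", {
  growth <- simulate_neutral_counts(tennessen_model(), 1e5, 1e-8,
                                    n_samples = 100, seed = 21,
                                    n_reps = 20)
  const <- simulate_neutral_counts(constant_model(10000), 1e5, 1e-8,
                                   n_samples = 100, population = "POP",
                                   seed = 22, n_reps = 20)
  sf <- function(reps) {
    cnt <- unlist(reps)
    mean(cnt == 1)
  }
  expect_gt(sf(growth), sf(const))
})

test_that("the constant-size SFS is proportional to 1/i", {
  reps <- simulate_neutral_counts(constant_model(5000), 2e5, 1e-8,
                                  n_samples = 10, population = "POP",
                                  seed = 33, n_reps = 40)
  cnt <- unlist(reps)
  ratio <- sum(cnt == 1) / sum(cnt == 2)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
  sfs <- compute_sfs(cnt, 20)
  expect_equal(sum(sfs$prop), 1, tolerance = 1e-12)
})

test_that("compute_sfs bins direct counts correctly and validates input", {
  sfs <- compute_sfs(c(1L, 1L, 2L), 10, bins = c(0.5, 1.5, 2.5))
  expect_equal(sfs$prop, c(2 / 3, 1 / 3))
  expect_equal(sfs$y_mean, c(0.1, 0.2))
  expect_error(compute_sfs(integer(0), 10), "empty")
  expect_error(compute_sfs(c(0L, 1L), 10), "strictly")
})

test_that("binomial projection has the right mean, identity and pruning", {
  tab <- fitness_variant_table(rep(0.01, 10000), rep(50L, 10000), 100000L)
  pr <- project_counts(tab, 10000, drop_monomorphic = FALSE, seed = 5)
  expected <- 5
  se <- sqrt(expected * (1 - 50 / 100000) / 10000)
  expect_lt(abs(mean(pr$count) - expected), 3 * se)

  expect_identical(project_counts(tab, 100000), tab)

  singles <- fitness_variant_table(rep(0.01, 5000), rep(1L, 5000), 100000L)
  kept <- project_counts(singles, 100, seed = 6)
  expect_lt(nrow(kept) / 5000, 0.005)   # ~99.9% projected to zero
  expect_error(project_counts(tab, 0), "positive")
  expect_error(project_counts(tab, 200000), "exceeds")
})

test_that("invalid demography and maps are rejected", {
  expect_error(constant_model(-5), "positive")
  expect_error(demographic_model(
    data.frame(name = "A", size = 100, growth = 0),
    migrations = data.frame(time = 0, rate = 1.5, from = "A", to = "A")),
    "migration")
  expect_error(recomb_map(c(0, 10, 5), c(1, 1, 1) * 1e-8, 100), "tile|increase")
  expect_error(recomb_map(0, -1e-8, 100), ">= 0")
})

test_that("fitness tables show purifying selection and record metadata", {
  pool <- fx_pool_raw()
  expect_true(all(pool$s >= 0))
  expect_true(all(pool$count > 0 & pool$count < pool$n_chrom))
  ct <- suppressWarnings(
    cor.test(pool$s, pool$count, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  expect_equal(attr(pool, "meta")$rescale, 100)

  # monotone decreasing mean frequency across |s| quartiles
  qs <- cut(pool$s, quantile(pool$s, 0:4 / 4), include.lowest = TRUE)
  mf <- tapply(pool$count, qs, mean)
  expect_true(all(diff(mf) < 0))
})

test_that("a neutral DFE reproduces the neutral frequency spectrum", {
  neutral_dfe <- simulate_fitness_table(
    tennessen_model(), dfe_params(mean = 0), n_loci = 15,
    locus_length = 5e4, n_individuals = 5000, rescale = 100, seed = 9)
  expect_true(all(neutral_dfe$s == 0))
  sel <- fx_pool_raw()
  # neutral spectrum is less singleton-skewed than the selected one
  expect_lt(mean(neutral_dfe$count == 1), mean(sel$count == 1))
})

test_that("fitness tables refuse too-severe rescaling", {
  expect_error(
    simulate_fitness_table(constant_model(2000), dfe_params(),
                           n_loci = 1, locus_length = 1e4,
                           n_individuals = 100, rescale = 100,
                           population = "POP", seed = 1),
    "below 50")
})

test_that("fitness table TSV round-trips", {
  pool <- head(fx_pool_raw(), 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fitness_table(pool, path)
  back <- read_fitness_table(path)
  expect_equal(back$s, pool$s)
  expect_equal(back$count, pool$count)
})

test_that("VCF export/import round-trips a panel", {
  skip_if_not_installed("vcfR")
  panel <- simulate_neutral_panel(tennessen_model(), 3e4, 1e-8,
                                  n_samples = 15, seed = 55)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(panel, path)
  back <- read_panel_vcf(path)
  expect_identical(back$H, panel$H)
  expect_equal(back$pos, panel$pos)
  expect_equal(back$region_length, panel$region_length)
})
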