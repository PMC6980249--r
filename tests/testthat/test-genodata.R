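test_that("the bundled manifest is valid and matches the region geometry", {
  man <- build_manifest_fixture()
  expect_equal(sum(man$proportions), 1, tolerance = 1e-8)
  expect_equal(round(5e6 / man$mean_spacing_bp), 2500)
  expect_error(array_manifest(c(0, 0.5), 1, -10), "positive")
  expect_error(array_manifest(c(0, 0.3, 0.5), c(0.7, 0.7), 1000),
               "sum to 1")
})

test_that("array downsampling matches the manifest spectrum and spacing", {
  panel <- fx_panel()
  man <- build_manifest_fixture()
  typed <- suppressWarnings(downsample_to_array(panel, man, seed = 5))
  n_target <- round(panel$region_length / man$mean_spacing_bp)
  expect_lt(abs(length(typed$typed_idx) - n_target) / n_target, 0.1)
  sp <- mean(diff(typed$pos))
  expect_lt(abs(sp - man$mean_spacing_bp) / man$mean_spacing_bp, 0.2)
  # arrays under-ascertain rare variants
  expect_lt(mean(panel$counts[typed$typed_idx] == 1),
            mean(panel$counts == 1) / 2)
  # chi-square distance between typed AFS and manifest proportions, at
  # a spacing the panel's site pool can fully populate
  man3k <- array_manifest(man$maf_edges, man$proportions, 3000)
  typed3k <- suppressWarnings(downsample_to_array(panel, man3k, seed = 5))
  maf <- pmin(panel$counts, panel$n_hap - panel$counts) / panel$n_hap
  tmaf <- maf[typed3k$typed_idx]
  obs <- tabulate(findInterval(tmaf, man$maf_edges,
                               rightmost.closed = TRUE),
                  nbins = length(man$proportions)) /
    length(typed3k$typed_idx)
  chi2 <- sum((obs - man$proportions)^2 /
                pmax(man$proportions, 1e-3))
  expect_lt(chi2, 0.2)
  # determinism
  typed2 <- suppressWarnings(downsample_to_array(panel, man, seed = 5))
  expect_identical(typed$typed_idx, typed2$typed_idx)
})

test_that("a degenerate manifest accepts any subset at the target count", {
  panel <- fx_panel()
  man <- array_manifest(c(0, 0.5), 1, mean_spacing_bp = 1500)
  typed <- downsample_to_array(panel, man, seed = 2)
  expect_equal(length(typed$typed_idx),
               round(panel$region_length / 1500), tolerance = 0.1)
})

test_that("typed sites pass through as the observed genotypes exactly", {
  s <- imputation_setup()
  truth <- diploid_genotypes(s$panel, s$coh)
  expect_equal(s$imp$dosage[, s$typed$typed_idx],
               truth[, s$typed$typed_idx, drop = FALSE])
  expect_true(all(s$imp$dosage >= 0 & s$imp$dosage <= 2))
})

test_that("imputation r2 declines from common to rare variants", {
  s <- imputation_setup()
  r2 <- imputation_r2(s$imp, s$panel, s$coh)
  bins <- cut(r2$maf[!r2$typed], c(0, 0.01, 0.05, 0.2, 0.5))
  mr2 <- tapply(r2$r2[!r2$typed], bins, mean, na.rm = TRUE)
  expect_true(all(diff(mr2) > 0))
})

test_that("r2 is exact for perfect dosages and missing for constants", {
  s <- imputation_setup()
  truth <- diploid_genotypes(s$panel, s$coh)
  perfect <- s$imp
  perfect$dosage <- truth
  r2 <- imputation_r2(perfect, s$panel, s$coh)
  poly <- apply(truth, 2, var) > 0
  expect_true(all(abs(r2$r2[poly] - 1) < 1e-12))
  const <- s$imp
  const$dosage[] <- 1
  r2c <- imputation_r2(const, s$panel, s$coh)
  expect_true(all(is.na(r2c$r2)))
  bad <- s$imp
  bad$dosage <- bad$dosage[, 1:3]
  expect_error(imputation_r2(bad, s$panel, s$coh), "dimensions differ")
})

test_that("larger reference panels impute rare variants at least as well", {
  s <- imputation_setup()
  small_ref <- subset_panel(s$panel, 61:140, drop_monomorphic = FALSE)
  imp_small <- impute(s$typed, small_ref, n_states = 120, seed = 3)
  r2_big <- imputation_r2(s$imp, s$panel, s$coh)
  r2_small <- imputation_r2(imp_small, s$panel, s$coh)
  rare <- !r2_big$typed & r2_big$maf > 0 & r2_big$maf < 0.05
  expect_gte(mean(r2_big$r2[rare], na.rm = TRUE),
             mean(r2_small$r2[rare], na.rm = TRUE))
})

test_that("imputation requires a usable reference panel", {
  s <- imputation_setup()
  empty <- s$reference
  empty$H <- NULL
  expect_error(impute(s$typed, empty), "empty reference")
  shifted <- s$reference
  shifted$pos <- shifted$pos + 1
  expect_error(impute(s$typed, shifted), "same site")
})

test_that("dosage VCF export writes well-formed records", {
  s <- imputation_setup()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_dosage_vcf(s$imp, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, length(s$imp$pos))
  first <- strsplit(body[1], "\t")[[1]]
  expect_equal(first[9], "DS")
  expect_length(first, 9 + nrow(s$imp$dosage))
})
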