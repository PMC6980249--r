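#' Power and false-positive rate from replicated block tests
#'
#' Power is the fraction of causal-block trials (block x replicate) with a
#' p-value below `alpha`; the false-positive rate is the same fraction
#' over non-causal blocks.  Untestable causal blocks (no qualifying
#' variants) count as misses — a test cannot discover a block it cannot
#' run on — while untestable non-causal blocks are excluded from the FPR
#' denominator.
#'
#' @param results A [run_blocks()] result, or a list of them (one per
#'   replicate).
#' @param causal_blocks Integer vector of causal block indices.
#' @param alpha Significance threshold per test; a named vector may give
#'   each test its own threshold (default 2.5e-6 for RVATs, 5e-8 for
#'   `GWAS-min`).
#' @return data.frame of class `power_summary` with one row per test:
#'   `power`, `fpr`, binomial standard errors and trial counts.
#' @export
estimate_power <- function(results, causal_blocks,
                           alpha = c(SKAT = 2.5e-6, SKATO = 2.5e-6,
                                     KBAC = 2.5e-6, `GWAS-min` = 5e-8)) {
  if (is.data.frame(results)) results <- list(results)
  tab <- do.call(rbind, results)
  tests <- unique(tab$test)
  out <- lapply(tests, function(tn) {
    a <- if (is.null(names(alpha))) {
      unname(alpha[1])
    } else if (tn %in% names(alpha)) {
      alpha[[tn]]
    } else {
      2.5e-6
    }
    rows <- tab[tab$test == tn, ]
    causal <- rows$block %in% causal_blocks
    hit <- !is.na(rows$p) & rows$p < a
    m_c <- sum(causal)
    power <- if (m_c > 0) sum(hit[causal]) / m_c else NA_real_
    nc <- !causal & rows$status == "ok"
    m_f <- sum(nc)
    fpr <- if (m_f > 0) sum(hit[nc]) / m_f else NA_real_
    data.frame(test = tn, alpha = a,
               power = power,
               power_se = if (m_c > 0) sqrt(power * (1 - power) / m_c)
                 else NA_real_,
               n_causal_trials = m_c,
               fpr = fpr,
               fpr_se = if (m_f > 0) sqrt(fpr * (1 - fpr) / m_f)
                 else NA_real_,
               n_null_trials = m_f)
  })
  structure(do.call(rbind, out),
            class = c("power_summary", "data.frame"))
}

#' Power conditional on another test's result
#'
#' Stratifies causal-block trials by whether a conditioning test (for
#' example a single-variant scan, or the same test run on imputed data)
#' was significant on the same block and replicate, and reports the power
#' of the primary test within each stratum.
#'
#' @param rvat_results List of [run_blocks()] results (primary test), one
#'   per replicate.
#' @param conditioning_results List of results over identical blocks and
#'   replicates (conditioning test).
#' @param causal_blocks Integer vector of causal block indices.
#' @param test,conditioning_test Test names to extract from each set.
#' @param alpha,conditioning_alpha Significance thresholds.
#' @return data.frame with rows `given_hit`, `given_no_hit`, `marginal`:
#'   power, binomial SE, trial count and an `empty` flag for strata with
#'   no trials.
#' @export
conditional_power <- function(rvat_results, conditioning_results,
                              causal_blocks, test = "SKATO",
                              conditioning_test = "GWAS-min",
                              alpha = 2.5e-6,
                              conditioning_alpha = 5e-8) {
  if (is.data.frame(rvat_results)) rvat_results <- list(rvat_results)
  if (is.data.frame(conditioning_results)) {
    conditioning_results <- list(conditioning_results)
  }
  stopifnot(length(rvat_results) == length(conditioning_results))
  hits_p <- logical(0)
  hits_c <- logical(0)
  for (r in seq_along(rvat_results)) {
    a <- rvat_results[[r]]
    b <- conditioning_results[[r]]
    a <- a[a$test == test & a$block %in% causal_blocks, ]
    b <- b[b$test == conditioning_test & b$block %in% causal_blocks, ]
    a <- a[order(a$block), ]
    b <- b[order(b$block), ]
    if (!identical(a$block, b$block)) {
      stop("result sets cover different blocks", call. = FALSE)
    }
    hits_p <- c(hits_p, !is.na(a$p) & a$p < alpha)
    hits_c <- c(hits_c, !is.na(b$p) & b$p < conditioning_alpha)
  }
  stratum <- function(sel, label) {
    m <- sum(sel)
    p <- if (m > 0) mean(hits_p[sel]) else NA_real_
    data.frame(stratum = label, power = p,
               se = if (m > 0) sqrt(p * (1 - p) / m) else NA_real_,
               n_trials = m, empty = m == 0)
  }
  rbind(stratum(hits_c, "given_hit"),
        stratum(!hits_c, "given_no_hit"),
        stratum(rep(TRUE, length(hits_p)), "marginal"))
}

#' Power gain per individual across sample sizes
#'
#' Ordinary least-squares slope of power on cohort size.
#'
#' @param power_by_n data.frame with columns `n` and `power` (one row per
#'   evaluated sample size, already averaged over replicates).
#' @return The per-individual slope.
#' @export
power_vs_n_slope <- function(power_by_n) {
  if (length(unique(power_by_n$n)) < 2L) {
    stop("at least two distinct sample sizes are required", call. = FALSE)
  }
  unname(coef(lm(power ~ n, data = power_by_n))[2])
}

#' Discovery-window profile around causal loci
#'
#' Bins blocks by the distance from their midpoint to the nearest causal
#' block (0 inside causal blocks), computes the fraction of significant
#' trials per distance bin, and reports the full-width-half-maximum
#' (FWHM) distance: where the linearly interpolated profile first falls
#' below half of its value at distance 0.
#'
#' @param results List of [run_blocks()] results, one per replicate.
#' @param causal_blocks Integer vector of causal block indices.
#' @param block_size Block size in bp (must match the runs).
#' @param test Test name to profile.
#' @param alpha Significance threshold.
#' @param bin_width Distance bin width in bp.
#' @param double_sided Report twice the one-sided crossing distance
#'   (`FALSE` by default: the crossing distance itself).
#' @return An object of class `window_profile`: data.frame of distance
#'   bins with `fraction` and `se`, plus attribute `fwhm` (bp, `NA` if
#'   power at distance zero is 0).
#' @export
discovery_window <- function(results, causal_blocks, block_size = 1e4,
                             test = "SKATO", alpha = 2.5e-6,
                             bin_width = 1e4, double_sided = FALSE) {
  if (is.data.frame(results)) results <- list(results)
  tab <- do.call(rbind, results)
  tab <- tab[tab$test == test, ]
  if (!nrow(tab)) stop("no results for test ", test, call. = FALSE)
  mid <- (tab$block - 0.5) * block_size
  cb_start <- (causal_blocks - 1) * block_size
  cb_end <- causal_blocks * block_size
  dist <- vapply(mid, function(x) {
    inside <- any(x >= cb_start & x < cb_end)
    if (inside) return(0)
    min(pmax(cb_start - x, x - cb_end))
  }, 0)
  bin <- floor(dist / bin_width)
  hit <- !is.na(tab$p) & tab$p < alpha
  agg <- aggregate(hit, list(bin = bin), function(z)
    c(frac = mean(z), n = length(z)))
  prof <- data.frame(distance = agg$bin * bin_width,
                     fraction = agg$x[, "frac"],
                     n_trials = agg$x[, "n"])
  prof$se <- sqrt(prof$fraction * (1 - prof$fraction) / prof$n_trials)
  prof <- prof[order(prof$distance), ]
  rownames(prof) <- NULL

  f0 <- prof$fraction[prof$distance == 0]
  fwhm <- NA_real_
  if (length(f0) && !is.na(f0) && f0 > 0) {
    half <- f0 / 2
    d <- prof$distance
    f <- prof$fraction
    for (i in seq_len(nrow(prof) - 1L)) {
      if (f[i] >= half && f[i + 1L] < half) {
        fwhm <- d[i] + (f[i] - half) / (f[i] - f[i + 1L]) *
          (d[i + 1L] - d[i])
        break
      }
    }
    if (is.na(fwhm) && f[1] < half) fwhm <- 0
    if (!is.na(fwhm) && double_sided) fwhm <- 2 * fwhm
  }
  structure(prof, class = c("window_profile", "data.frame"), fwhm = fwhm)
}

#' Compare per-architecture power between two tests
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on paired tables of
#' per-architecture power values; exact null distribution for small
#' samples without ties, normal approximation otherwise.
#'
#' @param power_a,power_b Numeric vectors of power values (one per
#'   architecture) for the two tests.
#' @param alternative Passed to [wilcox.test()].
#' @return List with the U `statistic` and `p` value.
#' @export
compare_tests <- function(power_a, power_b, alternative = "two.sided") {
  if (!length(power_a) || !length(power_b)) {
    stop("empty power tables", call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(power_a, power_b,
                                     alternative = alternative))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
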