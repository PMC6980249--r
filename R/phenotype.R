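#' Genetic architecture parameters (rho/tau model)
#'
#' Parameters of the evolutionary genetic architecture coupling fitness
#' effects to phenotypic effect sizes: with probability `rho` a causal
#' variant's effect magnitude is its own selection coefficient raised to
#' `tau` (`|z| = s^tau`), otherwise the selection coefficient of a random
#' variant from the functional pool is used; the sign is +1 or -1 with
#' equal probability.  `rho` measures pleiotropy/modularity, `tau` the
#' strength of the selection-to-effect coupling.
#'
#' @param rho Probability the effect derives from the variant's own
#'   selection coefficient, in `[0, 1]`.
#' @param tau Positive exponent coupling effect size to selection.
#' @param h2 Target trait heritability, in `(0, 1]`.
#' @param n_causal_loci Number of causal blocks.
#' @param prevalence Fraction of the population defined as cases.
#' @return An object of class `architecture_params`.
#' @export
architecture_params <- function(rho, tau, h2 = 0.8, n_causal_loci = 100,
                                prevalence = 0.25) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  structure(list(rho = rho, tau = tau, h2 = h2,
                 n_causal_loci = as.integer(n_causal_loci),
                 prevalence = prevalence),
            class = "architecture_params")
}

#' Map selection coefficients to signed phenotypic effect sizes
#'
#' Draws effect sizes under the rho/tau model: `|z| = s^tau` with
#' probability `rho`, otherwise `|z| = s_r^tau` with `s_r` sampled
#' uniformly from the functional pool; the sign is +1/-1 with equal
#' probability.  Vectorised over `s`.
#'
#' @param s Selection coefficient magnitudes (>= 0).
#' @param pool A [fitness_variant_table()] supplying random `s_r` draws.
#' @param params An [architecture_params()].
#' @param seed Optional integer seed.
#' @return Numeric vector of signed effect sizes.
#' @export
effect_size <- function(s, pool, params, seed = NULL) {
  stopifnot(all(s >= 0), nrow(pool) > 0)
  with_seed(seed, {
    n <- length(s)
    own <- runif(n) < params$rho
    mag <- ifelse(own, s,
                  pool$s[sample.int(nrow(pool), n, replace = TRUE)])
    delta <- sign(runif(n) - 0.5)
    delta[delta == 0] <- 1
    delta * mag^params$tau
  })
}

#' Assign effect sizes to causal blocks by frequency matching
#'
#' Chooses `n_causal_loci` blocks of `block_size` bp uniformly without
#' replacement among the region's non-overlapping blocks, and gives every
#' panel variant inside a causal block an effect size via a functional
#' variant with the same derived allele count (matching widened to the
#' nearest count within `+/- max(1, 5%)` when no exact match exists).
#' Variants outside causal blocks have effect 0.
#'
#' @param panel A [haplotype_panel()].
#' @param pool A [fitness_variant_table()] projected to the panel's
#'   chromosome count (see [project_counts()]), so count matching is well
#'   defined.
#' @param params An [architecture_params()].
#' @param block_size Causal block size in bp.
#' @param seed Integer seed.
#' @return An object of class `effect_assignment`: a data frame of causal
#'   variant records (`site`, `pos`, `count`, `s`, `z`, `block`) with the
#'   causal block table in attribute `causal_blocks` and the panel site
#'   count in attribute `n_sites`.
#' @export
assign_effects <- function(panel, pool, params, block_size = 1e4, seed) {
  if (pool$n_chrom[1] != panel$n_hap) {
    stop("pool must be projected to the panel's chromosome count (",
         panel$n_hap, "); see project_counts()", call. = FALSE)
  }
  n_blocks <- floor(panel$region_length / block_size)
  if (params$n_causal_loci > n_blocks) {
    stop("more causal loci requested than available blocks", call. = FALSE)
  }
  with_seed(seed, {
    causal <- sort(sample.int(n_blocks, params$n_causal_loci))
    blocks <- data.frame(block = causal,
                         start = (causal - 1) * block_size,
                         end = causal * block_size)
    site_block <- floor(panel$pos / block_size) + 1
    in_causal <- site_block %in% causal & site_block <= n_blocks
    idx <- which(in_causal)

    rec <- data.frame(site = integer(0), pos = numeric(0),
                      count = integer(0), s = numeric(0), z = numeric(0),
                      block = integer(0))
    if (length(idx)) {
      s_matched <- match_pool_s(panel$counts[idx], pool)
      z <- effect_size(s_matched, pool, params)
      rec <- data.frame(site = idx, pos = panel$pos[idx],
                        count = panel$counts[idx], s = s_matched, z = z,
                        block = site_block[idx])
    }
    structure(rec, class = c("effect_assignment", "data.frame"),
              causal_blocks = blocks, n_sites = length(panel$pos),
              block_size = block_size)
  })
}

# Frequency-matched draw of selection coefficients: for each target count,
# sample uniformly among pool variants with the same count; if none, use
# the nearest count within +/- max(1, 5% of count).
match_pool_s <- function(target_counts, pool) {
  by_count <- split(pool$s, pool$count)
  avail <- as.integer(names(by_count))
  vapply(target_counts, function(cc) {
    key <- as.character(cc)
    cand <- by_count[[key]]
    if (is.null(cand)) {
      w <- max(1, round(0.05 * cc))
      ok <- avail[abs(avail - cc) <= w]
      if (!length(ok)) {
        stop("no pool variant within the matching window of count ", cc,
             call. = FALSE)
      }
      best <- ok[abs(ok - cc) == min(abs(ok - cc))]
      pick <- best[sample.int(length(best), 1)]
      cand <- by_count[[as.character(pick)]]
    }
    cand[sample.int(length(cand), 1)]
  }, 0)
}

#' Per-site effect vector of an assignment
#' @param effects An [effect_assignment()][assign_effects].
#' @return Numeric vector over all panel sites (0 outside causal blocks).
#' @export
effect_vector <- function(effects) {
  z <- numeric(attr(effects, "n_sites"))
  z[effects$site] <- effects$z
  z
}

#' @export
print.effect_assignment <- function(x, ...) {
  cat(sprintf(
    "Effect assignment: %d causal variants in %d blocks (of %d sites)\n",
    nrow(x), nrow(attr(x, "causal_blocks")), attr(x, "n_sites")))
  invisible(x)
}

#' Write an effect assignment as TSV
#' @param effects An [effect_assignment()][assign_effects].
#' @param path File path.
#' @export
write_effects_tsv <- function(effects, path) {
  df <- as.data.frame(effects)[, c("pos", "count", "s", "z", "block")]
  names(df)[5] <- "block_id"
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a quantitative trait at a target heritability
#'
#' Additive model: each individual's genetic score is
#' `G_i = sum_j X_ij z_j` with `X_ij` the diploid derived-allele count at
#' causal site j.  Environmental noise is Normal with variance
#' `Var(G) (1 - h2) / h2` computed from the realised sample variance of
#' `G`, which fixes the realised heritability at `h2` in expectation.
#'
#' @param panel A [haplotype_panel()] with genotypes.
#' @param effects An [effect_assignment()][assign_effects] on that panel.
#' @param h2 Heritability in `(0, 1]`.
#' @param seed Integer seed for the environmental draw.
#' @return An object of class `quant_trait`: data frame with columns
#'   `indiv`, `G`, `eps`, `Y` and attributes `h2`, `sigma2_env`.
#' @export
simulate_trait <- function(panel, effects, h2, seed = NULL) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]", call. = FALSE)
  n_ind <- n_individuals(panel)
  G <- numeric(n_ind)
  if (nrow(effects)) {
    # subset causal columns before collapsing haplotypes (memory)
    Hc <- panel$H[, effects$site, drop = FALSE]
    X <- Hc[seq(1L, panel$n_hap, 2L), , drop = FALSE] +
      Hc[seq(2L, panel$n_hap, 2L), , drop = FALSE]
    G <- as.vector(X %*% effects$z)
  }
  v_g <- var(G)
  if (v_g == 0 && h2 < 1) {
    stop("genetic score has zero variance; heritability below 1 is not ",
         "attainable", call. = FALSE)
  }
  sigma2 <- if (h2 == 1) 0 else v_g * (1 - h2) / h2
  eps <- with_seed(seed, rnorm(n_ind, 0, sqrt(sigma2)))
  structure(data.frame(indiv = seq_len(n_ind), G = G, eps = eps,
                       Y = G + eps),
            class = c("quant_trait", "data.frame"),
            h2 = h2, sigma2_env = sigma2)
}

#' @export
print.quant_trait <- function(x, ...) {
  v_g <- var(x$G)
  v_y <- var(x$Y)
  cat(sprintf(
    "Quantitative trait: %d individuals, realised Var(G)/Var(Y) = %.3f\n",
    nrow(x), if (v_y > 0) v_g / v_y else NA_real_))
  invisible(x)
}

#' Dichotomize a quantitative trait at a prevalence threshold
#'
#' Labels the `round(prevalence * n)` individuals with the highest
#' phenotypes as cases and the rest as controls.  Ties at the threshold
#' are broken by individual index (deterministic).
#'
#' @param trait A [quant_trait()][simulate_trait].
#' @param prevalence Case fraction in `(0, 1)`.
#' @return Integer vector of 0/1 labels (1 = case) over individuals.
#' @export
dichotomize <- function(trait, prevalence) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  n <- nrow(trait)
  k <- round(prevalence * n)
  if (k == 0 || k == n) {
    stop("prevalence yields an empty case or control set", call. = FALSE)
  }
  lab <- integer(n)
  lab[order(-trait$Y, trait$indiv)[seq_len(k)]] <- 1L
  lab
}

# ---- cumulative genetic variance -------------------------------------------

#' Cumulative genetic variance explained below a frequency threshold
#'
#' Discrete-sum evaluation of
#' `V_x = 0.5 * sum_{y <= x} E(z^2 | y) f(y) y (1 - y)`
#' over the frequency classes of a neutral site frequency spectrum, where
#' `E(z^2 | y) = rho E(s^{2 tau} | y) + (1 - rho) E_pool(s^{2 tau})` and
#' the conditional expectation is estimated from the pooled
#' fitness-variant table binned by derived allele count (one bin per
#' distinct count up to 100 copies, log-spaced above).  The threshold is
#' applied to the derived allele frequency, exactly as in the defining
#' integral.  Frequency classes with no pool variant contribute 0 to the
#' rho-weighted conditional component.
#'
#' The normalised share `ratio` divides each architecture component by
#' its own total variance before mixing, so it is exactly linear in
#' `rho`: `ratio(rho) = rho ratio(1) + (1 - rho) ratio(0)`.  This matches
#' the convention under which the rho/tau model's rare-variance table is
#' usually reported; the raw `V_x` and `V_1` mix the components before
#' normalising.
#'
#' @param pool A [fitness_variant_table()] at the same chromosome count as
#'   the SFS (project first if necessary).
#' @param sfs An [compute_sfs()] object from neutral simulations.
#' @param params An [architecture_params()] (only `rho`, `tau` used).
#' @param x Frequency threshold in `(0, 1]`.
#' @return List with `V_x` (raw, mixed architecture), `V_1`, `ratio` (the
#'   normalised rare-variance share) and `x`.
#' @export
variance_explained <- function(pool, sfs, params, x = 0.01) {
  if (x <= 0 || x > 1) stop("x must lie in (0, 1]", call. = FALSE)
  if (pool$n_chrom[1] != sfs$n_chrom) {
    stop("pool and SFS chromosome counts differ (", pool$n_chrom[1],
         " vs ", sfs$n_chrom, "); use project_counts()", call. = FALSE)
  }
  terms <- vx_terms(pool, sfs, params$tau)
  rare <- terms$y <= x
  vx_own <- sum(terms$own[rare]); v1_own <- sum(terms$own)
  vx_rnd <- sum(terms$rnd[rare]); v1_rnd <- sum(terms$rnd)
  rho <- params$rho
  ratio <- rho * (if (v1_own > 0) vx_own / v1_own else 0) +
    (1 - rho) * (if (v1_rnd > 0) vx_rnd / v1_rnd else 0)
  list(V_x = rho * vx_own + (1 - rho) * vx_rnd,
       V_1 = rho * v1_own + (1 - rho) * v1_rnd,
       ratio = ratio, x = x)
}

# Per-variant contributions 0.5 * E(z^2|class) * y (1-y) / n_variants for
# every neutral variant in the SFS, split into the two architecture
# components: `own` uses the frequency-conditional mean squared selection
# coefficient (the rho part), `rnd` the pool-wide mean (the 1 - rho
# part).  Each component is normalised by its own total variance, so the
# rare-variance share is linear in rho.
vx_terms <- function(pool, sfs, tau) {
  n <- sfs$n_chrom
  edges <- count_bins(n)
  pool_cls <- findInterval(pool$count, edges, rightmost.closed = TRUE)
  s2t <- pool$s^(2 * tau)
  ez2_bin <- rep(0, length(edges) - 1L)
  agg <- tapply(s2t, pool_cls, mean)
  ez2_bin[as.integer(names(agg))] <- agg
  e_pool <- mean(s2t)

  cls <- findInterval(sfs$counts, edges, rightmost.closed = TRUE)
  y <- sfs$counts / n
  w <- 0.5 * y * (1 - y) / length(y)
  data.frame(y = y, own = ez2_bin[cls] * w, rnd = e_pool * w)
}

#' Cumulative variance curve V_x / V_1 over a frequency grid
#' @inheritParams variance_explained
#' @param x_grid Frequency thresholds.
#' @return data.frame with columns `x` and `ratio`.
#' @export
cumulative_variance_curve <- function(pool, sfs, params,
                                      x_grid = 10^seq(-5, 0, 0.1)) {
  terms <- vx_terms(pool, sfs, params$tau)
  terms <- terms[order(terms$y), ]
  cum_own <- cumsum(terms$own)
  cum_rnd <- cumsum(terms$rnd)
  v1_own <- cum_own[length(cum_own)]
  v1_rnd <- cum_rnd[length(cum_rnd)]
  idx <- findInterval(x_grid, terms$y)
  own <- ifelse(idx == 0, 0, cum_own[pmax(idx, 1)] / v1_own)
  rnd <- ifelse(idx == 0, 0, cum_rnd[pmax(idx, 1)] / v1_rnd)
  data.frame(x = x_grid,
             ratio = params$rho * own + (1 - params$rho) * rnd)
}
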