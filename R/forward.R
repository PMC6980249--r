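#' Gamma distribution of fitness effects
#'
#' Parameters of the gamma-distributed selection coefficients assigned to
#' new functional mutations.  Magnitudes are stored; the fitness model
#' applies them as deleterious with additive (genic, h = 0.5) dominance.
#' Defaults follow the classic human nonsynonymous-site calibration
#' (strongly leptokurtic: shape 0.184, mean |s| 0.03).
#'
#' @param shape Gamma shape parameter (> 0).
#' @param mean Mean selection coefficient magnitude (> 0).
#' @return An object of class `dfe_params`.
#' @export
dfe_params <- function(shape = 0.184, mean = 0.03) {
  stopifnot(shape > 0, mean >= 0)
  structure(list(shape = shape, mean = mean, scale = if (mean > 0)
    mean / shape else 0), class = "dfe_params")
}

as_fitness_table <- function(df, meta = NULL) {
  stopifnot(all(c("s", "count", "n_chrom") %in% names(df)))
  structure(df, class = c("fitness_variant_table", "data.frame"),
            meta = meta)
}

#' Table of functional variants with fitness effects
#'
#' A data frame with one row per segregating functional variant: selection
#' coefficient magnitude `s`, derived allele `count` and the sampled
#' chromosome number `n_chrom`.  This is the pool from which phenotypic
#' effect sizes are assigned by frequency matching.
#'
#' @param s Selection coefficient magnitudes (>= 0).
#' @param count Derived allele counts, strictly inside `(0, n_chrom)`.
#' @param n_chrom Number of sampled chromosomes.
#' @return An object of class `fitness_variant_table`.
#' @export
fitness_variant_table <- function(s, count, n_chrom) {
  s <- as.numeric(s)
  count <- as.integer(count)
  if (any(s < 0)) stop("selection coefficients must be magnitudes >= 0",
                       call. = FALSE)
  if (any(count <= 0 | count >= n_chrom)) {
    stop("counts must lie strictly between 0 and n_chrom", call. = FALSE)
  }
  as_fitness_table(data.frame(s = s, count = count,
                              n_chrom = as.integer(n_chrom)))
}

#' @export
print.fitness_variant_table <- function(x, ...) {
  cat(sprintf(
    "Fitness variant table: %d variants in %d chromosomes (mean |s| %.3g)\n",
    nrow(x), x$n_chrom[1], mean(x$s)))
  invisible(x)
}

#' Write / read a fitness-variant table as TSV
#' @param table A [fitness_variant_table()].
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_fitness_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fitness_table
#' @export
read_fitness_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  fitness_variant_table(df$s, df$count, df$n_chrom[1])
}

# Sample selection magnitudes from the strong tail of the DFE with density
# proportional to f(s)/s (sojourn weighting), by inverse-CDF on a log grid.
sample_tail_s <- function(n, dfe, s_min) {
  if (n == 0) return(numeric(0))
  s_hi <- stats::qgamma(1 - 1e-12, dfe$shape, scale = dfe$scale)
  grid <- exp(seq(log(s_min), log(max(s_hi, s_min * 2)), length.out = 2048))
  mid <- sqrt(grid[-1] * grid[-length(grid)])
  w <- stats::dgamma(mid, dfe$shape, scale = dfe$scale) / mid *
    diff(grid)
  idx <- sample.int(length(mid), n, replace = TRUE, prob = w)
  # jitter uniformly within the chosen log cell
  exp(log(grid[idx]) + runif(n) * (log(grid[idx + 1]) - log(grid[idx])))
}

#' Forward-simulate a pool of functional variants under selection
#'
#' Simulates `n_loci` independent loci forward in time under the African
#' size history of `model` with purifying selection: new mutations arise
#' at rate `mu` per bp, draw a gamma selection coefficient from `dfe`, and
#' drift under binomial Wright-Fisher sampling with genic selection
#' (h = 0.5).  The simulation is rescaled by `rescale` (population sizes
#' divided, selection and mutation multiplied, time compressed).  At the
#' final generation the population frequencies are binomially projected to
#' `2 * n_individuals` chromosomes.
#'
#' Mutations too strongly selected to be representable at the rescaled
#' population size (rescaled |s| above `s_cap`) are injected analytically
#' at deterministic mutation-selection balance (frequency `2 mu / s`), as
#' independent sampled copies; see the methods vignette for the
#' approximation involved.
#'
#' @param model A [demographic_model()] containing an `AFR` deme (or the
#'   deme named by `population`).
#' @param dfe A [dfe_params()].
#' @param n_loci Number of independent loci.
#' @param locus_length Locus length in bp.
#' @param n_individuals Diploid sample size for the output table.
#' @param rescale Rescaling factor (>= 1).
#' @param mu Per-bp per-generation mutation rate.
#' @param population Deme whose size history drives the simulation.
#' @param s_cap Largest representable rescaled selection magnitude.
#' @param seed Integer seed.
#' @return A [fitness_variant_table()] pooled across loci, with metadata
#'   attribute `meta` recording the simulation settings.
#' @export
simulate_fitness_table <- function(model, dfe, n_loci = 2000,
                                   locus_length = 1e5,
                                   n_individuals = 1e5, rescale = 100,
                                   mu = 1e-8, population = "AFR",
                                   s_cap = 1.9, seed) {
  stopifnot(rescale >= 1, n_loci >= 1, locus_length > 0)
  n_chrom_out <- as.integer(2 * n_individuals)
  traj <- forward_size_trajectory(model, population, rescale)
  mu_locus <- mu * rescale * locus_length
  scale_r <- max(dfe$scale * rescale, 1e-300)

  core <- .wf_fitness_core(traj, mu_locus, as.integer(n_loci), dfe$shape,
                           scale_r, s_cap, n_chrom_out,
                           as.integer(seed))
  s <- if (dfe$mean == 0) rep(0, length(core$s)) else core$s / rescale
  count <- core$count

  # analytic injection of the strong-selection tail (|s| > s_cap/rescale):
  # at mutation-selection balance each site segregates at frequency
  # 2*mu/s, so the expected number of sampled copies per locus is
  # n_chrom_out * mu * L * E_tail[2/s]; copies enter as singletons.
  s_min <- s_cap / rescale
  if (dfe$mean > 0) {
    p_tail <- stats::pgamma(s_min, dfe$shape, scale = dfe$scale,
                            lower.tail = FALSE)
    if (p_tail > 0) {
      e_inv <- stats::integrate(function(x)
        2 / x * stats::dgamma(x, dfe$shape, scale = dfe$scale),
        s_min, Inf, rel.tol = 1e-8)$value
      lambda <- n_chrom_out * mu * locus_length * n_loci * e_inv
      n_tail <- with_seed(derive_seed(seed, "tail"), {
        n_tail <- rpois(1, lambda)
        s <- c(s, sample_tail_s(n_tail, dfe, s_min))
        n_tail
      })
      count <- c(count, rep(1L, n_tail))
    }
  }

  ord <- order(s)
  tab <- fitness_variant_table(s[ord], count[ord], n_chrom_out)
  attr(tab, "meta") <- list(rescale = rescale, n_loci = n_loci,
                            locus_length = locus_length, mu = mu,
                            dfe = dfe, population = population,
                            s_cap = s_cap, seed = seed)
  tab
}
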