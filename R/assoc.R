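#' Fit the intercept-only logistic null model
#'
#' With no covariates the null model has closed form: every fitted
#' probability equals the case fraction.  The object carries the residuals
#' and variance function used by all score-based tests.
#'
#' @param y Binary 0/1 phenotype vector with both classes present.
#' @return An object of class `null_model` with fields `y`, `mu`,
#'   `resid`, `v` (= mu (1 - mu)) and `n`.
#' @export
fit_null <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both cases and controls are required", call. = FALSE)
  }
  mu <- mean(y)
  structure(list(y = y, mu = mu, resid = y - mu, v = mu * (1 - mu),
                 n = length(y)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Null model: n = %d, case fraction = %.4f (intercept %.4f)\n",
              x$n, x$mu, log(x$mu / (1 - x$mu))))
  invisible(x)
}

# ---- tail probability of a mixture of chi-squares ---------------------------

liu_params <- function(lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- 1 / s2
  }
  list(mu_q = c1, sigma_q = sqrt(2 * c2), df = df, delta = delta,
       mu_x = df + delta, sigma_x = sqrt(2 * (df + 2 * delta)))
}

liu_pvalue <- function(lambdas, q) {
  # moment-matching approximation (non-central chi-square surrogate)
  lp <- liu_params(lambdas)
  q_norm <- (q - lp$mu_q) / lp$sigma_q * lp$sigma_x + lp$mu_x
  pchisq(q_norm, df = lp$df, ncp = lp$delta, lower.tail = FALSE)
}

liu_quantile <- function(lambdas, p_upper) {
  # upper-tail quantile of the mixture under the Liu surrogate
  lp <- liu_params(lambdas)
  q_x <- qchisq(p_upper, df = lp$df, ncp = lp$delta, lower.tail = FALSE)
  (q_x - lp$mu_x) / lp$sigma_x * lp$sigma_q + lp$mu_q
}

saddlepoint_pvalue <- function(lambdas, q) {
  # Kuonen's saddlepoint approximation to P(sum lambda_k chi2_1 > q)
  k0 <- function(z) -0.5 * sum(log(1 - 2 * z * lambdas))
  kp <- function(z) sum(lambdas / (1 - 2 * z * lambdas))
  kpp <- function(z) 2 * sum(lambdas^2 / (1 - 2 * z * lambdas)^2)
  zmax <- 1 / (2 * max(lambdas)) * (1 - 1e-9)
  mean_q <- sum(lambdas)
  if (abs(q - mean_q) < 1e-12 * mean_q) return(NA_real_)
  root <- tryCatch(
    uniroot(function(z) kp(z) - q, lower = -1e3, upper = zmax,
            tol = 1e-12)$root,
    error = function(e) NA_real_)
  if (is.na(root)) return(NA_real_)
  w <- sign(root) * sqrt(max(0, 2 * (root * q - k0(root))))
  v <- root * sqrt(kpp(root))
  if (abs(v) < 1e-300 || abs(w) < 1e-8) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Imhof-form inversion integral (compiled): adaptive quadrature over
# oscillation-scaled segments plus a two-term integration-by-parts
# correction for the (infinite, oscillatory) tail.  Returns NA when the
# requested accuracy cannot be certified.
imhof_inversion <- function(lambdas, q, acc = 1e-9) {
  out <- .imhof_core(as.numeric(lambdas), q, acc)
  if (is.nan(out)) NA_real_ else out
}

#' Tail probability of a positive mixture of chi-square(1) variables
#'
#' Computes `P(sum_k lambda_k chi^2_1 > q)` by numerical inversion of the
#' characteristic function (the Davies/Imhof integral), with a
#' saddlepoint approximation for extreme tails and a moment-matching
#' (Liu) fallback when inversion fails.  The method actually used is
#' recorded in attribute `method`.
#'
#' @param lambdas Non-negative eigenvalue weights, at least one positive.
#' @param q Observed statistic.
#' @param acc Target absolute accuracy of the inversion.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
davies_pvalue <- function(lambdas, q, acc = 1e-9) {
  lambdas <- lambdas[lambdas > 0]
  if (!length(lambdas)) {
    stop("at least one positive eigenvalue is required", call. = FALSE)
  }
  if (q <= 0) return(structure(1, method = "exact"))
  lambdas <- lambdas[lambdas >= 1e-7 * max(lambdas)]
  if (length(lambdas) == 1L) {
    return(structure(pchisq(q / lambdas, df = 1, lower.tail = FALSE),
                     method = "exact"))
  }
  p <- imhof_inversion(lambdas, q, acc = acc)
  method <- "davies"
  if (is.na(p) || p < max(1e-7, 10 * acc) || p > 1 + 1e-8) {
    # deep tails: the saddlepoint approximation is relatively accurate
    # where an absolute-accuracy inversion is not
    sp <- saddlepoint_pvalue(lambdas, q)
    if (!is.na(sp)) {
      p <- sp
      method <- "saddlepoint"
    } else if (is.na(p) || p <= 0 || p > 1 + 1e-8) {
      p <- liu_pvalue(lambdas, q)
      method <- "liu"
    }
  }
  structure(min(max(p, 1e-300), 1), method = method)
}

# eigenvalues of a symmetric PSD matrix, small ones dropped
psd_eigenvalues <- function(A) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev) * 1e-10 & ev > 0]
}

#' Beta-density variant weights
#'
#' The standard kernel-test weighting: the Beta(`a`, `b`) density
#' evaluated at the minor allele frequency, up-weighting rare variants
#' (default Beta(1, 25)).
#'
#' @param maf Minor allele frequencies.
#' @param a,b Beta shape parameters.
#' @return Numeric weights.
#' @export
beta_maf_weights <- function(maf, a = 1, b = 25) dbeta(maf, a, b)

# ---- SKAT -------------------------------------------------------------------

#' Sequence kernel association test (variance-component score test)
#'
#' Computes the SKAT statistic `Q = (y - mu)' G W^2 G' (y - mu)` for a
#' block of (possibly fractional) dosages and evaluates its null tail
#' probability from the eigenvalues of `W G' P0 G W`, where `P0` is the
#' projection variance of the intercept-only logistic null.
#'
#' @param G n x m dosage matrix for the variants in the block.
#' @param null A [fit_null()] model on the same individuals.
#' @param weights Per-variant weights; default is the Beta(1, 25) density
#'   of the within-cohort MAF.
#' @return p-value with attribute `method` (tail algorithm used).
#' @export
skat <- function(G, null, weights = NULL) {
  G <- as.matrix(G)
  stopifnot(nrow(G) == null$n, ncol(G) >= 1)
  if (is.null(weights)) {
    maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
    weights <- beta_maf_weights(maf)
  }
  u <- as.vector(crossprod(G, null$resid)) * weights
  q_stat <- sum(u^2)
  Gw <- sweep(G, 2L, weights, "*")
  Gc <- sweep(Gw, 2L, colMeans(Gw), "-")
  lambdas <- psd_eigenvalues(null$v * crossprod(Gc))
  davies_pvalue(lambdas, q_stat)
}

# ---- SKAT-O -----------------------------------------------------------------

skat_o_prep <- function(G, null, weights) {
  Gw <- sweep(as.matrix(G), 2L, weights, "*")
  r <- null$resid
  score <- as.vector(crossprod(Gw, r))
  Z <- sqrt(null$v) * sweep(Gw, 2L, colMeans(Gw), "-")
  list(q_skat = sum(score^2), q_burden = sum(score)^2, Z = Z,
       m = ncol(Gw))
}

rho_kernel_lambdas <- function(Z, rho) {
  m <- ncol(Z)
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  # R_rho^{1/2} = a I + b 11'
  K <- crossprod(Z)
  ones <- matrix(1, m, m)
  Krho <- a^2 * K + a * b * (K %*% ones + ones %*% K) +
    b^2 * sum(K) * ones
  psd_eigenvalues(Krho)
}


#' Optimal unified kernel association test (SKAT-O)
#'
#' Evaluates `Q_rho = (1 - rho) Q_SKAT + rho Q_burden` over a grid of
#' kernel-mixing parameters, takes the minimum p-value over the grid and
#' corrects for the minimisation through the standard one-dimensional
#' integral over the common (burden-direction) chi-square component.
#' A single-point grid reduces exactly to SKAT (`rho = 0`) or to the
#' weighted burden score test (`rho = 1`).
#'
#' @inheritParams skat
#' @param rho_grid Grid of mixing parameters in `[0, 1]`.
#' @return p-value.
#' @export
skat_o <- function(G, null, weights = NULL,
                   rho_grid = seq(0, 1, by = 0.1)^2) {
  G <- as.matrix(G)
  if (is.null(weights)) {
    maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
    weights <- beta_maf_weights(maf)
  }
  prep <- skat_o_prep(G, null, weights)
  Z <- prep$Z
  m <- prep$m
  if (m == 1L) rho_grid <- 0   # one variant: all kernels coincide
  rho_grid <- sort(unique(rho_grid))
  q_rho <- (1 - rho_grid) * prep$q_skat + rho_grid * prep$q_burden
  lam_rho <- lapply(rho_grid, function(r) rho_kernel_lambdas(Z, r))
  p_each <- vapply(seq_along(rho_grid), function(i)
    as.numeric(davies_pvalue(lam_rho[[i]], q_rho[i])), 0)
  if (length(rho_grid) == 1L) return(p_each)
  t_min <- min(p_each)

  # parameters of the decomposition Q_rho ~ (1-rho) kappa + tau(rho) eta0
  z_mean <- rowMeans(Z)
  z2 <- sum(z_mean^2)
  if (z2 < 1e-300) return(t_min)   # degenerate burden direction
  cof1 <- as.vector(crossprod(z_mean, Z)) / z2
  Z1 <- Z - outer(z_mean, cof1)
  lambda <- psd_eigenvalues(crossprod(Z1))
  var_remain <- 4 * sum(crossprod(outer(z_mean, cof1)) * crossprod(Z1))
  mu_q <- sum(lambda)
  var_q <- 2 * sum(lambda^2) + var_remain
  tau_rho <- (m^2 * rho_grid + (1 - rho_grid) * sum(cof1^2)) * z2

  # per-rho null quantiles at level t_min (Liu moment-matched, as in the
  # reference implementation of the combined test)
  q_min <- vapply(seq_along(rho_grid), function(i)
    liu_quantile(lam_rho[[i]], t_min), 0)

  rho_c <- pmin(rho_grid, 0.999)   # avoid 1/(1 - rho) blow-up at rho = 1
  shrink <- sqrt(max(var_q - var_remain, 0) / var_q)
  sd_q <- sqrt(var_q)
  # p = P(min_rho p_rho <= t_min) = E_x[ P(kappa > min_rho cond. bound) ]
  # integrated against the chi-square(1) density of the common component;
  # integrating the survival side keeps small p-values accurate.
  surv_at <- function(xx) {
    qmin_cond <- min((q_min - tau_rho * xx) / (1 - rho_c))
    if (qmin_cond <= 0) return(1)
    if (qmin_cond > mu_q + 150 * sd_q) return(0)
    q_adj <- (qmin_cond - mu_q) * shrink + mu_q
    min(1, as.numeric(davies_pvalue(lambda, q_adj, acc = 1e-7)))
  }
  # substitute x = t^2 so the chi-square(1) density becomes a (smooth)
  # half-normal weight
  integrand <- function(t) {
    vapply(t, function(tt) surv_at(tt^2) * 2 * stats::dnorm(tt), 0)
  }
  t_max <- sqrt(qchisq(1e-12, df = 1, lower.tail = FALSE))
  int <- tryCatch(
    integrate(integrand, 0, t_max, subdivisions = 500L,
              rel.tol = 1e-6, abs.tol = t_min * 1e-4),
    error = function(e) NULL)
  if (is.null(int)) return(min(t_min * length(rho_grid), 1))
  p <- int$value + pchisq(t_max^2, df = 1, lower.tail = FALSE)
  p <- min(p, t_min * length(rho_grid))   # Bonferroni cap
  max(p, t_min)
}

# ---- KBAC -------------------------------------------------------------------

#' Kernel-based adaptive cluster test
#'
#' Groups individuals by their multi-site rare genotype pattern, weights
#' each non-null pattern by the hypergeometric-tail probability of its
#' observed case count, and tests the weighted difference between case
#' and control pattern frequencies by one-sided adaptive Monte-Carlo
#' permutation of the phenotype (early-stopping once the p-value's
#' confidence interval excludes `alpha_stop`).
#'
#' @param G n x m genotype matrix; dosages are rounded to hard calls.
#' @param y Binary phenotype vector.
#' @param max_perm Permutation cap.
#' @param alpha_stop Decision threshold driving adaptive early stopping;
#'   a non-positive value disables early stopping (all `max_perm`
#'   permutations are used).
#' @param alternative `"one.sided"` (case enrichment, the classic form)
#'   or `"two.sided"`.
#' @param seed Integer seed for the permutation stream.
#' @return p-value with attribute `n_perm` (permutations used).
#' @export
kbac <- function(G, y, max_perm = 1e4, alpha_stop = 0.05,
                 alternative = c("one.sided", "two.sided"), seed = NULL) {
  alternative <- match.arg(alternative)
  G <- round(as.matrix(G))
  y <- as.integer(y)
  stopifnot(nrow(G) == length(y))
  key <- do.call(paste, c(as.data.frame(G), sep = ","))
  carrier <- rowSums(G != 0) > 0
  if (!any(carrier)) {
    return(structure(1, n_perm = 0L))
  }
  pat <- integer(length(y))
  pat[carrier] <- as.integer(factor(key[carrier]))
  ord <- order(!carrier)            # carriers first for partial shuffling
  res <- .kbac_perm_core(pat[ord], y[ord], as.integer(max_perm),
                         alpha_stop, alternative == "two.sided",
                         as.integer(seed %||% 1L))
  structure(res$p, n_perm = res$n_perm, stat = res$stat)
}

# ---- single-variant logistic score test -------------------------------------

#' Single-variant association scan (logistic score test)
#'
#' One-degree-of-freedom score test of each dosage column against the
#' intercept-only logistic null, restricted to variants at or above a MAF
#' threshold.  Zero-variance genotypes are excluded.
#'
#' @param G n x m dosage matrix.
#' @param y Binary phenotype vector.
#' @param maf_min Minimum within-cohort MAF (default 0.01).
#' @return data.frame with columns `site` (column index in `G`), `maf`,
#'   `stat` (chi-square), `p`.
#' @export
gwas_logistic <- function(G, y, maf_min = 0.01) {
  G <- as.matrix(G)
  null <- fit_null(y)
  n <- null$n
  af <- colMeans(G) / 2
  maf <- pmin(af, 1 - af)
  cs <- colSums(G)
  css <- colSums(G^2)
  v_g <- css - cs^2 / n
  keep <- which(maf >= maf_min & v_g > 0)
  if (length(keep) < sum(maf >= maf_min)) {
    message(sum(maf >= maf_min) - length(keep),
            " zero-variance variant(s) excluded from the scan")
  }
  u <- as.vector(crossprod(G[, keep, drop = FALSE], null$resid))
  stat <- u^2 / (null$v * v_g[keep])
  data.frame(site = keep, maf = maf[keep], stat = stat,
             p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# ---- block runner -----------------------------------------------------------

#' Run association tests over non-overlapping blocks
#'
#' Applies the requested rare-variant tests (on variants with
#' within-cohort MAF below `rare_maf`) and/or the single-variant scan
#' (summarised per block as the minimum p-value, `GWAS-min`) to
#' non-overlapping blocks tiling the region.  A trailing partial block is
#' dropped.  Blocks without qualifying rare variants are recorded as
#' `no_rare_variants` with a missing p-value.
#'
#' @param data Genotype source: a [haplotype_panel()] (sequence mode;
#'   cohort individuals are extracted from it) or an imputed dosage
#'   matrix from [impute()] (rows already in cohort order).
#' @param cohort A [cohort][sample_cohort].
#' @param tests Subset of `c("SKAT", "SKATO", "KBAC", "GWAS")`.
#' @param block_size Block size in bp.
#' @param rare_maf Rare-variant inclusion threshold (MAF strictly below).
#' @param gwas_maf_min MAF threshold of the single-variant scan.
#' @param kbac_max_perm,kbac_alpha_stop KBAC permutation controls.
#' @param seed Integer seed (drives KBAC permutation streams).
#' @return data.frame of class `block_test_result` with columns `block`,
#'   `block_start`, `block_end`, `test`, `p`, `n_variants`, `status`.
#' @export
run_blocks <- function(data, cohort,
                       tests = c("SKAT", "SKATO", "KBAC", "GWAS"),
                       block_size = 1e4, rare_maf = 0.01,
                       gwas_maf_min = 0.01, kbac_max_perm = 1e4,
                       kbac_alpha_stop = 0.05, seed = 1L) {
  if (length(tests)) {
    tests <- match.arg(tests, several.ok = TRUE)
  }
  if (inherits(data, "haplotype_panel")) {
    D <- diploid_genotypes(data, cohort$indiv)
    pos <- data$pos
    region_length <- data$region_length
  } else if (inherits(data, "imputed_matrix")) {
    D <- data$dosage
    pos <- data$pos
    region_length <- data$region_length
    stopifnot(nrow(D) == nrow(cohort))
  } else {
    stop("data must be a haplotype_panel or imputed_matrix", call. = FALSE)
  }
  y <- cohort$case
  null <- fit_null(y)
  n_blocks <- floor(region_length / block_size)
  site_block <- floor(pos / block_size) + 1
  af <- colMeans(D) / 2
  maf <- pmin(af, 1 - af)
  rare <- maf > 0 & maf < rare_maf

  gwas_tab <- if ("GWAS" %in% tests) gwas_logistic(D, y, gwas_maf_min)

  res <- list()
  for (b in seq_len(n_blocks)) {
    sites <- which(site_block == b)
    rare_sites <- sites[rare[sites]]
    m <- length(rare_sites)
    rvat <- setdiff(tests, "GWAS")
    if (m > 0L && length(rvat)) {
      Gb <- D[, rare_sites, drop = FALSE]
      w <- beta_maf_weights(maf[rare_sites])
      for (tn in rvat) {
        p <- switch(tn,
          SKAT = as.numeric(skat(Gb, null, w)),
          SKATO = as.numeric(skat_o(Gb, null, w)),
          KBAC = as.numeric(kbac(Gb, y, max_perm = kbac_max_perm,
                                 alpha_stop = kbac_alpha_stop,
                                 seed = derive_seed(seed, "kbac", b))))
        res[[length(res) + 1L]] <-
          data.frame(block = b, test = tn, p = p, n_variants = m,
                     status = "ok")
      }
    } else if (length(rvat)) {
      for (tn in rvat) {
        res[[length(res) + 1L]] <-
          data.frame(block = b, test = tn, p = NA_real_, n_variants = 0L,
                     status = "no_rare_variants")
      }
    }
    if ("GWAS" %in% tests) {
      in_b <- gwas_tab[gwas_tab$site %in% sites, , drop = FALSE]
      res[[length(res) + 1L]] <- data.frame(
        block = b, test = "GWAS-min",
        p = if (nrow(in_b)) min(in_b$p) else NA_real_,
        n_variants = nrow(in_b),
        status = if (nrow(in_b)) "ok" else "no_common_variants")
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(block = integer(0), test = character(0),
                      p = numeric(0), n_variants = integer(0),
                      status = character(0))
  }
  out$block_start <- (out$block - 1) * block_size
  out$block_end <- out$block * block_size
  out <- out[, c("block", "block_start", "block_end", "test", "p",
                 "n_variants", "status")]
  class(out) <- c("block_test_result", "data.frame")
  out
}

#' Write block test results as TSV
#' @param results A [run_blocks()] result.
#' @param path File path.
#' @export
write_results_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
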