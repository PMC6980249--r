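#' Genotyping-array manifest
#'
#' Describes an array design by its target minor-allele-frequency
#' spectrum (proportions of markers per MAF bin) and mean inter-marker
#' spacing.
#'
#' @param maf_edges Increasing MAF bin edges from 0 to 0.5.
#' @param proportions Marker proportions per bin (sum to 1).
#' @param mean_spacing_bp Target mean distance between markers (> 0).
#' @return An object of class `array_manifest`.
#' @export
array_manifest <- function(maf_edges, proportions, mean_spacing_bp) {
  stopifnot(length(proportions) == length(maf_edges) - 1L)
  if (any(diff(maf_edges) <= 0)) {
    stop("maf_edges must be strictly increasing", call. = FALSE)
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  }
  if (mean_spacing_bp <= 0) {
    stop("mean_spacing_bp must be positive", call. = FALSE)
  }
  structure(list(maf_edges = as.numeric(maf_edges),
                 proportions = as.numeric(proportions),
                 mean_spacing_bp = as.numeric(mean_spacing_bp)),
            class = "array_manifest")
}

#' Bundled array manifest fixture
#'
#' Loads the packaged synthetic manifest emulating a dense commercial
#' genome-wide genotyping chip: a common-variant-skewed MAF spectrum and
#' one marker per ~2 kb (~2500 markers over 5 Mb).  Fully replaceable by
#' a user manifest via [array_manifest()].
#'
#' @return An [array_manifest()].
#' @export
build_manifest_fixture <- function() {
  path <- system.file("extdata", "array_manifest_omniexpress_synthetic.yaml",
                      package = "rvpower", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  array_manifest(cfg$maf_edges, cfg$proportions, cfg$mean_spacing_bp)
}

#' Downsample a sequence panel to an array-like typed panel
#'
#' Greedy stratified site selection: the number of markers is
#' `region_length / mean_spacing_bp`, allocated across MAF bins according
#' to the manifest proportions; within each bin sites are drawn in random
#' order subject to a minimum-spacing constraint (a quarter of the target
#' spacing).  Bins with too few eligible sites are topped up from the
#' nearest bins with a warning.
#'
#' @param panel A [haplotype_panel()] with genotypes.
#' @param manifest An [array_manifest()].
#' @param seed Integer seed (selection is deterministic given the seed).
#' @return An object of class `typed_panel`: the typed-site genotype
#'   matrix `H` plus the full-site coordinate system of the parent panel
#'   (`pos_all`, `typed_idx`).
#' @export
downsample_to_array <- function(panel, manifest, seed = 1L) {
  if (is.null(panel$H)) stop("panel carries no genotypes", call. = FALSE)
  maf <- pmin(panel$counts, panel$n_hap - panel$counts) / panel$n_hap
  n_target <- round(panel$region_length / manifest$mean_spacing_bp)
  n_target <- min(n_target, length(panel$pos))
  bin <- findInterval(maf, manifest$maf_edges, rightmost.closed = TRUE)
  n_bins <- length(manifest$proportions)
  quota <- round(manifest$proportions * n_target)
  min_gap <- manifest$mean_spacing_bp / 4

  chosen <- logical(length(panel$pos))
  taken_pos <- numeric(0)
  shortfall <- integer(n_bins)
  with_seed(seed, {
    for (b in order(quota)) {   # scarce bins first
      cand <- which(bin == b & !chosen)
      cand <- cand[sample.int(length(cand))]
      got <- 0L
      for (i in cand) {
        if (got >= quota[b]) break
        p <- panel$pos[i]
        if (!length(taken_pos) || min(abs(taken_pos - p)) >= min_gap) {
          chosen[i] <- TRUE
          taken_pos <- c(taken_pos, p)
          got <- got + 1L
        }
      }
      shortfall[b] <- quota[b] - got
    }
    deficit <- sum(shortfall)
    if (deficit > 0L) {
      warning(deficit, " marker(s) reallocated across MAF bins ",
              "(infeasible bins)", call. = FALSE)
      cand <- which(!chosen)
      cand <- cand[sample.int(length(cand))]
      for (i in cand) {
        if (deficit <= 0L) break
        p <- panel$pos[i]
        if (!length(taken_pos) || min(abs(taken_pos - p)) >= min_gap) {
          chosen[i] <- TRUE
          taken_pos <- c(taken_pos, p)
          deficit <- deficit - 1L
        }
      }
    }
  })
  typed_idx <- which(chosen)
  structure(list(H = panel$H[, typed_idx, drop = FALSE],
                 typed_idx = typed_idx,
                 pos_all = panel$pos,
                 pos = panel$pos[typed_idx],
                 n_hap = panel$n_hap,
                 region_length = panel$region_length,
                 manifest = manifest),
            class = "typed_panel")
}

#' @export
print.typed_panel <- function(x, ...) {
  sp <- if (length(x$pos) > 1) mean(diff(x$pos)) else NA_real_
  cat(sprintf(
    "Typed panel: %d of %d sites on the array (mean spacing %.0f bp)\n",
    length(x$typed_idx), length(x$pos_all), sp))
  invisible(x)
}

#' Restrict a typed panel to a subset of individuals
#' @param typed A [typed_panel][downsample_to_array].
#' @param individuals Individual indices to keep.
#' @export
typed_for_individuals <- function(typed, individuals) {
  hap <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  out <- typed
  out$H <- typed$H[hap, , drop = FALSE]
  out$n_hap <- length(hap)
  out
}

#' Impute untyped sites from a sequenced reference panel
#'
#' Haplotype-copying imputation: each (phased, simulated) target
#' haplotype is modelled as a mosaic of `n_states` randomly selected
#' reference haplotypes with a constant per-bp switch rate and a symmetric
#' mismatch rate; forward-backward posteriors over the copying path give
#' expected allele dosages at untyped sites.  Typed sites pass through as
#' the observed genotypes.
#'
#' @param typed A [typed_panel][downsample_to_array] holding the target
#'   individuals' typed genotypes.
#' @param reference A [haplotype_panel()] of reference individuals with
#'   the same full site list (`pos` identical to the typed panel's
#'   `pos_all`); must not contain the target individuals.
#' @param n_states Number of reference haplotypes copied per target
#'   haplotype.
#' @param recomb_penalty Per-bp switch rate of the copying path.
#' @param mismatch_penalty Allele mismatch probability at typed sites.
#' @param selection How the per-target copying states are chosen from the
#'   reference: `"nearest"` (smallest Hamming distance at typed sites,
#'   the usual pre-selection of haplotype-copying imputation) or
#'   `"random"`.
#' @param seed Integer seed for the reference-state selection
#'   (tie-breaking under `"nearest"`, sampling under `"random"`).
#' @return An object of class `imputed_matrix`: diploid dosage matrix
#'   (individuals x all sites, entries in `[0, 2]`) with `pos`,
#'   `typed_idx` and region metadata.
#' @export
impute <- function(typed, reference, n_states = 200,
                   recomb_penalty = 2e-6, mismatch_penalty = 1e-3,
                   selection = c("nearest", "random"), seed = 1L) {
  selection <- match.arg(selection)
  if (is.null(reference$H) || reference$n_hap == 0) {
    stop("empty reference panel", call. = FALSE)
  }
  if (!isTRUE(all.equal(reference$pos, typed$pos_all))) {
    stop("reference and typed panels must share the same site ",
         "coordinates", call. = FALSE)
  }
  n_states <- min(n_states, reference$n_hap)
  n_tgt_hap <- typed$n_hap
  states <- with_seed(seed, {
    if (selection == "random" || n_states == reference$n_hap) {
      vapply(seq_len(n_tgt_hap), function(h)
        sample.int(reference$n_hap, n_states), integer(n_states))
    } else {
      ref_t <- reference$H[, typed$typed_idx, drop = FALSE]
      obs <- typed$H
      # agreements = X R' + (1-X)(1-R)'; higher is closer
      agree <- obs %*% t(ref_t) + (1 - obs) %*% t(1 - ref_t)
      jitter <- matrix(runif(length(agree)), nrow(agree))
      vapply(seq_len(n_tgt_hap), function(h) {
        order(-agree[h, ], jitter[h, ])[seq_len(n_states)]
      }, integer(n_states))
    }
  })
  dos_hap <- .ls_impute_core(reference$H, typed$H,
                             as.integer(typed$typed_idx),
                             states, as.numeric(typed$pos_all),
                             recomb_penalty, mismatch_penalty)
  odd <- seq(1L, n_tgt_hap, 2L)
  dosage <- dos_hap[odd, , drop = FALSE] +
    dos_hap[odd + 1L, , drop = FALSE]
  dosage <- pmin(pmax(dosage, 0), 2)   # guard rounding overshoot
  structure(list(dosage = dosage, pos = typed$pos_all,
                 typed_idx = typed$typed_idx,
                 region_length = typed$region_length,
                 n_states = n_states),
            class = "imputed_matrix")
}

#' @export
print.imputed_matrix <- function(x, ...) {
  cat(sprintf(
    "Imputed matrix: %d individuals x %d sites (%d typed), %d copying states\n",
    nrow(x$dosage), ncol(x$dosage), length(x$typed_idx), x$n_states))
  invisible(x)
}

#' Per-site imputation quality r-squared
#'
#' Squared Pearson correlation between imputed dosage and the true
#' diploid genotype at every site.  Sites where either the dosage or the
#' truth is constant get a missing value.
#'
#' @param imputed An [impute()] result.
#' @param truth A [haplotype_panel()] with the true genotypes of the same
#'   individuals, same site list.
#' @param individuals Indices of the imputed individuals within `truth`.
#' @return data.frame with columns `pos`, `maf` (true within-sample MAF),
#'   `r2`, `typed`.
#' @export
imputation_r2 <- function(imputed, truth, individuals = NULL) {
  X <- diploid_genotypes(truth, individuals)
  if (!all(dim(X) == dim(imputed$dosage))) {
    stop("dosage and truth dimensions differ", call. = FALSE)
  }
  af <- colMeans(X) / 2
  maf <- pmin(af, 1 - af)
  r2 <- vapply(seq_len(ncol(X)), function(j) {
    if (var(X[, j]) == 0 || var(imputed$dosage[, j]) == 0) {
      return(NA_real_)
    }
    cor(imputed$dosage[, j], X[, j])^2
  }, 0)
  data.frame(pos = imputed$pos, maf = maf, r2 = r2,
             typed = seq_len(ncol(X)) %in% imputed$typed_idx)
}

#' Write imputed dosages as a VCF with DS field
#' @param imputed An [impute()] result.
#' @param path File path.
#' @param chrom Chromosome label.
#' @export
write_dosage_vcf <- function(imputed, path, chrom = "1") {
  n_ind <- nrow(imputed$dosage)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom,
                   as.integer(imputed$region_length)),
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ind", seq_len(n_ind))),
                 collapse = "\t"))
  rows <- vapply(seq_along(imputed$pos), function(j) {
    paste(c(chrom, format(imputed$pos[j] + 1, scientific = FALSE), ".",
            "A", "T", ".", "PASS", ".", "DS",
            sprintf("%.3f", imputed$dosage[, j])),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
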