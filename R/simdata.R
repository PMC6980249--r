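#' Phased haplotype panel
#'
#' Holds phased 0/1 haplotypes for a simulated region: `H` is an
#' n_haplotypes x n_sites integer matrix (0 = ancestral, 1 = derived),
#' `pos` the 0-based site positions and `counts` the per-site derived
#' allele counts.  `H` may be `NULL` for count-only panels (allele counts
#' without genotypes), which is how large site-frequency-spectrum inputs
#' are carried around without materialising genotype matrices.
#'
#' @param H Haplotype matrix or `NULL`.
#' @param pos Strictly increasing 0-based positions.
#' @param region_length Region length in bp.
#' @param n_hap Number of haplotypes (required when `H` is `NULL`).
#' @param counts Per-site derived counts (column sums of `H` if omitted).
#' @param allow_monomorphic Permit monomorphic columns (used for
#'   individual-subset panels that must keep the parent's site list).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(H, pos, region_length, n_hap = nrow(H),
                            counts = NULL, allow_monomorphic = FALSE) {
  pos <- as.numeric(pos)
  if (length(pos) > 1 && any(diff(pos) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (!is.null(H)) {
    stopifnot(ncol(H) == length(pos))
    counts <- as.integer(colSums(H))
  } else if (is.null(counts)) {
    stop("counts are required when H is NULL", call. = FALSE)
  }
  counts <- as.integer(counts)
  if (!allow_monomorphic && length(counts) &&
      (min(counts) <= 0 || max(counts) >= n_hap)) {
    stop("panel must not contain monomorphic sites", call. = FALSE)
  }
  structure(list(H = H, pos = pos, counts = counts,
                 n_hap = as.integer(n_hap),
                 region_length = as.numeric(region_length)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "Haplotype panel: %d haplotypes, %d segregating sites over %.3g bp%s\n",
    x$n_hap, length(x$pos), x$region_length,
    if (is.null(x$H)) " (counts only)" else ""))
  invisible(x)
}

#' Number of diploid individuals in a panel
#' @param panel A [haplotype_panel()].
#' @export
n_individuals <- function(panel) panel$n_hap %/% 2L

#' Diploid genotype matrix of a panel
#'
#' Collapses consecutive haplotype pairs (1,2), (3,4), ... into diploid
#' derived-allele counts in \{0, 1, 2\}.
#'
#' @param panel A [haplotype_panel()] with genotypes.
#' @param individuals Optional individual indices to extract.
#' @return n_individuals x n_sites integer matrix.
#' @export
diploid_genotypes <- function(panel, individuals = NULL) {
  if (is.null(panel$H)) stop("panel carries no genotypes", call. = FALSE)
  idx <- individuals %||% seq_len(n_individuals(panel))
  panel$H[2L * idx - 1L, , drop = FALSE] + panel$H[2L * idx, , drop = FALSE]
}

#' Restrict a panel to a subset of individuals
#' @param panel A [haplotype_panel()] with genotypes.
#' @param individuals Individual indices to keep.
#' @param drop_monomorphic Drop sites monomorphic in the subset.
#' @return A [haplotype_panel()] (with a `site_map` attribute giving, for
#'   each retained site, its column index in the parent panel).
#' @export
subset_panel <- function(panel, individuals, drop_monomorphic = TRUE) {
  if (is.null(panel$H)) stop("panel carries no genotypes", call. = FALSE)
  hap <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  H <- panel$H[hap, , drop = FALSE]
  keep <- seq_along(panel$pos)
  if (drop_monomorphic) {
    cs <- colSums(H)
    keep <- which(cs > 0 & cs < nrow(H))
  }
  out <- haplotype_panel(H[, keep, drop = FALSE], panel$pos[keep],
                         panel$region_length,
                         allow_monomorphic = !drop_monomorphic)
  attr(out, "site_map") <- keep
  out
}

# ---- msprime bridge ---------------------------------------------------------

python_backend <- function() {
  exe <- Sys.getenv("RVPOWER_PYTHON", "python")
  if (Sys.which(exe) == "") {
    stop("python executable not found; the coalescent backend requires ",
         "python with msprime on the PATH (or set RVPOWER_PYTHON)",
         call. = FALSE)
  }
  exe
}

model_to_json <- function(model) {
  pops <- lapply(seq_len(nrow(model$populations)), function(i) {
    p <- model$populations[i, ]
    list(name = p$name, size = p$size, growth = p$growth)
  })
  evs <- if (!is.null(model$events)) {
    lapply(seq_len(nrow(model$events)), function(i) {
      e <- model$events[i, ]
      out <- list(time = e$time, population = e$population)
      if (!is.na(e$size)) out$size <- e$size
      if (!is.na(e$growth)) out$growth <- e$growth
      out
    })
  } else {
    list()
  }
  sps <- if (!is.null(model$splits)) {
    lapply(seq_len(nrow(model$splits)), function(i) {
      s <- model$splits[i, ]
      list(time = s$time, derived = s$derived, ancestral = s$ancestral)
    })
  } else {
    list()
  }
  mgs <- if (!is.null(model$migrations)) {
    lapply(seq_len(nrow(model$migrations)), function(i) {
      m <- model$migrations[i, ]
      list(time = m$time, rate = m$rate, from = m$from, to = m$to)
    })
  } else {
    list()
  }
  list(populations = pops, events = evs, splits = sps, migrations = mgs)
}

run_neutral_backend <- function(model, region_length, mu, rmap, n_samples,
                                population, seed, n_reps, genotypes) {
  stopifnot(n_samples >= 2, mu >= 0, seed == round(seed))
  script <- system.file("python", "neutral_sim.py", package = "rvpower",
                        mustWork = TRUE)
  out_path <- tempfile("neutral_", fileext = ".txt")
  job_path <- tempfile("neutral_job_", fileext = ".json")
  on.exit(unlink(c(out_path, job_path)), add = TRUE)
  rec <- if (length(rmap$rates) == 1L) {
    list(rate = rmap$rates)
  } else {
    list(positions = rmap$starts, rates = rmap$rates)
  }
  samples <- stats::setNames(list(n_samples), population)
  job <- list(demography = model_to_json(model),
              region_length = region_length, mu = mu, recomb = rec,
              samples = samples, seed = seed, n_reps = n_reps,
              genotypes = genotypes, out = out_path)
  jsonlite::write_json(job, job_path, auto_unbox = TRUE, digits = NA)
  status <- system2(python_backend(), c(script, shQuote(job_path)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status"))) {
    stop("coalescent backend failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  parse_backend_output(out_path, genotypes)
}

parse_backend_output <- function(path, genotypes) {
  lines <- readLines(path)
  hdr <- grep("^#REP ", lines)
  reps <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    meta <- strsplit(lines[hdr[i]], " ", fixed = TRUE)[[1]]
    n_hap <- as.integer(meta[3])
    body <- if (bounds[i + 1L] - hdr[i] > 1L) {
      lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    } else {
      character(0)
    }
    if (!length(body)) {
      reps[[i]] <- list(pos = numeric(0), counts = integer(0),
                        H = if (genotypes) {
                          matrix(0L, n_hap, 0)
                        },
                        n_hap = n_hap,
                        region_length = as.numeric(meta[4]))
      next
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    pos <- as.numeric(vapply(fields, `[[`, "", 1L))
    counts <- as.integer(vapply(fields, `[[`, "", 2L))
    H <- NULL
    if (genotypes) {
      geno <- vapply(fields, `[[`, "", 3L)
      H <- matrix(as.integer(charToRaw(paste(geno, collapse = ""))) - 48L,
                  nrow = n_hap)
    }
    reps[[i]] <- list(pos = pos, counts = counts, H = H, n_hap = n_hap,
                      region_length = as.numeric(meta[4]))
  }
  reps
}

#' Simulate a neutral haplotype panel under a demographic model
#'
#' Runs the coalescent backend (msprime, through the bundled Python
#' bridge) to generate phased neutral haplotypes for one deme of a
#' demographic model.  Monomorphic sites are never emitted.
#'
#' @param model A [demographic_model()].
#' @param region_length Region length in bp.
#' @param mu Per-bp per-generation mutation rate.
#' @param rmap A [recomb_map()]; defaults to a uniform 1e-8/bp map.
#' @param n_samples Number of diploid individuals to sample.
#' @param population Deme to sample from.
#' @param seed Integer random seed (deterministic output).
#' @return A [haplotype_panel()] with `2 * n_samples` haplotypes.
#' @examples
#' \dontrun{
#' panel <- simulate_neutral_panel(tennessen_model(), 1e5, 1e-8,
#'                                 n_samples = 100, seed = 1)
#' }
#' @export
simulate_neutral_panel <- function(model, region_length, mu,
                                   rmap = uniform_recomb_map(region_length),
                                   n_samples, population = "AFR", seed) {
  rep1 <- run_neutral_backend(model, region_length, mu, rmap, n_samples,
                              population, seed, n_reps = 1L,
                              genotypes = TRUE)[[1]]
  H <- rep1$H %||% matrix(0L, 2L * n_samples, 0L)
  haplotype_panel(H, rep1$pos, region_length)
}

#' Simulate neutral derived-allele counts (no genotype matrix)
#'
#' Replicated coalescent simulations returning only per-site derived
#' allele counts, for site-frequency-spectrum estimation at sample sizes
#' where genotype matrices would be prohibitively large.
#'
#' @inheritParams simulate_neutral_panel
#' @param n_reps Number of independent replicate regions.
#' @return List of integer count vectors, one per replicate; each carries
#'   the number of sampled chromosomes in attribute `n_chrom`.
#' @export
simulate_neutral_counts <- function(model, region_length, mu,
                                    rmap = uniform_recomb_map(region_length),
                                    n_samples, population = "AFR", seed,
                                    n_reps = 1L) {
  reps <- run_neutral_backend(model, region_length, mu, rmap, n_samples,
                              population, seed, n_reps = n_reps,
                              genotypes = FALSE)
  lapply(reps, function(r) structure(r$counts, n_chrom = r$n_hap))
}

# ---- SFS and projection -----------------------------------------------------

# Frequency-class binning shared by the SFS and the conditional
# mean-squared-effect estimator: one bin per distinct derived count up to
# `exact_max` copies, log-spaced bins above.
count_bins <- function(n_chrom, exact_max = 100L, n_log = 40L) {
  exact_max <- min(exact_max, n_chrom - 1L)
  edges <- seq(0.5, exact_max + 0.5, by = 1)
  if (n_chrom - 1L > exact_max) {
    hi <- exp(seq(log(exact_max + 0.5), log(n_chrom - 0.5),
                  length.out = n_log + 1L))[-1]
    edges <- c(edges, hi)
  }
  edges
}

#' Site frequency spectrum
#'
#' Bins per-site derived allele counts into frequency classes and returns
#' the proportion of variants per class.  The default binning keeps one
#' class per distinct count up to 100 copies and log-spaced classes above,
#' which preserves full resolution where rare-variant quantities are
#' computed.  Raw counts are retained in the object so downstream variance
#' partitioning can work at site resolution.
#'
#' @param counts Per-variant derived allele counts (all in
#'   `(0, n_chromosomes)`).
#' @param n_chromosomes Number of sampled chromosomes.
#' @param bins Optional numeric vector of bin edges on the count scale.
#' @return An object of class `sfs` with fields `edges`, `prop` (summing
#'   to 1), `y_mean` (mean derived frequency per occupied class), `counts`
#'   and `n_chrom`.
#' @export
compute_sfs <- function(counts, n_chromosomes, bins = NULL) {
  counts <- as.integer(counts)
  if (!length(counts)) stop("empty count vector", call. = FALSE)
  if (min(counts) <= 0 || max(counts) >= n_chromosomes) {
    stop("counts must lie strictly between 0 and n_chromosomes",
         call. = FALSE)
  }
  edges <- bins %||% count_bins(n_chromosomes)
  cls <- findInterval(counts, edges, rightmost.closed = TRUE)
  tab <- tabulate(cls, nbins = length(edges) - 1L)
  y_mean <- vapply(seq_along(tab), function(b) {
    if (tab[b] == 0) return(NA_real_)
    mean(counts[cls == b]) / n_chromosomes
  }, 0)
  structure(list(edges = edges, prop = tab / length(counts),
                 y_mean = y_mean, counts = counts,
                 n_chrom = as.integer(n_chromosomes)),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf(
    "SFS: %d variants in %d chromosomes, %d frequency classes (singleton fraction %.3f)\n",
    length(x$counts), x$n_chrom, length(x$prop), mean(x$counts == 1L)))
  invisible(x)
}

#' Project a fitness-variant table to a smaller sample size
#'
#' Replaces each derived allele count `c` out of `n` chromosomes by a
#' draw from Binomial(`n_target`, `c / n`), the standard hypergeometric-
#' approximating downsampling of a frequency table.  Projection to the
#' table's own size is the identity.
#'
#' @param table A [fitness_variant_table()].
#' @param n_target Target number of chromosomes (`<= n_chrom` of table).
#' @param drop_monomorphic Remove rows projected to 0 or `n_target`.
#' @param seed Optional integer seed.
#' @return A [fitness_variant_table()] at `n_target` chromosomes.
#' @export
project_counts <- function(table, n_target, drop_monomorphic = TRUE,
                           seed = NULL) {
  n_target <- as.integer(n_target)
  if (n_target <= 0) stop("n_target must be positive", call. = FALSE)
  n_from <- unique(table$n_chrom)
  stopifnot(length(n_from) == 1L)
  if (n_target > n_from) {
    stop("n_target exceeds the table's chromosome count", call. = FALSE)
  }
  if (n_target == n_from) return(table)
  cnt <- with_seed(seed, rbinom(nrow(table), n_target, table$count / n_from))
  out <- data.frame(s = table$s, count = cnt, n_chrom = n_target)
  if (drop_monomorphic) out <- out[out$count > 0 & out$count < n_target, ]
  rownames(out) <- NULL
  as_fitness_table(out, attr(table, "meta"))
}

# ---- VCF / TSV interchange --------------------------------------------------

#' Write a haplotype panel to a phased VCF
#'
#' Plain-text VCF 4.2 with the ancestral allele as REF, derived as ALT and
#' phased GT fields; one diploid sample per consecutive haplotype pair.
#' Positions are converted to the VCF's 1-based convention.
#'
#' @param panel A [haplotype_panel()] with genotypes.
#' @param path Output file path.
#' @param chrom Chromosome label to write.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, chrom = "1") {
  if (is.null(panel$H)) stop("panel carries no genotypes", call. = FALSE)
  n_ind <- n_individuals(panel)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom,
                   as.integer(panel$region_length)),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ind", seq_len(n_ind))),
                 collapse = "\t"))
  gt <- matrix(paste(panel$H[seq(1, panel$n_hap, 2), , drop = FALSE],
                     panel$H[seq(2, panel$n_hap, 2), , drop = FALSE],
                     sep = "|"),
               nrow = n_ind)
  rows <- vapply(seq_along(panel$pos), function(j) {
    paste(c(chrom, format(panel$pos[j] + 1, scientific = FALSE), ".",
            "A", "T", ".", "PASS", "AA=A", "GT", gt[, j]),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires the `vcfR` package.  All genotypes must be phased and
#' biallelic; REF is taken as the ancestral allele.
#'
#' @param path VCF file path.
#' @param region_length Region length in bp (defaults to the contig length
#'   declared in the header, if present).
#' @return A [haplotype_panel()].
#' @export
read_panel_vcf <- function(path, region_length = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_panel_vcf requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotypes in VCF", call. = FALSE)
  }
  pos <- as.numeric(vcfR::getPOS(v)) - 1
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  n_ind <- ncol(gt)
  H <- matrix(0L, 2L * n_ind, nrow(gt))
  H[seq(1, 2 * n_ind, 2), ] <- t(a1)
  H[seq(2, 2 * n_ind, 2), ] <- t(a2)
  if (is.null(region_length)) {
    m <- regmatches(v@meta, regexec("length=([0-9]+)", v@meta))
    len <- suppressWarnings(as.numeric(vapply(
      m, function(x) if (length(x) == 2) x[2] else NA_character_, "")))
    region_length <- if (any(!is.na(len))) max(len, na.rm = TRUE) else
      max(pos) + 1
  }
  haplotype_panel(H, pos, region_length)
}
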