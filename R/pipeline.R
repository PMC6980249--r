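#' Experiment configuration
#'
#' Builds (and validates) the full configuration of a power experiment:
#' the simulated region, demography, DFE, the genetic-architecture grid,
#' the study-design grid and replication settings.  Configurations can be
#' written to / read from YAML; a stable hash of the configuration is
#' recorded in every output for provenance.
#'
#' @param region list(length, mu, n_population, population); region
#'   length in bp, per-bp mutation rate, number of simulated diploid
#'   individuals in the source population and the sampled deme.
#' @param demography A [demographic_model()].
#' @param dfe A [dfe_params()].
#' @param pool list(n_loci, locus_length, n_individuals, rescale)
#'   controlling the functional-variant pool simulation.
#' @param architectures data.frame grid with columns `rho`, `tau`, `h2`,
#'   `n_causal_loci` (a prevalence column is optional).
#' @param designs data.frame grid with columns `strategy`, `n_total` and
#'   optionally `data_mode` (`"sequence"` or `"array_impute"`) and
#'   `n_reference` (imputation reference-panel individuals).
#' @param tests Character vector of tests for [run_blocks()].
#' @param prevalence Trait prevalence.
#' @param block_size Analysis (and causal) block size in bp.
#' @param rare_maf Rare-variant MAF threshold.
#' @param alphas Named significance thresholds (see [estimate_power()]).
#' @param n_replicates Replicates per grid cell.
#' @param seed Master seed; all per-cell streams derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(region, demography = tennessen_model(),
                              dfe = dfe_params(),
                              pool = list(n_loci = 200,
                                          locus_length = 1e5,
                                          n_individuals = 1e5,
                                          rescale = 100),
                              architectures,
                              designs,
                              tests = c("SKATO", "GWAS"),
                              prevalence = 0.25,
                              block_size = 1e4,
                              rare_maf = 0.01,
                              alphas = c(SKAT = 2.5e-6, SKATO = 2.5e-6,
                                         KBAC = 2.5e-6,
                                         `GWAS-min` = 5e-8),
                              n_replicates = 10,
                              seed = 1L) {
  stopifnot(nrow(architectures) >= 1, nrow(designs) >= 1)
  if (is.null(designs$data_mode)) designs$data_mode <- "sequence"
  if (is.null(designs$n_reference)) designs$n_reference <- 0L
  cfg <- structure(list(region = region, demography = demography,
                        dfe = dfe, pool = pool,
                        architectures = architectures, designs = designs,
                        tests = tests, prevalence = prevalence,
                        block_size = block_size, rare_maf = rare_maf,
                        alphas = alphas,
                        n_replicates = as.integer(n_replicates),
                        seed = as.integer(seed)),
                   class = "experiment_config")
  cfg
}

# canonical plain-list representation shared by the YAML writer and the
# configuration hash
config_obj <- function(config) {
  dem <- config$demography
  num_df <- function(d) {
    if (is.null(d)) return(NULL)
    d[] <- lapply(d, function(col) if (is.numeric(col)) as.numeric(col)
                  else as.character(col))
    d
  }
  list(
    region = lapply(config$region, function(x)
      if (is.numeric(x)) as.numeric(x) else x),
    demography = list(populations = num_df(dem$populations),
                      events = num_df(dem$events),
                      splits = num_df(dem$splits),
                      migrations = num_df(dem$migrations)),
    dfe = list(shape = config$dfe$shape, mean = config$dfe$mean),
    pool = lapply(config$pool, as.numeric),
    architecture = num_df(config$architectures),
    designs = num_df(config$designs),
    tests = as.character(config$tests),
    prevalence = as.numeric(config$prevalence),
    block_size = as.numeric(config$block_size),
    rare_maf = as.numeric(config$rare_maf),
    alphas = lapply(as.list(config$alphas), as.numeric),
    n_replicates = as.numeric(config$n_replicates),
    seed = as.numeric(config$seed))
}

#' Stable hash of a configuration
#' @param config An [experiment_config()].
#' @return Integer hash of the canonical (YAML) representation; invariant
#'   under a YAML round trip.
#' @export
config_hash <- function(config) {
  derive_seed(1L, yaml::as.yaml(config_obj(config), column.major = FALSE))
}

#' Read / write an experiment configuration as YAML
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config_obj(config), path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  as_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(row) as.data.frame(row)))
  dem <- demographic_model(populations = as_df(obj$demography$populations),
                           events = as_df(obj$demography$events),
                           splits = as_df(obj$demography$splits),
                           migrations = as_df(obj$demography$migrations))
  experiment_config(
    region = obj$region, demography = dem,
    dfe = dfe_params(obj$dfe$shape, obj$dfe$mean),
    pool = obj$pool,
    architectures = as_df(obj$architecture),
    designs = as_df(obj$designs),
    tests = unlist(obj$tests), prevalence = obj$prevalence,
    block_size = obj$block_size, rare_maf = obj$rare_maf,
    alphas = unlist(obj$alphas),
    n_replicates = obj$n_replicates, seed = obj$seed)
}

#' Bundled experiment scales
#'
#' Ready-made configurations at three scales: `smoke` (1 Mb, 2,000
#' individuals, 2 architectures, minutes), `desk` (2 Mb, 10,000
#' individuals, reduced grid) and `full` (the 5 Mb / 50,000-individual
#' grid with all architectures and designs).
#'
#' @param scale One of `"smoke"`, `"desk"`, `"full"`.
#' @param seed Master seed.
#' @return An [experiment_config()].
#' @export
make_fixture <- function(scale = c("smoke", "desk", "full"), seed = 1L) {
  scale <- match.arg(scale)
  arch_full <- expand.grid(rho = c(0.5, 0.8, 0.9, 1.0),
                           tau = c(0.5, 1.0),
                           h2 = c(0.2, 0.8),
                           n_causal_loci = c(10L, 100L))
  designs_full <- expand.grid(strategy = c("random", "fifty_fifty",
                                           "extremes"),
                              n_total = c(5000L, 10000L),
                              data_mode = c("sequence", "array_impute"),
                              n_reference = 10000L,
                              stringsAsFactors = FALSE)
  switch(scale,
    smoke = experiment_config(
      region = list(length = 1e6, mu = 1e-8, n_population = 2000L,
                    population = "AFR"),
      pool = list(n_loci = 40, locus_length = 5e4, n_individuals = 2000L,
                  rescale = 100),
      architectures = data.frame(rho = c(1, 0.5), tau = c(1, 0.5),
                                 h2 = 0.8, n_causal_loci = 10L),
      designs = data.frame(strategy = c("extremes", "random"),
                           n_total = 500L, data_mode = "sequence",
                           n_reference = 0L),
      n_replicates = 2, seed = seed),
    desk = experiment_config(
      region = list(length = 2e6, mu = 1e-8, n_population = 10000L,
                    population = "AFR"),
      pool = list(n_loci = 200, locus_length = 1e5,
                  n_individuals = 10000L, rescale = 100),
      architectures = expand.grid(rho = c(0.5, 1.0), tau = c(0.5, 1.0),
                                  h2 = 0.8, n_causal_loci = 20L),
      designs = expand.grid(strategy = c("random", "fifty_fifty",
                                         "extremes"),
                            n_total = 2000L, data_mode = "sequence",
                            n_reference = 0L, stringsAsFactors = FALSE),
      n_replicates = 10, seed = seed),
    full = experiment_config(
      region = list(length = 5e6, mu = 1e-8, n_population = 50000L,
                    population = "AFR"),
      pool = list(n_loci = 2000, locus_length = 1e5,
                  n_individuals = 1e5, rescale = 100),
      architectures = arch_full,
      designs = designs_full,
      tests = c("SKAT", "SKATO", "KBAC", "GWAS"),
      n_replicates = 10, seed = seed))
}

#' Run a full power experiment
#'
#' Executes simulate -> phenotype -> cohort -> (array/impute) -> test ->
#' power for every cell of the architecture x design grid, with per-cell
#' seeds derived deterministically from the master seed.  Stage failures
#' are caught and recorded per cell; the run continues.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory for summary TSVs (created if missing);
#'   `NULL` skips writing.
#' @param dry_run Print the cell manifest and return it without
#'   computing.
#' @param verbose Progress messages.
#' @return data.frame of per-cell power summaries (one row per cell x
#'   test), with failed cells flagged in `status`.
#' @export
run_experiment <- function(config, out_dir = NULL, dry_run = FALSE,
                           verbose = interactive()) {
  arch <- config$architectures
  des <- config$designs
  cells <- expand.grid(arch_id = seq_len(nrow(arch)),
                       design_id = seq_len(nrow(des)))
  manifest <- cbind(cells,
                    arch[cells$arch_id, , drop = FALSE],
                    des[cells$design_id, , drop = FALSE])
  rownames(manifest) <- NULL
  if (dry_run) {
    print(manifest)
    return(invisible(manifest))
  }
  hash <- config_hash(config)

  # one functional pool for the whole experiment
  pool_seed <- derive_seed(config$seed, "pool")
  pool_full <- simulate_fitness_table(
    config$demography, config$dfe, n_loci = config$pool$n_loci,
    locus_length = config$pool$locus_length,
    n_individuals = config$pool$n_individuals,
    rescale = config$pool$rescale, mu = config$region$mu,
    population = config$region$population, seed = pool_seed)

  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    a <- arch[cells$arch_id[ci], ]
    d <- des[cells$design_id[ci], ]
    cell_key <- paste("cell", cells$arch_id[ci], cells$design_id[ci])
    params <- architecture_params(a$rho, a$tau, a$h2, a$n_causal_loci,
                                  a$prevalence %||% config$prevalence)
    reps <- vector("list", config$n_replicates)
    causal_ref <- NULL
    status <- "ok"
    for (r in seq_len(config$n_replicates)) {
      res <- tryCatch({
        run_experiment_cell(config, pool_full, params, d,
                            derive_seed(config$seed, cell_key, r))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        status <- paste0("failed: ", conditionMessage(res))
        break
      }
      reps[[r]] <- res$results
      causal_ref <- c(causal_ref, list(res$causal_blocks))
    }
    if (status == "ok") {
      # power over replicates; causal blocks differ per replicate, so
      # aggregate per replicate and average the Bernoulli trials jointly
      tab <- do.call(rbind, lapply(seq_along(reps), function(r) {
        s <- estimate_power(reps[[r]], causal_ref[[r]],
                            alpha = config$alphas)
        s$replicate <- r
        s
      }))
      agg <- do.call(rbind, lapply(split(tab, tab$test), function(tt) {
        m_c <- sum(tt$n_causal_trials)
        m_f <- sum(tt$n_null_trials)
        pw <- sum(tt$power * tt$n_causal_trials) / max(m_c, 1)
        fp <- sum(tt$fpr * tt$n_null_trials, na.rm = TRUE) / max(m_f, 1)
        data.frame(test = tt$test[1], power = pw,
                   power_se = sqrt(pw * (1 - pw) / max(m_c, 1)),
                   fpr = fp, n_causal_trials = m_c, n_null_trials = m_f)
      }))
      rownames(agg) <- NULL
    } else {
      agg <- data.frame(test = NA_character_, power = NA_real_,
                        power_se = NA_real_, fpr = NA_real_,
                        n_causal_trials = 0L, n_null_trials = 0L)
    }
    agg$rho <- a$rho; agg$tau <- a$tau; agg$h2 <- a$h2
    agg$n_causal_loci <- a$n_causal_loci
    agg$strategy <- d$strategy; agg$n_total <- d$n_total
    agg$data_mode <- d$data_mode
    agg$status <- status
    agg$config_hash <- hash
    rows[[ci]] <- agg
    if (verbose) {
      message(sprintf("[%d/%d] %s %s rho=%.2g tau=%.2g: %s",
                      ci, nrow(cells), d$strategy, d$data_mode,
                      a$rho, a$tau, status))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(out_dir, "power_overview.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_config_yaml(config, file.path(out_dir, "config.yaml"))
  }
  out
}

# One replicate of one grid cell: panel -> effects -> trait -> cohort ->
# (array/impute) -> block tests.
run_experiment_cell <- function(config, pool_full, params, design, seed) {
  reg <- config$region
  panel <- simulate_neutral_panel(
    config$demography, reg$length, reg$mu,
    n_samples = reg$n_population, population = reg$population,
    seed = derive_seed(seed, "panel"))
  pool <- project_counts(pool_full, panel$n_hap,
                         seed = derive_seed(seed, "project"))
  effects <- assign_effects(panel, pool, params,
                            block_size = config$block_size,
                            seed = derive_seed(seed, "effects"))
  trait <- simulate_trait(panel, effects, params$h2,
                          seed = derive_seed(seed, "trait"))
  spec <- cohort_spec(design$strategy, design$n_total,
                      prevalence = params$prevalence,
                      seed = derive_seed(seed, "cohort"))
  cohort <- sample_cohort(trait, spec)

  data <- if (identical(design$data_mode, "array_impute")) {
    typed_all <- downsample_to_array(panel, build_manifest_fixture(),
                                     seed = derive_seed(seed, "array"))
    remaining <- setdiff(seq_len(n_individuals(panel)), cohort$indiv)
    n_ref <- min(design$n_reference %||% length(remaining),
                 length(remaining))
    ref_ind <- with_seed(derive_seed(seed, "refpanel"),
                         sample(remaining, n_ref))
    reference <- subset_panel(panel, ref_ind, drop_monomorphic = FALSE)
    typed <- typed_for_individuals(typed_all, cohort$indiv)
    impute(typed, reference, seed = derive_seed(seed, "impute"))
  } else {
    panel
  }
  results <- run_blocks(data, cohort, tests = config$tests,
                        block_size = config$block_size,
                        rare_maf = config$rare_maf,
                        seed = derive_seed(seed, "assoc"))
  list(results = results,
       causal_blocks = attr(effects, "causal_blocks")$block)
}
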