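#' Case/control sampling specification
#'
#' @param strategy One of `"random"`, `"fifty_fifty"`, `"extremes"`.
#'   Random draws cases in proportion to the prevalence; 50/50 draws equal
#'   numbers of cases and controls; extremes takes the top and bottom
#'   tails of the quantitative phenotype (ignoring prevalence).
#' @param n_total Total cohort size (even for `fifty_fifty`/`extremes`).
#' @param prevalence Trait prevalence (used by `random`/`fifty_fifty`).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(strategy = c("random", "fifty_fifty", "extremes"),
                        n_total, prevalence = 0.25, seed = NULL) {
  strategy <- match.arg(strategy)
  n_total <- as.integer(n_total)
  if (strategy != "random" && n_total %% 2L != 0L) {
    stop("n_total must be even for the ", strategy, " strategy",
         call. = FALSE)
  }
  structure(list(strategy = strategy, n_total = n_total,
                 prevalence = prevalence, seed = seed),
            class = "cohort_spec")
}

#' Sample a case/control cohort from a dichotomized population
#'
#' Implements the three sampling strategies on a simulated quantitative
#' trait.  `extremes` selects the `n/2` highest-phenotype individuals as
#' cases and the `n/2` lowest as controls (ties broken by index).
#' `fifty_fifty` samples `n/2` uniformly without replacement from the
#' prevalence-defined case population and `n/2` from the controls.
#' `random` samples `round(n * prevalence)` cases and the rest controls.
#'
#' @param trait A [quant_trait()][simulate_trait].
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: data frame with columns `indiv`,
#'   `Y`, `case` (1 = case), ordered by individual index; the strategy is
#'   recorded in attribute `strategy`.
#' @export
sample_cohort <- function(trait, spec) {
  n_pop <- nrow(trait)
  n <- spec$n_total
  if (n > n_pop) stop("cohort larger than the population", call. = FALSE)
  out <- with_seed(spec$seed, {
    if (spec$strategy == "extremes") {
      cases <- order(-trait$Y, trait$indiv)[seq_len(n %/% 2L)]
      controls <- order(trait$Y, trait$indiv)[seq_len(n %/% 2L)]
      data.frame(indiv = c(cases, controls),
                 case = rep(1:0, each = n %/% 2L))
    } else {
      lab <- dichotomize(trait, spec$prevalence)
      pool_case <- which(lab == 1L)
      pool_ctrl <- which(lab == 0L)
      k <- if (spec$strategy == "fifty_fifty") {
        n %/% 2L
      } else {
        as.integer(round(n * spec$prevalence))
      }
      if (k > length(pool_case) || (n - k) > length(pool_ctrl)) {
        stop("requested more cases or controls than the population holds",
             call. = FALSE)
      }
      data.frame(
        indiv = c(pool_case[sample.int(length(pool_case), k)],
                  pool_ctrl[sample.int(length(pool_ctrl), n - k)]),
        case = rep(1:0, c(k, n - k)))
    }
  })
  if (anyDuplicated(out$indiv)) {
    stop("internal error: duplicated individuals in cohort")   # nocov
  }
  ord <- order(out$indiv)
  structure(data.frame(indiv = out$indiv[ord],
                       Y = trait$Y[out$indiv[ord]],
                       case = out$case[ord]),
            class = c("cohort", "data.frame"),
            strategy = spec$strategy)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort (%s): %d cases / %d controls\n",
              attr(x, "strategy"), sum(x$case == 1L), sum(x$case == 0L)))
  invisible(x)
}

#' Write a cohort as TSV
#' @param cohort A [cohort][sample_cohort].
#' @param path File path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  df <- data.frame(indiv = cohort$indiv, Y = cohort$Y,
                   case_control = cohort$case)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
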