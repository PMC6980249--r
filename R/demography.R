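#' Two-deme demographic model
#'
#' Container describing piecewise-exponential population size histories for
#' two demes plus split and migration events, in the parameterisation used
#' by coalescent simulators: `populations` gives the present-day state of
#' each deme, `events` change size and/or growth rate going back in time,
#' `splits` merge a derived deme into its ancestor, and `migrations` set
#' (backwards-time) migration rates from a given time onwards.  All times
#' are in generations before present; sizes are diploid effective sizes.
#'
#' @param populations data.frame with columns `name`, `size`, `growth`.
#' @param events data.frame with columns `time`, `population`, `size`,
#'   `growth` (`NA` leaves the corresponding parameter unchanged).
#' @param splits data.frame with columns `time`, `derived`, `ancestral`.
#' @param migrations data.frame with columns `time`, `rate`, `from`, `to`;
#'   `time = 0` rows set the present-day rate.
#' @return An object of class `demographic_model`.
#' @seealso [tennessen_model()] for the bundled out-of-Africa history.
#' @export
demographic_model <- function(populations,
                              events = NULL,
                              splits = NULL,
                              migrations = NULL) {
  stopifnot(is.data.frame(populations),
            all(c("name", "size", "growth") %in% names(populations)))
  if (any(populations$size <= 0)) {
    stop("population sizes must be positive", call. = FALSE)
  }
  if (!is.null(events)) {
    if (any(events$time < 0)) stop("event times must be >= 0", call. = FALSE)
    if (any(!is.na(events$size) & events$size <= 0)) {
      stop("population sizes must be positive", call. = FALSE)
    }
  }
  if (!is.null(migrations) &&
      any(migrations$rate < 0 | migrations$rate >= 1)) {
    stop("migration rates must lie in [0, 1)", call. = FALSE)
  }
  structure(list(populations = populations,
                 events = events,
                 splits = splits,
                 migrations = migrations),
            class = "demographic_model")
}

#' Out-of-Africa demographic history (African and European demes)
#'
#' The bundled two-population history of African and European demes: an
#' ancestral population that expands in the deep past, an out-of-Africa
#' bottleneck followed by a second (founding-of-Europe) bottleneck,
#' super-exponential recent growth in Europe, recent exponential growth in
#' Africa, and bidirectional migration throughout.  Default parameter
#' values follow the widely used calibration of this model (sizes in
#' diploids, times in generations, growth rates per generation); every
#' parameter can be overridden.
#'
#' @param n_africa,africa_growth Present-day African size and growth rate.
#' @param n_europe,europe_growth Present-day European size and growth rate.
#' @param t_growth Onset of recent explosive growth in both demes.
#' @param n_africa_old African size before recent growth.
#' @param n_europe_old,europe_growth_old European size/growth between the
#'   second bottleneck and recent growth.
#' @param t_bottleneck2 Time of the second European bottleneck.
#' @param n_bottleneck Size of the out-of-Africa bottleneck population.
#' @param t_split Time of the out-of-Africa split.
#' @param t_expand,n_ancestral Ancient African expansion time and the
#'   ancestral size before it.
#' @param m_recent,m_old Bidirectional migration rates after/before the
#'   second bottleneck.
#' @return A [demographic_model()].
#' @export
tennessen_model <- function(n_africa = 424000, africa_growth = 0.0166,
                            n_europe = 512000, europe_growth = 0.0195,
                            t_growth = 204.6,
                            n_africa_old = 14474,
                            n_europe_old = 9300, europe_growth_old = 0.00307,
                            t_bottleneck2 = 920, n_bottleneck = 1861,
                            t_split = 2040,
                            t_expand = 5920, n_ancestral = 7310,
                            m_recent = 2.5e-5, m_old = 15e-5) {
  demographic_model(
    populations = data.frame(
      name = c("AFR", "EUR"),
      size = c(n_africa, n_europe),
      growth = c(africa_growth, europe_growth)),
    events = data.frame(
      time = c(t_growth, t_growth, t_bottleneck2, t_expand),
      population = c("AFR", "EUR", "EUR", "AFR"),
      size = c(n_africa_old, n_europe_old, n_bottleneck, n_ancestral),
      growth = c(0, europe_growth_old, 0, 0)),
    splits = data.frame(time = t_split, derived = "EUR", ancestral = "AFR"),
    migrations = data.frame(
      time = c(0, 0, t_bottleneck2, t_bottleneck2),
      rate = c(m_recent, m_recent, m_old, m_old),
      from = c("AFR", "EUR", "AFR", "EUR"),
      to = c("EUR", "AFR", "EUR", "AFR")))
}

#' Constant-size single-population model
#'
#' @param n Diploid effective population size.
#' @param name Deme name.
#' @return A [demographic_model()].
#' @export
constant_model <- function(n, name = "POP") {
  demographic_model(populations = data.frame(name = name, size = n,
                                             growth = 0))
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model:", nrow(x$populations), "deme(s)\n")
  for (i in seq_len(nrow(x$populations))) {
    p <- x$populations[i, ]
    cat(sprintf("  %s: present N = %g (growth %g/gen)\n",
                p$name, p$size, p$growth))
  }
  cat(" ", NROW(x$events), "size-change event(s),",
      NROW(x$splits), "split(s)\n")
  invisible(x)
}

# Piecewise size history N(t_ago) of a single deme, as step/exponential
# segments; used by the forward simulator.
deme_size_at <- function(model, deme, t_ago) {
  p <- model$populations[model$populations$name == deme, ]
  if (nrow(p) != 1) stop("unknown deme: ", deme, call. = FALSE)
  seg <- data.frame(time = 0, size = p$size, growth = p$growth)
  ev <- model$events
  if (!is.null(ev)) {
    ev <- ev[ev$population == deme, , drop = FALSE]
    if (nrow(ev)) {
      ev <- ev[order(ev$time), ]
      seg <- rbind(seg, data.frame(time = ev$time, size = ev$size,
                                   growth = ifelse(is.na(ev$growth), 0,
                                                   ev$growth)))
    }
  }
  i <- findInterval(t_ago, seg$time)
  pmax(seg$size[i] * exp(-seg$growth[i] * (t_ago - seg$time[i])), 2)
}

# Forward-in-time trajectory of rescaled diploid sizes for one deme:
# burn-in at the most ancient size followed by the model's history, with
# time compressed and sizes divided by `rescale`.  Element 1 is the most
# ancient generation, the last element is the present.
forward_size_trajectory <- function(model, deme, rescale = 100,
                                    burnin_factor = 10) {
  t_max <- max(c(0, model$events$time[model$events$population == deme]))
  n_hist <- ceiling(t_max / rescale)
  t_ago <- (n_hist:1 - 0.5) * rescale          # midpoint of each step
  n_traj <- round(deme_size_at(model, deme, t_ago) / rescale)
  n_anc <- round(deme_size_at(model, deme, t_max + rescale) / rescale)
  burnin <- rep(n_anc, burnin_factor * 2 * n_anc)
  traj <- c(burnin, n_traj,
            round(deme_size_at(model, deme, 0) / rescale))
  if (min(traj) < 50) {
    stop("rescaled population size drops below 50 diploids; ",
         "use a smaller rescale factor", call. = FALSE)
  }
  as.integer(traj)
}

#' Recombination map
#'
#' A piecewise-constant per-bp recombination rate map over `[0,
#' region_length)`.  Coordinates are 0-based and half-open.
#'
#' @param starts Integer vector of interval start positions; the first must
#'   be 0 and starts must be strictly increasing.
#' @param rates Per-bp per-generation recombination rate of each interval.
#' @param region_length Total length covered by the map.
#' @return An object of class `recomb_map`.
#' @export
recomb_map <- function(starts, rates, region_length) {
  stopifnot(length(starts) == length(rates))
  if (starts[1] != 0 || any(diff(starts) <= 0) ||
      any(starts >= region_length)) {
    stop("interval starts must begin at 0, increase strictly and tile ",
         "[0, region_length)", call. = FALSE)
  }
  if (any(rates < 0)) stop("recombination rates must be >= 0", call. = FALSE)
  structure(list(starts = as.numeric(starts), rates = as.numeric(rates),
                 region_length = as.numeric(region_length)),
            class = "recomb_map")
}

#' @rdname recomb_map
#' @param rate Uniform per-bp rate.
#' @export
uniform_recomb_map <- function(region_length, rate = 1e-8) {
  recomb_map(0, rate, region_length)
}

#' Bundled variable-rate recombination map
#'
#' A synthetic piecewise map emulating the rate heterogeneity (broad-scale
#' variation plus narrow hotspots) of a 5 Mb human chromosome-22 segment.
#' The mean rate is ~1e-8/bp.  Truncated or tiled to the requested region
#' length.
#'
#' @param region_length Region length in bp (default 5 Mb).
#' @return A [recomb_map()].
#' @export
chr22_like_map <- function(region_length = 5e6) {
  path <- system.file("extdata", "recomb_map_chr22like_synthetic.tsv",
                      package = "rvpower", mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t")
  keep <- tab$start < region_length
  recomb_map(tab$start[keep], tab$rate[keep], region_length)
}
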