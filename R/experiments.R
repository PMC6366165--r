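#' Study ranges of the five biological traits
#'
#' The trait box explored by the experiments: movement speed 1--5 cells per
#' step, perceptual range 1--5 cells, per-step mortality 0.0001--0.015 (the
#' single-trait sweep uses the five listed levels 0.0001, 0.001, 0.005,
#' 0.01, 0.015), minimum patch area 1--50 cells, foraging tendency 0--0.5.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
trait_ranges <- function() {
  list(speed = c(1, 5),
       perceptual_range = c(1, 5),
       mortality = c(0.0001, 0.015),
       min_area = c(1, 50),
       foraging_tendency = c(0, 0.5))
}

mortality_levels <- function() c(0.0001, 0.001, 0.005, 0.01, 0.015)

#' Baseline phenotype (centres of the trait ranges)
#'
#' Speed 3, perceptual range 3, mortality 0.005 (the middle listed level),
#' minimum patch area 25, foraging tendency 0.25.
#'
#' @return A [trait_set()].
#' @export
baseline_traits <- function() {
  trait_set(speed = 3, perceptual_range = 3, mortality = 0.005,
            min_area = 25, foraging_tendency = 0.25)
}

#' Broken-stick allocation of a unit budget
#'
#' Draws `k - 1` independent Uniform(0, 1) breakpoints, sorts them, and
#' returns the successive gaps: a uniform random partition of 1 into `k`
#' exchangeable shares, each with mean `1/k`.
#'
#' @param k Number of shares (default 5, one per biological trait).
#' @return Numeric vector of `k` non-negative shares summing to 1.
#' @export
broken_stick <- function(k = 5L) {
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  diff(c(0, sort(stats::runif(k - 1L)), 1))
}

#' Shannon diversity of an allocation
#'
#' Natural-log Shannon entropy `H = -sum(p * log(p))` with `0 * log(0) = 0`;
#' maximal (`log(5)` = 1.609 for five traits) when the budget is spread
#' evenly, 0 under full specialization.
#'
#' @param shares Non-negative shares (need not be normalized; they are
#'   scaled to sum to 1).
#' @return Entropy in nats.
#' @export
shannon_index <- function(shares) {
  if (any(shares < 0)) stop("shares must be non-negative", call. = FALSE)
  p <- shares / sum(shares)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Trait-investment allocation
#'
#' A point on the five-trait investment simplex, ordered (speed,
#' perceptual range, mortality-avoidance, minimum-area reduction,
#' foraging), with its Shannon index.
#'
#' @param shares Five non-negative fractions summing to 1.
#' @return An `allocation` list with `shares` (named) and `shannon`.
#' @export
allocation <- function(shares) {
  if (length(shares) != 5L)
    stop("an allocation has five shares", call. = FALSE)
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-9)
    stop("shares must be non-negative and sum to 1", call. = FALSE)
  names(shares) <- c("speed", "perceptual_range", "mortality",
                     "min_area", "foraging_tendency")
  structure(list(shares = shares, shannon = shannon_index(shares)),
            class = "allocation")
}

#' Map investment shares to trait values
#'
#' Linear map of each share onto its trait's study range in the beneficial
#' direction: investment raises speed, perceptual range and foraging
#' tendency, and lowers mortality (anti-predator adaptations) and the
#' minimum-area requirement:
#' `speed = 1 + 4u`, `range = 1 + 4u`, `mortality = 0.015 - 0.0149u`,
#' `min_area = 50 - 49u`, `foraging = 0.5u` (shares clamped to `[0, 1]`).
#'
#' @param alloc An [allocation()].
#' @return A [trait_set()].
#' @examples
#' shares_to_traits(allocation(rep(0.2, 5)))  # speed 1.8, min_area 40.2, ...
#' @export
shares_to_traits <- function(alloc) {
  stopifnot(inherits(alloc, "allocation"))
  u <- pmin(pmax(alloc$shares, 0), 1)
  rr <- trait_ranges()
  lin <- function(nm, beneficial_up) {
    r <- rr[[nm]]
    v <- if (beneficial_up) r[1] + (r[2] - r[1]) * u[[nm]]
         else r[2] - (r[2] - r[1]) * u[[nm]]
    min(max(v, r[1]), r[2])   # guard the endpoints against rounding
  }
  trait_set(speed = lin("speed", TRUE),
            perceptual_range = lin("perceptual_range", TRUE),
            mortality = lin("mortality", FALSE),
            min_area = lin("min_area", FALSE),
            foraging_tendency = lin("foraging_tendency", TRUE))
}

#' Latin hypercube design over the model parameter space
#'
#' Each dimension is stratified into `n_samples` equal-probability
#' intervals with one sample per interval (one random permutation of
#' strata, uniform jitter within each), then scaled to the parameter's
#' study range.  The full design varies the five traits plus habitat
#' amount (0.05--0.50) and aggregation (0--0.75); the trait-only design
#' fixes the two landscape parameters at the midpoints of their ranges
#' (0.275 and 0.375).
#'
#' @param n_samples Number of samples.
#' @param vary `"full"` (7 parameters) or `"traits"` (5 traits only).
#' @return An `lhs_design` list.
#' @export
lhs_design <- function(n_samples, vary = c("full", "traits")) {
  vary <- match.arg(vary)
  if (n_samples < 1L) stop("`n_samples` must be >= 1", call. = FALSE)
  ranges <- trait_ranges()
  if (vary == "full")
    ranges <- c(ranges, list(hab_amount = c(0.05, 0.5),
                             hab_agg = c(0, 0.75)))
  structure(list(n_samples = as.integer(n_samples), vary = vary,
                 ranges = ranges),
            class = "lhs_design")
}

#' Draw a Latin hypercube sample
#'
#' @param design An [lhs_design()].
#' @return Data frame (`n_samples` rows) with one column per varied
#'   parameter, scaled to the study ranges; the trait-only design also
#'   carries constant `hab_amount` and `hab_agg` columns at the range
#'   midpoints.
#' @export
lhs_sample <- function(design) {
  stopifnot(inherits(design, "lhs_design"))
  k <- length(design$ranges)
  u <- lhs::randomLHS(design$n_samples, k)
  out <- as.data.frame(mapply(function(col, r) r[1] + (r[2] - r[1]) * col,
                              as.data.frame(u), design$ranges,
                              SIMPLIFY = FALSE))
  names(out) <- names(design$ranges)
  if (design$vary == "traits") {
    out$hab_amount <- mean(c(0.05, 0.5))
    out$hab_agg <- mean(c(0, 0.75))
  }
  out
}

#' Run the Latin-hypercube exploration
#'
#' For each sampled parameter vector, generates a fresh landscape at the
#' sampled (amount, aggregation) and runs one cohort, recording the
#' dispersal success proportion.  All randomness derives from `seed` via
#' [seed_stream()], so rows are independent of execution order.
#'
#' @param design An [lhs_design()].
#' @param config A [sim_config()].
#' @param n_agents Agents per cohort (defaults to `config$cohort_size`).
#' @param seed Global seed.
#' @return Data frame: sampled parameters plus `n_success`, `n_died`,
#'   `n_timeout`, `success`.
#' @export
run_lhs_experiment <- function(design, config = sim_config(),
                               n_agents = config$cohort_size, seed = 1L) {
  samples <- with_seed(seed_stream(seed, 0L), lhs_sample(design))
  res <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    land <- generate_landscape(
      landscape_params(hab_amount = s$hab_amount, hab_agg = s$hab_agg),
      seed = seed_stream(seed, i, 1L))
    tr <- trait_set(speed = s$speed, perceptual_range = s$perceptual_range,
                    mortality = s$mortality, min_area = s$min_area,
                    foraging_tendency = s$foraging_tendency)
    co <- with_seed(seed_stream(seed, i, 2L),
                    run_cohort(land, tr, config, n = n_agents))
    c(n_success = co$n_success, n_died = co$n_died,
      n_timeout = co$n_timeout, success = co$success)
  })
  cbind(samples, do.call(rbind, res))
}

#' Single-trait sensitivity sweep design
#'
#' One trait is varied over five levels spanning its study range while the
#' other four are held at the baseline phenotype; every (habitat amount,
#' aggregation, trait value) cell is replicated on fresh landscapes.  The
#' full design uses 10 habitat amounts x 4 aggregations x 5 values = 200
#' cells at 100 replicates each.
#'
#' @param trait One of `"speed"`, `"perceptual_range"`, `"mortality"`,
#'   `"min_area"`, `"foraging_tendency"`.
#' @param hab_amounts Habitat amounts (default 0.05--0.50 by 0.05).
#' @param hab_aggs Aggregation levels (default 0, 0.25, 0.5, 0.75).
#' @param values Five trait levels (defaults span the study range; the
#'   mortality sweep uses its five listed levels).
#' @param replicates Cohorts per cell (default 100).
#' @param baseline Baseline [trait_set()] for the non-varied traits.
#' @return A `sweep_design` list.
#' @export
sweep_design <- function(trait = c("speed", "perceptual_range", "mortality",
                                   "min_area", "foraging_tendency"),
                         hab_amounts = seq(0.05, 0.50, by = 0.05),
                         hab_aggs = c(0, 0.25, 0.5, 0.75),
                         values = NULL, replicates = 100L,
                         baseline = baseline_traits()) {
  trait <- match.arg(trait)
  if (is.null(values)) {
    values <- if (trait == "mortality") mortality_levels()
              else seq(trait_ranges()[[trait]][1], trait_ranges()[[trait]][2],
                       length.out = 5)
  }
  structure(list(trait = trait, hab_amounts = hab_amounts,
                 hab_aggs = hab_aggs, values = values,
                 replicates = as.integer(replicates), baseline = baseline),
            class = "sweep_design")
}

#' Run a single-trait sensitivity sweep
#'
#' @param design A [sweep_design()].
#' @param config A [sim_config()].
#' @param n_agents Agents per cohort.
#' @param seed Global seed.
#' @return Data frame, one row per cohort: `trait`, `value`, `hab_amount`,
#'   `hab_agg`, `replicate`, `success` and the failure breakdown.
#' @export
run_sweep <- function(design, config = sim_config(),
                      n_agents = config$cohort_size, seed = 1L) {
  stopifnot(inherits(design, "sweep_design"))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      value = design$values,
                      hab_agg = design$hab_aggs,
                      hab_amount = design$hab_amounts,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    land <- generate_landscape(
      landscape_params(hab_amount = g$hab_amount, hab_agg = g$hab_agg),
      seed = seed_stream(seed, i, 1L))
    tr <- unclass(design$baseline)
    tr[[design$trait]] <- g$value
    tr <- do.call(trait_set, tr)
    co <- with_seed(seed_stream(seed, i, 2L),
                    run_cohort(land, tr, config, n = n_agents))
    c(n_success = co$n_success, n_died = co$n_died,
      n_timeout = co$n_timeout, success = co$success)
  })
  out <- cbind(data.frame(trait = design$trait), grid, do.call(rbind, res))
  out[, c("trait", "hab_amount", "hab_agg", "value", "replicate",
          "n_success", "n_died", "n_timeout", "success")]
}

#' Cell means of a sweep table
#'
#' Mean dispersal success per (habitat amount, aggregation, trait value)
#' cell; the full design yields 200 rows per trait.
#'
#' @param sweep_table Output of [run_sweep()].
#' @return Data frame of cell means.
#' @export
cell_means <- function(sweep_table) {
  out <- stats::aggregate(success ~ trait + hab_amount + hab_agg + value,
                          data = sweep_table, FUN = mean)
  out[order(out$hab_amount, out$hab_agg, out$value), , drop = FALSE]
}

#' Broken-stick trait-budget experiment design
#'
#' Each replicate draws a broken-stick allocation of the unit investment
#' budget over the five traits, maps it to a phenotype, and runs a cohort.
#' The study design uses 1000 allocations in landscapes of 5, 10, 15 and
#' 20 % habitat at aggregation 0.1 and 0.4 (eight landscapes).
#'
#' @param n_allocations Allocations per landscape (default 1000).
#' @param hab_amounts Habitat amounts (default 0.05, 0.10, 0.15, 0.20).
#' @param hab_aggs Aggregation levels (default 0.1, 0.4).
#' @return A `budget_design` list.
#' @export
budget_design <- function(n_allocations = 1000L,
                          hab_amounts = c(0.05, 0.10, 0.15, 0.20),
                          hab_aggs = c(0.1, 0.4)) {
  structure(list(n_allocations = as.integer(n_allocations),
                 hab_amounts = hab_amounts, hab_aggs = hab_aggs),
            class = "budget_design")
}

#' Run the trait-budget trade-off experiment
#'
#' For every landscape x allocation: broken-stick shares -> phenotype ->
#' cohort.  Allocations are redrawn per landscape.  Records the five
#' shares, the Shannon index, the joint speed + mortality-avoidance
#' investment score, and dispersal success.
#'
#' @param design A [budget_design()].
#' @param config A [sim_config()].
#' @param n_agents Agents per cohort.
#' @param seed Global seed.
#' @return Data frame, one row per cohort.
#' @export
run_budget_experiment <- function(design, config = sim_config(),
                                  n_agents = config$cohort_size, seed = 1L) {
  stopifnot(inherits(design, "budget_design"))
  env <- expand.grid(hab_agg = design$hab_aggs,
                     hab_amount = design$hab_amounts,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (e in seq_len(nrow(env))) {
    for (a in seq_len(design$n_allocations)) {
      land <- generate_landscape(
        landscape_params(hab_amount = env$hab_amount[e],
                         hab_agg = env$hab_agg[e]),
        seed = seed_stream(seed, e, a, 1L))
      alloc <- allocation(with_seed(seed_stream(seed, e, a, 2L),
                                    broken_stick(5L)))
      tr <- shares_to_traits(alloc)
      co <- with_seed(seed_stream(seed, e, a, 3L),
                      run_cohort(land, tr, config, n = n_agents))
      rows[[length(rows) + 1L]] <- data.frame(
        hab_amount = env$hab_amount[e], hab_agg = env$hab_agg[e],
        allocation = a,
        share_speed = alloc$shares[["speed"]],
        share_range = alloc$shares[["perceptual_range"]],
        share_mortality = alloc$shares[["mortality"]],
        share_min_area = alloc$shares[["min_area"]],
        share_foraging = alloc$shares[["foraging_tendency"]],
        shannon = alloc$shannon,
        joint_speed_mortality = alloc$shares[["speed"]] +
          alloc$shares[["mortality"]],
        n_success = co$n_success, n_died = co$n_died,
        n_timeout = co$n_timeout, success = co$success)
    }
  }
  do.call(rbind, rows)
}
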