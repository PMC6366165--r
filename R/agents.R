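#' Biological trait set of a dispersing phenotype
#'
#' The five traits that govern a dispersal attempt: movement speed,
#' perceptual range, per-step background mortality (a proxy for predation
#' risk), minimum patch area required for settlement (MINAREA, a proxy for
#' energetic area requirements), and foraging tendency (the probability of
#' switching into slow, energy-gaining foraging when entering a forage
#' cell).
#'
#' @param speed Movement speed, cells per step, in `[1, 5]`.
#' @param perceptual_range Detection radius in cells, in `[1, 5]`.
#' @param mortality Per-step mortality probability, in `[0.0001, 0.015]`.
#' @param min_area Minimum patch size (cells) for a patch to be targeted
#'   or settled, in `[1, 50]`.
#' @param foraging_tendency Probability of entering foraging mode on
#'   arrival in a forage cell, in `[0, 0.5]`.
#' @param validate Check values against the study ranges above (default
#'   `TRUE`). Disable for diagnostic scenarios outside the study box, e.g.
#'   an unbounded perceptual range on an oracle fixture.
#' @return A `trait_set` list.
#' @export
trait_set <- function(speed = 3, perceptual_range = 3, mortality = 0.005,
                      min_area = 25, foraging_tendency = 0.25,
                      validate = TRUE) {
  tr <- list(speed = speed, perceptual_range = perceptual_range,
             mortality = mortality, min_area = min_area,
             foraging_tendency = foraging_tendency)
  if (any(!vapply(tr, is.finite, logical(1))))
    stop("trait values must be finite", call. = FALSE)
  if (mortality < 0 || mortality > 1)
    stop("`mortality` must be a probability", call. = FALSE)
  if (validate) {
    chk <- function(v, lo, hi, nm) {
      if (v < lo || v > hi)
        stop(sprintf("`%s` = %g outside study range [%g, %g]", nm, v, lo, hi),
             call. = FALSE)
    }
    chk(speed, 1, 5, "speed")
    chk(perceptual_range, 1, 5, "perceptual_range")
    chk(mortality, 0.0001, 0.015, "mortality")
    chk(min_area, 1, 50, "min_area")
    chk(foraging_tendency, 0, 0.5, "foraging_tendency")
  }
  structure(tr, class = "trait_set")
}

#' Simulation configuration
#'
#' Fixed constants of the dispersal model: the 250-step stopping point, the
#' cohort of 2500 attempts per model run, the correlated-random-walk
#' maximum turning angle of 90 degrees, the 180-degree forward perceptual
#' arc, the 0.1 cells-per-step foraging speed and the one-step-per-step
#' energy gain while foraging.  Energy gained by foraging extends an
#' agent's step budget (budget = `max_steps` + energy), bounded by
#' `hard_step_cap` so runs terminate even with zero mortality.
#'
#' @param max_steps Stopping point in model steps (default 250).
#' @param cohort_size Dispersal attempts per model run (default 2500).
#' @param max_turn Maximum CRW turning angle, degrees (default 90).
#' @param perception_arc Full width of the forward perceptual arc, degrees
#'   (default 180).
#' @param forage_speed Movement speed while foraging, cells/step (default 0.1).
#' @param forage_energy_gain Step-budget credit per foraging step (default 1).
#' @param hard_step_cap Absolute step bound (default 2500).
#' @param boundary `"reflect"` (default) or `"wrap"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(max_steps = 250L, cohort_size = 2500L,
                       max_turn = 90, perception_arc = 180,
                       forage_speed = 0.1, forage_energy_gain = 1,
                       hard_step_cap = 2500L,
                       boundary = c("reflect", "wrap")) {
  boundary <- match.arg(boundary)
  max_steps <- as.integer(max_steps)
  hard_step_cap <- as.integer(hard_step_cap)
  if (max_steps < 0L) stop("`max_steps` must be >= 0", call. = FALSE)
  if (hard_step_cap < max_steps)
    stop("`hard_step_cap` must be >= `max_steps`", call. = FALSE)
  structure(list(max_steps = max_steps,
                 cohort_size = as.integer(cohort_size),
                 max_turn = max_turn, perception_arc = perception_arc,
                 forage_speed = forage_speed,
                 forage_energy_gain = forage_energy_gain,
                 hard_step_cap = hard_step_cap,
                 boundary = boundary),
            class = "sim_config")
}

#' Simulate a single dispersal attempt
#'
#' Initializes one agent at the centre of a random edge cell of a random
#' habitat patch and advances it step by step until it settles in a
#' suitable patch (size >= `min_area`, different from the start patch),
#' dies, or exhausts its step budget.  Each step applies, in order:
#' background mortality; perception (a suitable patch within the forward
#' perceptual window is approached directly); movement (CRW turn unless
#' approaching); foraging-mode bookkeeping; settlement; step accounting.
#'
#' @param landscape A `dispersim_landscape`.
#' @param traits A [trait_set()].
#' @param config A [sim_config()].
#' @param trace Record the trajectory (`step`, `x`, `y`, `mode`, `energy`)?
#' @return List with `outcome` (`"success"`, `"died"` or `"timeout"`),
#'   `steps`, `energy`, `start_patch`, start coordinates, and `trace`
#'   (matrix) when requested.
#' @export
run_agent <- function(landscape, traits = trait_set(), config = sim_config(),
                      trace = FALSE) {
  stopifnot(inherits(landscape, "dispersim_landscape"))
  if (length(landscape$patch_sizes) == 0L)
    stop("landscape has no habitat patches", call. = FALSE)
  res <- run_agent_cpp(landscape$patch_id, landscape$patch_sizes,
                       landscape$forage_mask, unclass(traits),
                       unclass(config), trace)
  res$outcome <- c("success", "died", "timeout")[res$outcome]
  res
}

#' Simulate a cohort of dispersal attempts
#'
#' Runs `n` independent dispersal attempts (one agent at a time, no
#' interactions) on one landscape and reports the dispersal success
#' proportion -- the fraction of agents that settled in a habitat patch
#' different from their start patch without dying -- together with the
#' failure breakdown (death vs. step-budget timeout, both counted as
#' dispersal failure).
#'
#' @inheritParams run_agent
#' @param n Number of attempts (defaults to `config$cohort_size`, 2500).
#' @return A `cohort_result` list: `n_attempted`, `n_success`, `n_died`,
#'   `n_timeout`, `success`, plus per-agent `outcomes` and `steps`.
#' @examples
#' land <- make_fixture("two-abutting")
#' res <- with_seed(1, run_cohort(land, trait_set(mortality = 0.005), n = 500))
#' res$success
#' @export
run_cohort <- function(landscape, traits = trait_set(), config = sim_config(),
                       n = config$cohort_size) {
  stopifnot(inherits(landscape, "dispersim_landscape"), n >= 1)
  if (length(landscape$patch_sizes) == 0L)
    stop("landscape has no habitat patches", call. = FALSE)
  res <- run_cohort_cpp(landscape$patch_id, landscape$patch_sizes,
                        landscape$forage_mask, unclass(traits),
                        unclass(config), as.integer(n))
  res$success <- res$n_success / res$n_attempted
  class(res) <- "cohort_result"
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort of %d dispersal attempts: success %.3f (%d settled, %d died, %d timed out)\n",
              x$n_attempted, x$success, x$n_success, x$n_died, x$n_timeout))
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the previous RNG state, so
#' simulations are reproducible without clobbering the caller's stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
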