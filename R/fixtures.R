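#' Deterministic test landscapes
#'
#' Small landscapes built in code, used for oracle tests and debugging:
#'
#' * `"corridor"` -- a start patch (one column) and a target patch placed
#'   so that a directed approach takes exactly `T` full-speed steps; the
#'   corridor has no forage cells, so with an unbounded perceptual range
#'   the survival probability of an attempt is exactly `(1 - m)^T`.
#' * `"two-abutting"` -- two large rectangular patches sharing a border
#'   (labelled separately); with zero mortality almost every attempt
#'   settles within a few steps.
#' * `"single-patch"` -- one patch in an empty matrix; no attempt can ever
#'   succeed because settlement requires a different patch.
#' * `"random20"` -- a 20 x 20 generated landscape with a fixed seed
#'   (amount 0.3, aggregation 0.5), regenerated bit-exactly from code.
#'
#' @param name Fixture name.
#' @param T Corridor length in steps (corridor fixture; default 100).
#' @param speed Agent speed the corridor is tuned for (default 1).
#' @return A `dispersim_landscape`.
#' @export
make_fixture <- function(name = c("corridor", "two-abutting", "single-patch",
                                  "random20"),
                         T = 100L, speed = 1) {
  name <- match.arg(name)
  switch(name,
    "corridor" = {
      # two single-column patches exactly T * speed cells apart.  An agent
      # starts at (x0 + 0.5, y + 0.5) in either patch; the nearest cell of
      # the other patch is the same-row centre at distance T * speed, so a
      # straight approach at `speed` crosses into it on step T exactly,
      # from whichever side the agent starts.
      xT <- as.integer(round(T * speed))
      W <- xT + 1L; H <- 3L
      patch_id <- matrix(0L, H, W)
      patch_id[, 1L] <- 1L
      patch_id[, W] <- 2L
      landscape_from_grids(patch_id)
    },
    "two-abutting" = {
      patch_id <- matrix(0L, 20L, 20L)
      patch_id[3:18, 2:10] <- 1L
      patch_id[3:18, 11:19] <- 2L
      landscape_from_grids(patch_id)
    },
    "single-patch" = {
      patch_id <- matrix(0L, 15L, 15L)
      patch_id[6:10, 6:10] <- 1L
      landscape_from_grids(patch_id)
    },
    "random20" = with_seed(20200620,
      generate_landscape(landscape_params(width = 20L, height = 20L,
                                          hab_amount = 0.3, hab_agg = 0.5)))
  )
}
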