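test_that("trait and configuration validation enforce the study ranges", {
  expect_error(trait_set(speed = 6), "speed")
  expect_error(trait_set(mortality = 0.5), "mortality")
  expect_error(trait_set(min_area = 0), "min_area")
  expect_silent(trait_set(speed = 9, validate = FALSE))
  expect_error(trait_set(mortality = 1.5, validate = FALSE), "probability")
  expect_error(sim_config(max_steps = 250, hard_step_cap = 100), "hard_step_cap")
})

test_that("cohort counts partition and runs are seed-reproducible", {
  land <- make_fixture("random20")
  res <- with_seed(4, run_cohort(land, baseline_traits(), n = 400))
  expect_identical(res$n_success + res$n_died + res$n_timeout, res$n_attempted)
  expect_equal(res$success, res$n_success / res$n_attempted)
  res2 <- with_seed(4, run_cohort(land, baseline_traits(), n = 400))
  expect_identical(res, res2)
})

test_that("certain death and immediate settlement behave as terminal cases", {
  land <- make_fixture("two-abutting")
  # mortality 1: everyone dies on the first step
  tr <- trait_set(mortality = 1, validate = FALSE)
  res <- with_seed(1, run_cohort(land, tr, n = 100))
  expect_identical(res$n_died, 100L)
  # zero mortality, adjacent large patches: success is certain
  tr0 <- trait_set(mortality = 0, perceptual_range = 5, min_area = 10,
                   validate = FALSE)
  res0 <- with_seed(2, run_cohort(land, tr0, n = 300))
  expect_identical(res0$n_success, 300L)
  # a zero step budget times out before anything else can happen
  rt <- with_seed(3, run_agent(land, baseline_traits(),
                               sim_config(max_steps = 0, hard_step_cap = 0)))
  expect_identical(rt$outcome, "timeout")
  expect_identical(rt$steps, 0L)
})

test_that("a single-patch world never yields dispersal success", {
  land <- make_fixture("single-patch")
  tr <- trait_set(mortality = 0.0001, min_area = 1)
  res <- with_seed(5, run_cohort(land, tr, n = 200))
  expect_identical(res$n_success, 0L)
})

test_that("start patches are chosen uniformly and starts lie on edge cells", {
  land <- make_fixture("two-abutting")
  edge1 <- edge_cells(land$patch_id, 1L)
  edge2 <- edge_cells(land$patch_id, 2L)
  starts <- with_seed(6, vapply(1:2000, function(i) {
    a <- run_agent(land, trait_set(mortality = 1, validate = FALSE))
    edges <- if (a$start_patch == 1L) edge1 else edge2
    cell_ok <- any(edges[, "ix"] == floor(a$start_x) &
                   edges[, "iy"] == floor(a$start_y))
    expect_true(cell_ok)
    a$start_patch
  }, integer(1)))
  # binomial 3 sigma around 50/50
  expect_lt(abs(mean(starts == 1L) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("per-step displacement equals the movement speed away from borders", {
  land <- make_fixture("single-patch")   # 15 x 15, patch in the centre
  tr <- trait_set(speed = 2, perceptual_range = 1, mortality = 0,
                  min_area = 50, foraging_tendency = 0, validate = FALSE)
  res <- with_seed(8, run_agent(land, tr, sim_config(max_steps = 40), trace = TRUE))
  pos <- res$trace[, c("x", "y")]
  d <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  interior <- pos[-nrow(pos), 1] > 2 & pos[-nrow(pos), 1] < 13 &
              pos[-nrow(pos), 2] > 2 & pos[-nrow(pos), 2] < 13 &
              pos[-1, 1] > 0.1 & pos[-1, 1] < 14.9 &
              pos[-1, 2] > 0.1 & pos[-1, 2] < 14.9
  expect_true(any(interior))
  expect_true(all(abs(d[interior] - 2) < 1e-9))
  # a reflected step never exceeds the speed as the crow flies
  expect_true(all(d <= 2 + 1e-9))
})

test_that("corridor survival matches the closed form (1 - m)^T", {
  land <- make_fixture("corridor", T = 20, speed = 1)
  m <- 0.01
  res <- with_seed(9, run_cohort(land, corridor_traits(m, T = 20), n = 4000))
  p <- (1 - m)^20
  expect_lt(abs(res$success - p), 3 * sqrt(p * (1 - p) / 4000))
  # every successful attempt takes exactly T steps
  expect_true(all(res$steps[res$outcomes == 1L] == 20L))
})

test_that("patches below the minimum-area requirement are never settled", {
  land <- make_fixture("corridor", T = 10, speed = 1)  # both patches: 3 cells
  tr <- trait_set(speed = 1, perceptual_range = 15, mortality = 0,
                  min_area = 4, foraging_tendency = 0, validate = FALSE)
  res <- with_seed(10, run_cohort(land, tr, sim_config(max_steps = 100), n = 100))
  expect_identical(res$n_success, 0L)
  expect_identical(res$n_timeout, 100L)
})

test_that("success responds monotonically to speed and mortality", {
  n_seeds <- 20
  succ <- function(tr) vapply(1:n_seeds, function(s) {
    land <- generate_landscape(landscape_params(hab_amount = 0.15,
                                                hab_agg = 0.4), seed = s)
    with_seed(1000 + s, run_cohort(land, tr, n = 150))$success
  }, numeric(1))
  fast <- succ(trait_set(speed = 5)); slow <- succ(trait_set(speed = 1))
  expect_gt(mean(fast), mean(slow))
  safe <- succ(trait_set(mortality = 0.0001))
  risky <- succ(trait_set(mortality = 0.015))
  expect_gt(mean(safe), mean(risky))
})

test_that("agents always terminate, even with zero mortality and no targets", {
  land <- make_fixture("single-patch")
  tr <- trait_set(mortality = 0, foraging_tendency = 0.5, validate = FALSE)
  cfg <- sim_config(max_steps = 50, hard_step_cap = 120)
  res <- with_seed(11, run_cohort(land, tr, cfg, n = 50))
  expect_identical(res$n_timeout, 50L)
  expect_true(all(res$steps <= 120L))
})
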