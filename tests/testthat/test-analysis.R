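test_that("BRT input validation rejects malformed problems", {
  X <- data.frame(a = runif(100), b = runif(100))
  expect_error(fit_brt(X[, 1, drop = FALSE], runif(100)), "two predictors")
  expect_error(fit_brt(X[1:20, ], runif(20)), "50 rows")
  Xbad <- X; Xbad$a[3] <- NA
  expect_error(fit_brt(Xbad, runif(100)), "non-finite")
  expect_error(fit_brt(X, c(runif(99), Inf)), "non-finite")
  expect_error(brt_config(learning_rate = 0), "learning_rate")
  expect_error(brt_config(bag_fraction = 1.2), "bag_fraction")
})

test_that("BRT recovers a known signal and is deterministic given the seed", {
  set.seed(31)
  n <- 2000
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- 2 * X$x1 + rnorm(n, sd = 0.2)
  m <- with_seed(32, fit_brt(X, y))
  Xh <- data.frame(x1 = runif(500), x2 = runif(500))
  yh <- 2 * Xh$x1
  p <- predict(m, Xh)
  r2 <- 1 - sum((yh - p)^2) / sum((yh - mean(yh))^2)
  expect_gt(r2, 0.8)
  m2 <- with_seed(32, fit_brt(X, y))
  expect_identical(predict(m2, Xh), p)
  expect_gt(m$n_trees, 0L)
})

test_that("relative influence is normalized, non-negative and signal-driven", {
  set.seed(33)
  n <- 5000
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  m1 <- with_seed(34, fit_brt(X, X$x1 + rnorm(n, sd = 0.01)))
  ri <- relative_influence(m1)
  expect_equal(sum(ri$influence), 100, tolerance = 1e-6)
  expect_true(all(ri$influence >= 0))
  expect_gt(ri$influence[ri$predictor == "x1"], 95)
  # two independent predictors of equal variance split the influence
  m2 <- with_seed(35, fit_brt(X, X$x1 + X$x2 + rnorm(n, sd = 0.05)))
  ri2 <- relative_influence(m2)
  expect_lt(abs(ri2$influence[ri2$predictor == "x1"] - 50), 10)
  expect_lt(abs(ri2$influence[ri2$predictor == "x2"] - 50), 10)
})

test_that("a constant response degenerates safely to the mean", {
  X <- data.frame(a = runif(200), b = runif(200))
  m <- fit_brt(X, rep(0.4, 200))
  expect_identical(m$n_trees, 0L)
  expect_true(all(relative_influence(m)$influence == 0))
  expect_equal(predict(m, X[1:5, ]), rep(0.4, 5))
  expect_error(relative_influence(structure(list(), class = "lm")),
               "dispersim_brt")
})

test_that("influence ranking is stable to the tree-count rule", {
  set.seed(36)
  n <- 1500
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 3 * X$x1 + 1 * X$x2 + rnorm(n, sd = 0.3)
  rank_of <- function(cfg) {
    ri <- relative_influence(with_seed(37, fit_brt(X, y, cfg)))
    ri$predictor
  }
  early <- rank_of(brt_config(max_trees = 4000, patience = 50))
  fixed <- rank_of(brt_config(max_trees = 150, patience = 150))
  expect_identical(early, c("x1", "x2", "x3"))
  expect_identical(fixed, c("x1", "x2", "x3"))
})

test_that("quantile slopes recover exact and location-shift relationships", {
  # exact line: any quantile regression returns its slope
  x <- seq(0, 1, length.out = 50)
  tb <- data.frame(hab_amount = 0.1, hab_agg = 0.4,
                   share_speed = x, share_range = x, share_mortality = x,
                   share_min_area = x, share_foraging = x,
                   success = 1 + 2 * x)
  qf <- quantile_slopes(tb, tau = 0.25)
  expect_true(all(abs(qf$slope - 2) < 1e-8))
  # location-shift model with asymmetric noise: slope is still the shift
  set.seed(38)
  n <- 5000
  xs <- runif(n)
  tb2 <- data.frame(hab_amount = 0.2, hab_agg = 0.4,
                    share_speed = xs, share_range = runif(n),
                    share_mortality = runif(n), share_min_area = runif(n),
                    share_foraging = runif(n),
                    success = 1 + 2 * xs + (rexp(n) - 1))
  qf2 <- quantile_slopes(tb2, tau = 0.25)
  expect_lt(abs(qf2$slope[qf2$trait == "speed"] - 2), 0.1)
  expect_true(all(is.finite(qf2$se[qf2$trait == "speed"])))
  expect_error(quantile_slopes(tb2[1:10, ]), "30 rows")
  expect_error(quantile_slopes(tb2[, -3]), "missing columns")
})

test_that("degenerate investment columns are flagged rather than fitted", {
  x <- runif(60)
  tb <- data.frame(hab_amount = 0.1, hab_agg = 0.1,
                   share_speed = x, share_range = 0.2, share_mortality = x,
                   share_min_area = x, share_foraging = x,
                   success = 0.5 + x)
  qf <- quantile_slopes(tb)
  expect_true(is.na(qf$slope[qf$trait == "range"]))
  expect_false(anyNA(qf$slope[qf$trait != "range"]))
})

test_that("payoff ratios standardize slopes to speed and round-trip", {
  fit <- data.frame(hab_amount = rep(c(0.05, 0.2), each = 3),
                    hab_agg = 0.4,
                    trait = rep(c("speed", "mortality", "min_area"), 2),
                    slope = c(0.4, 0.2, -0.1, 0.5, 0.5, 0.5),
                    se = 0.01, tau = 0.25)
  class(fit) <- c("quantile_fit", class(fit))
  pr <- payoff_ratios(fit)
  expect_equal(pr$ratio[pr$trait == "speed"], c(1, 1))
  expect_equal(pr$ratio[pr$hab_amount == 0.05 & pr$trait == "mortality"], 0.5)
  expect_equal(pr$ratio[pr$hab_amount == 0.05 & pr$trait == "min_area"], -0.25)
  expect_true(all(pr$ratio[pr$hab_amount == 0.2] == 1))
  # multiplying back by the speed slope reproduces the inputs
  back <- pr$ratio * rep(c(0.4, 0.5), each = 3)
  expect_equal(back, pr$slope)
  # a zero speed slope leaves ratios undefined
  bad <- fit; bad$slope[bad$trait == "speed"] <- 0
  expect_error(payoff_ratios(bad), "zero")
})
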