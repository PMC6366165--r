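test_that("habitat count is exact for every amount, seed and method", {
  for (method in c("blob", "cluster", "sequential")) {
    for (amount in c(0.05, 0.17, 0.3, 0.5)) {
      for (seed in 1:3) {
        p <- landscape_params(width = 50, height = 40, hab_amount = amount,
                              hab_agg = 0.4, method = method)
        mask <- with_seed(seed, generate_habitat(p))
        expect_identical(sum(mask), as.integer(round(amount * 50 * 40)))
      }
    }
  }
  # the canonical example: 5% of a 100 x 100 grid is exactly 500 cells
  mask <- with_seed(1, generate_habitat(landscape_params(hab_amount = 0.05)))
  expect_identical(sum(mask), 500L)
})

test_that("degenerate amounts still satisfy the count and patch invariants", {
  p <- landscape_params(width = 10, height = 10, hab_amount = 0.01)
  mask <- with_seed(3, generate_habitat(p))   # a single habitat cell
  expect_identical(sum(mask), 1L)
  lab <- label_patches(mask)
  expect_identical(lab$patch_sizes, 1L)
  expect_error(landscape_params(hab_amount = 1.5), "hab_amount")
  expect_error(landscape_params(hab_amount = 0), "hab_amount")
})

test_that("patch labelling matches known shapes and connectivity rules", {
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  lab <- label_patches(m)
  expect_identical(lab$patch_sizes, 9L)
  expect_true(all(lab$patch_id[m] == 1L))
  expect_true(all(lab$patch_id[!m] == 0L))
  # two diagonal cells: one patch under Moore, two under von Neumann
  d <- matrix(FALSE, 4, 4); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_identical(label_patches(d, 8L)$patch_sizes, 2L)
  expect_identical(label_patches(d, 4L)$patch_sizes, c(1L, 1L))
  # empty mask: zero patches
  expect_length(label_patches(matrix(FALSE, 3, 3))$patch_sizes, 0L)
})

test_that("patch labelling agrees with a flood-fill oracle on random masks", {
  for (seed in 1:12) {
    mask <- with_seed(seed, matrix(runif(144) < 0.4, 12, 12))
    for (conn in c(4L, 8L)) {
      got <- label_patches(mask, conn)
      ref <- flood_fill_labels(mask, conn)
      expect_identical(got$patch_id, ref$patch_id)
      expect_identical(got$patch_sizes, ref$patch_sizes)
    }
  }
})

test_that("quality smoothing preserves the global mean exactly", {
  p <- landscape_params(width = 60, height = 60)
  for (seed in 1:5) {
    q0 <- with_seed(seed, smooth_quality(p, passes = 0))
    q <- q0
    for (k in 1:4) {
      q1 <- dispersim:::moore_mean_torus(q)
      expect_lt(abs(mean(q1) - mean(q)), 1e-12)
      q <- q1
    }
    # raw field is Uniform(0,1): sample mean within 3 sigma of 1/2
    expect_lt(abs(mean(q0) - 0.5), 3 / sqrt(12 * length(q0)))
  }
})

test_that("smoothing is the identity on constant fields and contracts variance", {
  cst <- matrix(0.7, 20, 20)
  expect_equal(dispersim:::moore_mean_torus(cst), cst)
  p <- landscape_params(width = 40, height = 40)
  v <- sapply(1:30, function(seed) {
    q0 <- with_seed(seed, smooth_quality(p, passes = 0))
    q1 <- dispersim:::moore_mean_torus(q0)
    q3 <- dispersim:::moore_mean_torus(dispersim:::moore_mean_torus(q1))
    c(var(c(q0)), var(c(q1)), var(c(q3)))
  })
  means <- rowMeans(v)
  expect_lt(means[2], means[1])
  expect_lt(means[3], means[2])
})

test_that("forage cells are the top quality quantile of matrix cells, exactly counted", {
  hab <- matrix(FALSE, 10, 10); hab[1:2, 1:5] <- TRUE  # 90 matrix cells
  q <- with_seed(5, matrix(runif(100), 10, 10))
  fm <- forage_mask(q, hab, 0.15)
  expect_identical(sum(fm), as.integer(round(0.15 * 90)))
  expect_false(any(fm & hab))
  # selected values dominate unselected matrix values
  expect_gte(min(q[fm]), max(q[!hab & !fm]))
  expect_error(forage_mask(q, hab, 0), "fraction")
  expect_error(forage_mask(q, hab, 1), "fraction")
})

test_that("forage ties break by scan order (ascending row, then column)", {
  hab <- matrix(FALSE, 10, 10)
  q <- matrix(0.5, 10, 10)        # all equal: first 15 cells in scan order
  fm <- forage_mask(q, hab, 0.15)
  rows <- (which(fm) - 1L) %% 10L
  expect_identical(sum(fm), 15L)
  expect_true(all(rows <= 1L))    # rows 0 and 1 fill first
  # strictly increasing in scan order over 20 matrix cells: the 3 largest win
  hab2 <- matrix(FALSE, 4, 5)                  # 20 matrix cells
  sc <- matrix(0, 4, 5)
  idx <- which(!hab2)
  r <- (idx - 1L) %% 4L; cc <- (idx - 1L) %/% 4L
  sc[idx[order(r, cc)]] <- seq_len(20)
  fm2 <- forage_mask(sc, hab2, 0.15)
  expect_identical(sum(fm2), 3L)
  expect_true(all(sc[fm2] >= 18))
})

test_that("edge cells are patch cells with an outside Moore neighbour", {
  pid <- matrix(0L, 7, 7); pid[3:5, 3:5] <- 1L
  ec <- edge_cells(pid, 1L)
  expect_identical(nrow(ec), 8L)                  # all but the centre
  expect_false(any(ec[, "ix"] == 3 & ec[, "iy"] == 3))
  pid1 <- matrix(0L, 5, 5); pid1[3, 3] <- 1L
  expect_identical(nrow(edge_cells(pid1, 1L)), 1L)
  strip <- matrix(0L, 5, 7); strip[3, 2:6] <- 1L
  expect_identical(nrow(edge_cells(strip, 1L)), 5L)
  expect_error(edge_cells(pid, 9L), "label")
})

test_that("mean patch size increases with aggregation (one-sided, many seeds)", {
  mean_size <- function(agg, seeds) {
    vapply(seeds, function(s) {
      p <- landscape_params(width = 60, height = 60, hab_amount = 0.3,
                            hab_agg = agg)
      mean(label_patches(with_seed(s, generate_habitat(p)))$patch_sizes)
    }, numeric(1))
  }
  lo <- mean_size(0.0, 1:200)
  hi <- mean_size(0.75, 1:200)
  tt <- t.test(hi, lo, alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
  expect_gt(mean(hi), mean(lo))
  # the sequential strategy obeys the same ordering
  seq_size <- function(agg) vapply(1:60, function(s) {
    p <- landscape_params(width = 40, height = 40, hab_amount = 0.3,
                          hab_agg = agg, method = "sequential")
    mean(label_patches(with_seed(s, generate_habitat(p)))$patch_sizes)
  }, numeric(1))
  expect_gt(mean(seq_size(0.75)), mean(seq_size(0)))
})

test_that("generated landscapes satisfy the structural invariants", {
  for (seed in 1:5) {
    land <- generate_landscape(landscape_params(hab_amount = 0.2,
                                                hab_agg = 0.5), seed = seed)
    n_hab <- sum(land$habitat_mask)
    expect_identical(n_hab, 2000L)
    expect_identical(sum(land$patch_sizes), n_hab)
    expect_true(all(land$patch_id[land$habitat_mask] >= 1L))
    expect_true(all(land$patch_id[!land$habitat_mask] == 0L))
    expect_false(any(land$forage_mask & land$habitat_mask))
    n_matrix <- sum(!land$habitat_mask)
    expect_identical(sum(land$forage_mask), as.integer(round(0.15 * n_matrix)))
    expect_gte(length(land$patch_sizes), 2L)
  }
  # pure function of (params, seed)
  a <- generate_landscape(landscape_params(), seed = 7)
  b <- generate_landscape(landscape_params(), seed = 7)
  expect_identical(a, b)
})
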