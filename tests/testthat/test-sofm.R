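test_that("initialization is seeded, sized by the grid, and small", {
  cfg <- sofm_config(seed = 123)
  m1 <- init_sofm(cfg, input_dim = 5)
  m2 <- init_sofm(cfg, input_dim = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(dim(m1$weights), c(24L, 5L))
  expect_true(all(abs(m1$weights) <= 0.1))
  expect_identical(m1$biases, numeric(24))
  expect_false(identical(init_sofm(sofm_config(seed = 124), 5)$weights,
                         m1$weights))
  expect_error(sofm_config(grid_rows = 0), "grid_rows")
})

test_that("the winner is the nearest weight row, ties to the lowest index", {
  cfg <- sofm_config(seed = 1)
  model <- init_sofm(cfg, 4)
  # sample equal to a weight row wins that row
  expect_identical(sofm_winner(model, model$weights[17, ]), 17L)
  # two equidistant rows: lower index wins
  model$weights[] <- 5
  model$weights[5, ] <- c(1, 0, 0, 0)
  model$weights[9, ] <- c(-1, 0, 0, 0)
  expect_identical(sofm_winner(model, c(0, 0, 0, 0)), 5L)
  expect_error(sofm_winner(model, c(0, 0)), "dimension")
})

test_that("winner agrees with brute-force nearest-row search", {
  withr::with_seed(99, {
    for (i in 1:100) {
      model <- init_sofm(sofm_config(seed = i), 5)
      model$weights <- matrix(rnorm(24 * 5), 24)
      p <- rnorm(5)
      d <- apply(model$weights, 1, function(w) sqrt(sum((w - p)^2)))
      expect_identical(sofm_winner(model, p), which.min(d))
    }
  })
})

test_that("decay follows the linear schedule with the ceiling radius", {
  expect_equal(sofm_decay(0.5, 4, 5, 10), list(eta = 0.25, nc = 2))
  expect_equal(sofm_decay(0.7, 3, 10, 10), list(eta = 0, nc = 0))
  expect_equal(sofm_decay(0.9, 3, 1, 10), list(eta = 0.81, nc = 3))  # ceil(2.7)
  expect_error(sofm_decay(0.5, 4, 11, 10), "max_steps")
})

test_that("the neighborhood update moves exactly the in-radius rows", {
  cfg <- sofm_config(seed = 5)
  model <- init_sofm(cfg, 3)
  p <- c(2, -1, 4)

  # eta = 1 and a radius covering the grid: every row becomes the sample
  m <- sofm_update(model, p, winner = 10, nc = 10, eta = 1)
  expect_true(all(abs(sweep(m$weights, 2, p)) < 1e-12))

  # eta = 0: identity
  m <- sofm_update(model, p, winner = 10, nc = 10, eta = 0)
  expect_identical(m$weights, model$weights)

  # eta = 0.5, nc = 0: only the winner moves, halfway, per direct formula
  m <- sofm_update(model, p, winner = 7, nc = 0, eta = 0.5)
  expect_equal(m$weights[7, ], model$weights[7, ] + 0.5 * (p - model$weights[7, ]))
  expect_identical(m$weights[-7, ], model$weights[-7, ])
})

test_that("training is reproducible and separates two point clouds", {
  withr::with_seed(31, {
    cloud_a <- matrix(rnorm(30 * 2, mean = 0), ncol = 2)
    cloud_b <- matrix(rnorm(30 * 2, mean = 8), ncol = 2)
  })
  samples <- rbind(cloud_a, cloud_b)
  cfg <- sofm_config(max_steps = 500, seed = 77)
  m1 <- train_sofm(samples, cfg)
  m2 <- train_sofm(samples, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$steps_trained, 500L)
  wa <- unique(assign_winners(m1, cloud_a))
  wb <- unique(assign_winners(m1, cloud_b))
  expect_length(intersect(wa, wb), 0)
})

test_that("trained weights stay in the box spanned by init and samples", {
  withr::with_seed(8, samples <- matrix(rnorm(12 * 4, sd = 3), ncol = 4))
  m <- train_sofm(samples, sofm_config(max_steps = 200, seed = 3))
  lo <- pmin(apply(samples, 2, min), -0.1)
  hi <- pmax(apply(samples, 2, max), 0.1)
  for (j in seq_len(ncol(samples))) {
    expect_true(all(m$weights[, j] >= lo[j] - 1e-12))
    expect_true(all(m$weights[, j] <= hi[j] + 1e-12))
  }
})

test_that("partitions are label-invariant and built from shared winners", {
  labs <- c(16, 13, 1, 19, 12, 8, 24, 19, 19, 20, 20, 1)
  p <- labels_to_partition(labs, canonical_descriptors())
  expect_length(p, 8)
  # any relabeling gives an equal partition
  relab <- match(labs, unique(labs)) + 100
  q <- labels_to_partition(relab, canonical_descriptors())
  expect_true(partitions_equal(p, q))
  expect_identical(partition_signature(p), partition_signature(q))
  # identical samples collapse to a single group
  same <- matrix(1, nrow = 4, ncol = 3)
  m <- train_sofm(same, sofm_config(max_steps = 50, seed = 2))
  expect_length(assign_and_partition(m, same, letters[1:4]), 1)
})

test_that("consensus over restarts is deterministic given the seed", {
  g <- generate_table(synthetic_spec(seed = 4))
  prof <- t(scale(descriptor_matrix(g$table)))
  cfg <- sofm_config(seed = 10)
  c1 <- consensus_partition(prof, canonical_descriptors(), cfg, n_restarts = 5)
  c2 <- consensus_partition(prof, canonical_descriptors(), cfg, n_restarts = 5)
  expect_identical(partition_signature(c1$partition),
                   partition_signature(c2$partition))
  expect_identical(c1$support, c2$support)
})
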