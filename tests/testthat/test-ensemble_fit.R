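test_that("weighted_average_map mixes voxelwise", {
  fx <- disjoint_mixture()
  m1 <- fx$maps[[1]]
  expect_equal(weighted_average_map(fx$maps, c(1, 0, 0))$values, m1$values)
  expect_equal(weighted_average_map(list(m1, m1), c(0.3, 0.7))$values,
               m1$values)
  two <- weighted_average_map(fx$maps[1:2], c(0.25, 0.75))
  expect_equal(two$values[1, 1, 1], 0.25)
  expect_equal(two$values[2, 1, 1], 0.75)
  expect_error(weighted_average_map(fx$maps, c(0.5, 0.5)), "length")
  expect_error(weighted_average_map(fx$maps, c(0.5, 0.6, -0.1)), "nonnegative")
  expect_error(weighted_average_map(fx$maps, c(0.5, 0.3, 0.1)), "sum to 1")
})

test_that("optimize_weights recovers a noiseless disjoint mixture exactly", {
  fx <- disjoint_mixture(c(0.20, 0.25, 0.55))
  res <- optimize_weights(fx$maps, fx$target, grid_step = 0.01)
  expect_equal(res$weights, c(0.20, 0.25, 0.55), tolerance = 1e-12)
  expect_equal(res$rho, 1, tolerance = 1e-9)
  # full surface is the whole 0.01 barycentric lattice
  expect_equal(nrow(res$surface), choose(100 + 2, 2))
  # lattice maximizer agrees with an independent brute-force scan of the surface
  best_row <- res$surface[which.max(res$surface$rho), ]
  expect_equal(unlist(best_row[c("w1", "w2", "w3")], use.names = FALSE),
               res$weights)
})

test_that("optimize_weights handles one-hot targets and degenerate ties", {
  fx <- disjoint_mixture()
  t1 <- density_map(fx$grid, fx$maps[[1]]$values,
                    array(TRUE, dim = fx$grid$shape))
  res <- optimize_weights(fx$maps, t1)
  expect_equal(res$weights, c(1, 0, 0))
  expect_equal(res$rho, 1, tolerance = 1e-12)
  # identical maps: tie broken to the lexicographically smallest vector
  same <- list(fx$maps[[1]], fx$maps[[1]], fx$maps[[1]])
  res2 <- optimize_weights(same, t1)
  expect_equal(res2$weights, c(0, 0, 1))
  flat <- density_map(fx$grid, array(5, dim = fx$grid$shape),
                      array(TRUE, dim = fx$grid$shape))
  expect_error(optimize_weights(fx$maps, flat), "zero variance")
  expect_error(optimize_weights(fx$maps[1], t1), "length")
})

test_that("optimal rho is never below the best single map", {
  s <- selection_fixture()
  singles <- vapply(s$pool_maps, function(m)
    map_correlation(m, s$target, mask = s$target$mask)$rho, numeric(1))
  res <- optimize_weights(s$pool_maps[1:3], s$target, return_surface = FALSE)
  expect_gte(res$rho, max(singles[1:3]) - 1e-9)
})

test_that("weight optimization beyond three maps matches the lattice answer", {
  # 4 maps where map 4 is irrelevant: support enumeration must find the
  # same optimum as the 3-map lattice
  fx <- disjoint_mixture(c(0.20, 0.25, 0.55))
  set.seed(99)
  far <- density_map(fx$grid, array(stats::rnorm(64, sd = 0.01), fx$grid$shape))
  res3 <- optimize_weights(fx$maps, fx$target, return_surface = FALSE)
  res4 <- optimize_weights(c(fx$maps, list(far)), fx$target)
  expect_equal(res4$rho, res3$rho, tolerance = 1e-6)
  expect_equal(res4$weights[1:3], res3$weights, tolerance = 1e-6)
  expect_lt(res4$weights[4], 1e-6)
})

test_that("structure-set selection finds the single identical map", {
  s <- selection_fixture()
  pool <- c(s$pool_maps,
            list(density_map(s$target$grid, s$target$values)))
  cfg <- selection_config(1, seed = 7)
  res <- optimize_structure_set(pool, s$target, cfg)
  expect_equal(res$member_indices, length(pool))
  expect_equal(res$rho, 1, tolerance = 1e-9)
})

test_that("selection matches the exhaustive oracle and is reproducible", {
  s <- selection_fixture()
  bf <- brute_force_select(s$pool_maps, s$target, 2)
  expect_equal(bf$iterations, choose(8, 2))
  cfg <- selection_config(2, seed = 123)
  res1 <- optimize_structure_set(s$pool_maps, s$target, cfg)
  res2 <- optimize_structure_set(s$pool_maps, s$target, cfg)
  expect_identical(res1$member_indices, res2$member_indices)   # bit-reproducible
  expect_identical(res1$rho, res2$rho)
  expect_identical(res1$traces, res2$traces)
  expect_equal(res1$rho, bf$rho, tolerance = 1e-9)
  # replica spread satisfies the convergence criterion
  expect_lte(max(res1$replica_rhos) - min(res1$replica_rhos), 1e-2)
  # accepted-rho sequence never decreases, final >= initial
  for (tr in res1$traces) {
    expect_true(all(diff(tr) >= 0))
    expect_gte(tr[length(tr)], tr[1])
  }
})

test_that("brute-force oracle endpoints", {
  s <- selection_fixture()
  n <- length(s$pool_maps)
  full <- brute_force_select(s$pool_maps, s$target, n)
  expect_equal(full$member_indices, seq_len(n))
  one <- brute_force_select(s$pool_maps, s$target, 1)
  singles <- vapply(s$pool_maps, function(m)
    map_correlation(m, s$target, mask = s$target$mask)$rho, numeric(1))
  expect_equal(one$member_indices, which.max(singles))
  expect_error(brute_force_select(s$pool_maps, s$target, 3, max_subsets = 5),
               "cap exceeded")
  expect_error(optimize_structure_set(s$pool_maps, s$target,
                                      selection_config(n + 1L)),
               "exceeds pool")
})

test_that("best_n_curve is non-decreasing and reports reference correlations", {
  s <- selection_fixture()
  cfg <- selection_config(1, n_replicas = 3, seed = 42, max_iterations = 400)
  curve <- best_n_curve(s$pool_maps, s$target, n_values = c(1, 2, 3), cfg)
  expect_equal(curve$n, c(1, 2, 3))
  expect_true(all(diff(curve$rho) >= -1e-9))
  expect_true(is.numeric(attr(curve, "rho_full_ensemble")))
  # n = pool size equals the full-pool optimum
  full_cfg <- selection_config(1, n_replicas = 2, seed = 1)
  full <- best_n_curve(s$pool_maps, s$target,
                       n_values = length(s$pool_maps), full_cfg)
  bf <- brute_force_select(s$pool_maps, s$target, length(s$pool_maps))
  expect_equal(full$rho, bf$rho, tolerance = 1e-9)
})

test_that("noiseless mixture weights are recovered through the full pipeline path", {
  s <- small_scenario()
  res <- optimize_weights(s$tgt$ensemble_maps, s$tgt$target,
                          return_surface = FALSE)
  expect_equal(res$weights, s$scenario$true_weights, tolerance = 0.011)
  expect_gte(res$rho, 0.999)
})
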