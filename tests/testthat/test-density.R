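fine_grid <- function(sigma = 1.1, half = 8) {
  # odd shape centered on the origin, so (0, 0, 0) is a voxel center
  n_half <- ceiling(half / (sigma / 2))
  grid_spec(origin = rep(-n_half * sigma / 2, 3), spacing = sigma / 2,
            shape = rep(2L * n_half + 1L, 3))
}

test_that("single-atom spread integrates to 1 and hits the closed-form peak", {
  sigma <- 1.1
  g <- fine_grid(sigma)
  center <- c(0, 0, 0)                                 # a voxel center
  d <- spread_density(matrix(center, 1), g, spread_params(sigma))
  expect_equal(sum(d$values) * prod(g$spacing), 1, tolerance = 1e-3)
  expect_equal(max(d$values), (2 * pi * sigma^2)^(-3 / 2), tolerance = 1e-3)
  peak_idx <- arrayInd(which.max(d$values), g$shape)
  expect_equal(as.integer(peak_idx), as.integer((g$shape - 1) / 2 + 1))
})

test_that("spreading is linear in atoms and amplitudes", {
  g <- fine_grid()
  p <- spread_params(1.1)
  a1 <- matrix(c(-2, 0, 0), 1); a2 <- matrix(c(2, 1, -1), 1)
  both <- spread_density(rbind(a1, a2), g, p)
  expect_equal(both$values,
               spread_density(a1, g, p)$values + spread_density(a2, g, p)$values,
               tolerance = 1e-12)
  z6 <- spread_density(a1, g, p, amplitudes = 6)
  expect_equal(z6$values, 6 * spread_density(a1, g, p)$values, tolerance = 1e-12)
})

test_that("atomic-number amplitude mode weights atoms by Z", {
  g <- fine_grid()
  m <- toy_chain(3)
  m$atoms$element <- c("C", "N", "O")
  d <- spread_density(m, g, spread_params(1.1, amplitude_mode = "atomic_number"))
  expect_equal(sum(d$values) * prod(g$spacing), 6 + 7 + 8, tolerance = 0.05)
})

test_that("spreading warns on aliasing grids and out-of-grid atoms", {
  g <- grid_spec(origin = c(0, 0, 0), spacing = 3, shape = c(5, 5, 5))
  expect_warning(spread_density(matrix(c(6, 6, 6), 1), g, spread_params(1.1)),
                 "aliasing")
  g2 <- fine_grid()
  expect_warning(spread_density(matrix(c(500, 0, 0), 1), g2, spread_params(1.1)),
                 "outside the grid")
})

test_that("translation by whole voxels translates the map identically", {
  g <- grid_spec(origin = c(-10, -10, -10), spacing = 1, shape = c(21, 21, 21))
  p <- spread_params(1.1)
  xyz <- coords(toy_chain(5))
  s <- c(-2L, 1L, 3L)                     # whole-voxel shift
  d0 <- spread_density(xyz, g, p)$values
  d1 <- spread_density(sweep(xyz, 2, s, `+`), g, p)$values
  v <- 6:15                               # interior where both are defined
  expect_equal(d1[v + s[1], v + s[2], v + s[3]], d0[v, v, v],
               tolerance = 1e-12)
})

test_that("ensemble_density is the arithmetic mean of frame maps", {
  g <- fine_grid()
  p <- spread_params(1.1)
  f1 <- matrix(c(-4, 0, 0), 1); f2 <- matrix(c(4, 0, 0), 1)  # non-overlapping
  single <- spread_density(f1, g, p)
  expect_equal(ensemble_density(list(f1), g, p)$values, single$values)
  expect_equal(ensemble_density(list(f1, f1), g, p)$values, single$values)
  two <- ensemble_density(list(f1, f2), g, p)
  expect_equal(max(two$values), max(single$values) / 2, tolerance = 1e-6)
  expect_error(ensemble_density(list(), g, p), "at least one")
})

test_that("reference region mask is the 5 A lattice ball and unions over structures", {
  g <- grid_spec(origin = c(-10, -10, -10), spacing = 1, shape = c(21, 21, 21))
  m <- density_map(g, array(seq_len(21^3), dim = g$shape))
  rr <- extract_reference_region(m, matrix(0, 1, 3), radius = 5)
  expect_equal(sum(rr$mask), 515L)          # |{v in Z^3 : |v| <= 5}|
  expect_equal(rr$values, m$values)         # values untouched
  # radius 0 -> only the coincident voxel center
  rr0 <- extract_reference_region(m, matrix(0, 1, 3), radius = 0)
  expect_equal(sum(rr0$mask), 1L)
  # union identity over three structures
  pts <- list(matrix(c(-4, 0, 0), 1), matrix(c(4, 0, 0), 1),
              matrix(c(0, 5, 0), 1))
  joint <- extract_reference_region(m, pts, radius = 3)
  singles <- lapply(pts, function(p) extract_reference_region(m, p, radius = 3)$mask)
  expect_equal(joint$mask, Reduce(`|`, singles))
  expect_error(extract_reference_region(m, matrix(c(1e4, 0, 0), 1), radius = 2),
               "empty")
})

test_that("map correlation is Pearson over the mask", {
  g <- grid_spec(origin = c(0, 0, 0), spacing = 1, shape = c(3, 1, 1))
  mask <- array(TRUE, dim = c(3, 1, 1))
  a <- density_map(g, array(c(1, 2, 3), dim = c(3, 1, 1)), mask)
  b <- density_map(g, array(c(3, 2, 1), dim = c(3, 1, 1)))
  expect_equal(map_correlation(a, a)$rho, 1)
  expect_equal(map_correlation(a, b)$rho, -1)
  aff <- density_map(g, 2 * a$values + 7)
  expect_equal(map_correlation(a, aff)$rho, 1)
  # symmetry
  expect_equal(map_correlation(a, b)$rho, map_correlation(b, a)$rho)
  expect_equal(map_correlation(a, b)$n_voxels, 3L)
  flat <- density_map(g, array(1, dim = c(3, 1, 1)))
  expect_error(map_correlation(a, flat), "zero variance")
  g2 <- grid_spec(origin = c(1, 0, 0), spacing = 1, shape = c(3, 1, 1))
  expect_error(map_correlation(a, density_map(g2, b$values)), "different grids")
})

test_that("mean versus sum of frame maps gives identical correlation", {
  s <- small_scenario()
  g <- s$scenario$grid
  p <- spread_params(1.1)
  frames <- lapply(1:4, function(i)
    s$tgt$fitted_ensembles[[1]]$coords[s$system$chain_index, , i])
  mean_map <- ensemble_density(frames, g, p)
  sum_map <- density_map(g, mean_map$values * length(frames))
  tgt <- s$tgt$target
  expect_equal(map_correlation(mean_map, tgt, mask = tgt$mask)$rho,
               map_correlation(sum_map, tgt, mask = tgt$mask)$rho,
               tolerance = 1e-12)
})

test_that("sigma calibration recovers the generating width with a unimodal scan", {
  m <- toy_chain(5)
  g <- grid_spec(origin = c(-12, -12, -12), spacing = 1, shape = c(25, 25, 25))
  truth <- spread_density(m, g, spread_params(1.1))
  target <- extract_reference_region(truth, m, radius = 5)
  res <- calibrate_sigma(m, target, sigmas = seq(0.5, 1.5, by = 0.1))
  expect_equal(res$best_sigma, 1.1)
  expect_equal(max(res$scan$rho), 1, tolerance = 1e-9)
  peak <- which.max(res$scan$rho)
  expect_true(all(diff(res$scan$rho[seq_len(peak)]) > 0))
  expect_true(all(diff(res$scan$rho[peak:nrow(res$scan)]) < 0))
  # single-value scan returns that value
  expect_equal(calibrate_sigma(m, target, sigmas = 0.8)$best_sigma, 0.8)
  expect_error(calibrate_sigma(m, target, sigmas = numeric(0)))
})
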