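# build an ensemble directly from a frame list (times 1 ns apart so the
# default covariance subsampling keeps every frame)
ensemble_from_frames <- function(frames, topology, tag = "I", replica = 1L) {
  arr <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3L, length(frames)))
  trajectory_ensemble(topology, arr, seq_along(frames) - 1,
                      origin_conformation = tag, replica_id = replica)
}

test_that("rank-1 motion yields mode 1 = the displacement direction", {
  topo <- toy_chain(6)
  base <- coords(topo)
  v <- matrix(rnorm(18), 6, 3); v <- v / sqrt(sum(v^2))
  frames <- lapply(seq(-2, 2, by = 0.5), function(t) base + t * v)
  ens <- ensemble_from_frames(frames, topo)
  basis <- pca_modes(list(ens), selection = 1:6)
  expect_equal(basis$variance_fractions[1], 1, tolerance = 1e-9)
  vflat <- as.numeric(t(v))
  overlap <- abs(sum(basis$eigenvectors[, 1] * vflat))
  expect_equal(overlap, 1, tolerance = 1e-9)
  # total variance equals the covariance trace
  expect_equal(sum(basis$eigenvalues),
               sum(apply(do.call(rbind, lapply(frames, function(f)
                 as.numeric(t(f)))), 2, stats::var)),
               tolerance = 1e-8)
})

test_that("two orthogonal modes with 4:1 variances give fractions 0.8/0.2", {
  set.seed(10)
  topo <- toy_chain(5)
  base <- coords(topo)
  v1 <- matrix(0, 5, 3); v1[1, 1] <- 1
  v2 <- matrix(0, 5, 3); v2[2, 2] <- 1
  n <- 1e4
  frames <- lapply(seq_len(n), function(i)
    base + rnorm(1, 0, 2) * v1 + rnorm(1, 0, 1) * v2)
  ens <- ensemble_from_frames(frames, topo)
  basis <- pca_modes(list(ens), selection = 1:5)
  expect_equal(basis$variance_fractions[1], 0.8, tolerance = 0.03)
  expect_equal(basis$variance_fractions[2], 0.2, tolerance = 0.03)
  expect_lt(basis$variance_fractions[3], 1e-9)
})

test_that("fewer than 2 sampled frames errors", {
  topo <- toy_chain(4)
  ens <- ensemble_from_frames(list(coords(topo)), topo)
  expect_error(pca_modes(list(ens), selection = 1:4), "at least 2")
})

test_that("projections honor orthonormality and reconstruct frames", {
  set.seed(11)
  topo <- toy_chain(5)
  base <- coords(topo)
  frames <- lapply(1:40, function(i) base + matrix(rnorm(15, 0, 0.5), 5, 3))
  ens <- ensemble_from_frames(frames, topo)
  basis <- pca_modes(list(ens), selection = 1:5)
  V <- basis$eigenvectors
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-8)
  # frame = mean -> projection (0, 0)
  mean_ens <- ensemble_from_frames(
    list(matrix(basis$mean_flat, 5, 3, byrow = TRUE),
         matrix(basis$mean_flat, 5, 3, byrow = TRUE) + 1e-30), topo)
  pr <- project_frames(mean_ens, basis)
  expect_equal(unname(unlist(pr[1, c("pc1", "pc2")])), c(0, 0), tolerance = 1e-9)
  # frame = mean + 2 * eigenvector_1 -> (2, 0)
  shifted <- matrix(basis$mean_flat + 2 * V[, 1], 5, 3, byrow = TRUE)
  pr2 <- project_frames(ensemble_from_frames(list(shifted, shifted + 1e-30),
                                             topo), basis)
  expect_equal(unname(unlist(pr2[1, c("pc1", "pc2")])), c(2, 0),
               tolerance = 1e-8)
  # full-basis reconstruction reproduces the centered frame
  prall <- project_frames(ens, basis, n_modes = ncol(V))
  p1 <- as.numeric(prall[1, paste0("pc", seq_len(ncol(V)))])
  recon <- basis$mean_flat + as.numeric(V %*% p1)
  expect_equal(recon, as.numeric(t(frames[[1]])), tolerance = 1e-8)
  # one point per input frame, at full resolution
  expect_equal(nrow(project_frames(ens, basis)), length(frames))
})

test_that("eigenvector sign convention makes projections deterministic", {
  s <- small_scenario()
  b1 <- pca_modes(s$tgt$fitted_ensembles, selection = s$system$chain_index,
                  sample_interval_ns = 100)
  b2 <- pca_modes(s$tgt$fitted_ensembles, selection = s$system$chain_index,
                  sample_interval_ns = 100)
  expect_identical(b1$eigenvectors, b2$eigenvectors)
  for (j in 1:3) {
    jmax <- which.max(abs(b1$eigenvectors[, j]))
    expect_gt(b1$eigenvectors[jmax, j], 0)
  }
})

test_that("extreme states return the endpoint frames with earliest-time ties", {
  topo <- toy_chain(4)
  base <- coords(topo)
  v <- matrix(0, 4, 3); v[1, 1] <- 1
  sweep_frames <- lapply(c(-3, -1, 0, 1, 3), function(t) base + t * v)
  ens <- ensemble_from_frames(sweep_frames, topo)
  basis <- pca_modes(list(ens), selection = 1:4)
  proj <- project_frames(list(ens), basis)
  ext <- extreme_states(proj, n_modes = 1)
  got <- sort(unname(c(coords(ext$mode1$min)[1, 1], coords(ext$mode1$max)[1, 1])))
  expect_equal(got, base[1, 1] + c(-3, 3), tolerance = 1e-9, ignore_attr = TRUE)
  # single frame is both extremes; duplicated frame resolves to earliest time
  dup <- ensemble_from_frames(list(base + 3 * v, base - 3 * v, base + 3 * v),
                              topo)
  pd <- project_frames(list(dup), basis)
  ed <- extreme_states(pd, n_modes = 1)
  expect_equal(coords(ed$mode1$max), base + 3 * v, tolerance = 1e-9,
               ignore_attr = TRUE)
  single <- ensemble_from_frames(list(base + 3 * v), topo)
  ps <- project_frames(list(single), basis)
  es <- extreme_states(ps, n_modes = 1)
  expect_equal(coords(es$mode1$min), coords(es$mode1$max))
})

test_that("projection histogram normalizes and outlines occupied bins", {
  s <- small_scenario()
  basis <- pca_modes(s$tgt$fitted_ensembles, selection = s$system$chain_index,
                     sample_interval_ns = 100)
  proj <- project_frames(s$tgt$fitted_ensembles, basis)
  h <- projection_histogram(proj, bins = 20)
  expect_equal(sum(h$density), 1, tolerance = 1e-12)
  expect_setequal(names(h$outlines), c("I", "II", "III"))
  for (o in h$outlines) {
    expect_true(all(o$outline <= o$occupied))   # outline subset of occupied
    expect_gt(sum(o$occupied), 0)
  }
  # all points in one bin -> that bin holds density 1
  one <- proj[rep(1, 5), ]
  class(one) <- class(proj)
  attr(one, "ensembles") <- attr(proj, "ensembles")
  attr(one, "n_modes") <- 2L
  h1 <- projection_histogram(one, bins = 4)
  expect_equal(max(h1$density), 1)
})
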