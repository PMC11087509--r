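# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# a 20-atom carbon chain with sub-milliAngstrom-representable coordinates
toy_chain <- function(n = 20L, seed = 42L) {
  set.seed(seed)
  structure_model(data.frame(
    atom_name = paste0("C", seq_len(n)), element = "C",
    residue_name = "CHN", residue_index = seq_len(n), chain_id = "A",
    x = round(stats::rnorm(n, 0, 4), 3),
    y = round(stats::rnorm(n, 0, 4), 3),
    z = round(seq(-6, 6, length.out = n), 3)), label = "chain")
}

# small fully built scenario (K = 3, reduced frame count) shared by the
# ensemble-fit and mode tests
small_scenario <- function() {
  fixture("small_scenario", function() {
    sc <- synthetic_scenario("paper_like", frames_per_replica = 21L,
                             timestep_ns = 100, seed = 5L)
    sys <- make_toy_system(sc)
    ens <- sample_ensembles(sc, sys)
    tgt <- make_target_map(sc, sys, ens)
    list(scenario = sc, system = sys, ensembles = ens, tgt = tgt)
  })
}

# full paper-like scenario (the stated world of the acceptance criteria);
# built once (~15 s) and shared by the acceptance tests
paper_scenario <- function(seed = 1L) {
  fixture(paste0("paper_scenario_", seed), function() {
    sc <- synthetic_scenario("paper_like", seed = seed)
    sys <- make_toy_system(sc)
    ens <- sample_ensembles(sc, sys)
    tgt <- make_target_map(sc, sys, ens)
    list(scenario = sc, system = sys, ensembles = ens, tgt = tgt)
  })
}

# three maps with disjoint one-hot supports plus a known mixture target
disjoint_mixture <- function(weights = c(0.20, 0.25, 0.55)) {
  g <- grid_spec(origin = c(0, 0, 0), spacing = 1, shape = c(4, 4, 4))
  maps <- lapply(1:3, function(i) {
    v <- array(0, dim = g$shape)
    v[i, 1, 1] <- 1
    density_map(g, v)
  })
  tv <- array(0, dim = g$shape)
  for (i in 1:3) tv[i, 1, 1] <- weights[i]
  mask <- array(TRUE, dim = g$shape)
  list(grid = g, maps = maps,
       target = density_map(g, tv, mask), weights = weights)
}

# small pool of single-frame maps plus target, for selection tests
selection_fixture <- function() {
  fixture("selection_fixture", function() {
    s <- small_scenario()
    pool <- build_structure_pool(s$tgt$fitted_ensembles,
                                 discard_ns = 500, interval_ns = 250)
    frames <- attr(pool, "frames")
    params <- spread_params(sigma = s$scenario$sigma_spread)
    pool_maps <- lapply(frames[seq(1, 105, by = 14)], function(f)
      spread_density(f[s$system$chain_index, , drop = FALSE],
                     s$scenario$grid, params))
    list(pool_maps = pool_maps, target = s$tgt$target)   # 8 maps
  })
}
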