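#' Synthetic scenario specification
#'
#' Describes a toy system with the statistical structure the analysis
#' assumes: a short flexible chain held in a rigid scaffold, K metastable
#' base conformations, per-conformation replica trajectories generated by
#' Gaussian positional perturbation, and a target map built as a known
#' weighted mixture of the per-conformation ensemble maps with optional
#' voxel noise.
#'
#' Presets:
#' * `"paper_like"` — K = 3 conformations, true weights (0.20, 0.25, 0.55)
#'   with the third state dominant, 5 replicas each (15 trajectories),
#'   production span 0..2000 ns so the default pool rule (discard 500 ns,
#'   extract every 250 ns) yields 105 structures. Frames are recorded every
#'   2.5 ns (a scaled-down recording rate; the pool lattice hits recorded
#'   frames exactly, and the 5 ps-rate rule is exercised on time vectors).
#' * `"minimal"` — K = 2, 2 replicas, short trajectories, small grid; for
#'   fast tests.
#'
#' @param preset `"paper_like"` or `"minimal"`, or NULL for fully manual.
#' @param n_chain_atoms atoms in the flexible chain (default 20).
#' @param k_conformations number of metastable base conformations K.
#' @param positional_noise_sigma per-atom isotropic displacement SD, A.
#' @param frames_per_replica recorded frames per trajectory.
#' @param timestep_ns recording interval, ns.
#' @param n_replicas trajectories per conformation.
#' @param true_weights mixture weights of the target map (length K).
#' @param map_noise_fraction SD of added i.i.d. voxel noise as a fraction of
#'   the noiseless target's SD (default 0).
#' @param grid a [grid_spec()] for all maps.
#' @param sigma_spread Gaussian spread width used for the target, A.
#' @param region_radius reference-region mask radius, A (default 5).
#' @param scaffold_jitter SD of random rigid-body displacement applied to
#'   whole frames before fitting, plus small scaffold atom noise, A.
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(preset = c("paper_like", "minimal"),
                               n_chain_atoms = 20L,
                               k_conformations = 3L,
                               positional_noise_sigma = 0.5,
                               frames_per_replica = 801L,
                               timestep_ns = 2.5,
                               n_replicas = 5L,
                               true_weights = NULL,
                               map_noise_fraction = 0,
                               grid = NULL,
                               sigma_spread = 1.1,
                               region_radius = 5,
                               scaffold_jitter = 0.2,
                               seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    if (preset == "minimal") {
      k_conformations <- 2L
      n_replicas <- 2L
      frames_per_replica <- 41L
      timestep_ns <- 50
      n_chain_atoms <- 10L
    }
  }
  if (is.null(true_weights)) {
    true_weights <- if (k_conformations == 3L) c(0.20, 0.25, 0.55)
                    else rep(1 / k_conformations, k_conformations)
  }
  stopifnot(length(true_weights) == k_conformations)
  validate_weights(true_weights)
  if (is.null(grid))
    grid <- grid_spec(origin = c(-15.5, -15.5, -15.5), spacing = 1,
                      shape = c(32L, 32L, 32L))
  structure(list(
    n_chain_atoms = as.integer(n_chain_atoms),
    k_conformations = as.integer(k_conformations),
    positional_noise_sigma = positional_noise_sigma,
    frames_per_replica = as.integer(frames_per_replica),
    timestep_ns = timestep_ns,
    n_replicas = as.integer(n_replicas),
    true_weights = true_weights,
    map_noise_fraction = map_noise_fraction,
    grid = grid,
    sigma_spread = sigma_spread,
    region_radius = region_radius,
    scaffold_jitter = scaffold_jitter,
    seed = as.integer(seed)), class = "synthetic_scenario")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# coordinate RMSD between two conformations (no fitting)
.coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Build the rigid scaffold and the base chain conformations
#'
#' The scaffold is a fixed ring of 12 phosphorus atoms (radius 10 A in the
#' z = 0 plane), standing in for the rigid environment the fit selection
#' uses. Each of the K base conformations is a chain of carbon atoms
#' threaded through the ring along z with a conformation-specific smooth
#' lateral deflection, so the conformations are well separated (pairwise
#' RMSD must exceed `2 * positional_noise_sigma`, otherwise an error).
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `scaffold` ([structure_model()]), `conformations`
#'   (list of K chain [structure_model()]s, labels "I", "II", ...),
#'   `topology` (scaffold + chain combined model), `chain_index` and
#'   `scaffold_index` (atom indices into the topology).
#' @export
make_toy_system <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_chain_atoms
  K <- scenario$k_conformations
  .with_seed(scenario$seed, {
    ring_n <- 12L
    theta <- 2 * pi * (0:(ring_n - 1L)) / ring_n
    scaffold_xyz <- cbind(10 * cos(theta), 10 * sin(theta), 0)
    scaffold <- structure_model(data.frame(
      atom_name = "P", element = "P", residue_name = "SCF",
      residue_index = seq_len(ring_n), chain_id = "S",
      x = scaffold_xyz[, 1], y = scaffold_xyz[, 2], z = scaffold_xyz[, 3]),
      label = "scaffold")

    z <- seq(-6, 6, length.out = n)
    phases <- stats::runif(K, 0, 2 * pi)
    conformations <- vector("list", K)
    for (k in seq_len(K)) {
      # distinct smooth lateral deflections per metastable state
      amp <- 2.0 + 0.8 * (k - 1)
      x <- amp * sin(pi * (z + 6) / 12 + phases[k]) +
        1.2 * cos(2 * pi * k * (z + 6) / 12)
      y <- amp * cos(pi * (z + 6) / 12 + phases[k]) -
        1.2 * sin(2 * pi * k * (z + 6) / 12)
      conformations[[k]] <- structure_model(data.frame(
        atom_name = "C", element = "C", residue_name = "CHN",
        residue_index = seq_len(n), chain_id = "A",
        x = x, y = y, z = z), label = as.character(as.roman(k)))
    }
    if (K > 1L) {
      for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
        r <- .coord_rmsd(coords(conformations[[i]]), coords(conformations[[j]]))
        if (r <= 2 * scenario$positional_noise_sigma)
          stop(sprintf(
            "base conformations %d and %d are not distinguishable (RMSD %.2f <= 2*noise %.2f)",
            i, j, r, 2 * scenario$positional_noise_sigma))
      }
    }
    topo_atoms <- rbind(scaffold$atoms, conformations[[1]]$atoms)
    topology <- structure_model(topo_atoms, label = "scaffold+chain")
    list(scaffold = scaffold, conformations = conformations,
         topology = topology,
         scaffold_index = seq_len(ring_n),
         chain_index = ring_n + seq_len(n))
  })
}

.random_small_rigid <- function(jitter) {
  # small random rotation (~jitter/10 rad per axis) + translation (SD jitter)
  ang <- stats::rnorm(3, 0, jitter / 10)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  list(rotation = Rz %*% Ry %*% Rx, translation = stats::rnorm(3, 0, jitter))
}

#' Sample replica trajectories around each base conformation
#'
#' Each frame is the base conformation plus isotropic Gaussian displacement
#' (`positional_noise_sigma`) on the chain atoms; the whole frame (scaffold
#' included) is then displaced by a small random rigid-body transform and the
#' scaffold atoms receive tiny extra noise, so frames must be refit to the
#' reference scaffold before analysis (see [fit_ensemble()]).
#'
#' @param scenario a [synthetic_scenario()].
#' @param system a [make_toy_system()] result.
#' @return list of `K * n_replicas` [trajectory_ensemble()]s, ordered by
#'   conformation then replica.
#' @export
sample_ensembles <- function(scenario, system) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  K <- scenario$k_conformations
  nf <- scenario$frames_per_replica
  n_atoms <- nrow(system$topology$atoms)
  sigma <- scenario$positional_noise_sigma
  jit <- scenario$scaffold_jitter
  times <- (seq_len(nf) - 1L) * scenario$timestep_ns
  scaffold_xyz <- coords(system$scaffold)
  out <- vector("list", K * scenario$n_replicas)
  for (k in seq_len(K)) {
    base <- coords(system$conformations[[k]])
    for (r in seq_len(scenario$n_replicas)) {
      arr <- .with_seed(scenario$seed + 1000L * k + r, {
        a <- array(0, dim = c(n_atoms, 3L, nf))
        for (i in seq_len(nf)) {
          chain <- base + matrix(stats::rnorm(length(base), 0, sigma),
                                 ncol = 3)
          scaf <- scaffold_xyz +
            matrix(stats::rnorm(length(scaffold_xyz), 0, jit / 4), ncol = 3)
          frame <- rbind(scaf, chain)
          if (jit > 0) frame <- apply_transform(frame, .random_small_rigid(jit))
          a[, , i] <- frame
        }
        a
      })
      out[[(k - 1L) * scenario$n_replicas + r]] <-
        trajectory_ensemble(system$topology, arr, times,
                            origin_conformation = system$conformations[[k]]$label,
                            replica_id = r)
    }
  }
  out
}

#' Build the synthetic target map with known ground truth
#'
#' Fits every ensemble to the reference scaffold, computes the K
#' per-conformation ensemble maps (chain atoms only), mixes them with the
#' scenario's true weights, optionally adds i.i.d. Gaussian voxel noise
#' (SD = `map_noise_fraction` times the noiseless map's SD), and masks the
#' result at `region_radius` around the base conformations.
#'
#' @param scenario a [synthetic_scenario()].
#' @param system a [make_toy_system()] result.
#' @param ensembles the [sample_ensembles()] output (fitted or raw; raw
#'   frames are fitted here).
#' @param noise_seed optional separate seed for the voxel noise (defaults to
#'   `scenario$seed + 777`), so noise realizations can be varied while the
#'   ensembles are held fixed.
#' @param precomputed optionally, the result of a previous call on the same
#'   scenario/system/ensembles: its fitted ensembles and ensemble maps are
#'   reused and only the mixing, noise and masking are redone (useful when
#'   varying `noise_seed`).
#' @return list with `target` (masked [density_map()]), `ensemble_maps`
#'   (list of K per-conformation maps), `fitted_ensembles`, and `truth`
#'   (weights, sigma, noise fraction, seed) — a record that round-trips
#'   through JSON.
#' @export
make_target_map <- function(scenario, system, ensembles, noise_seed = NULL,
                            precomputed = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (is.null(noise_seed)) noise_seed <- scenario$seed + 777L
  if (!is.null(precomputed)) {
    fitted <- precomputed$fitted_ensembles
    ens_maps <- precomputed$ensemble_maps
  } else {
    params <- spread_params(sigma = scenario$sigma_spread)
    ref_xyz <- coords(system$scaffold)
    fitted <- lapply(ensembles, fit_ensemble, reference = ref_xyz,
                     selection = system$scaffold_index)
    tags <- vapply(fitted, `[[`, character(1), "origin_conformation")
    labels <- vapply(system$conformations, `[[`, character(1), "label")
    ens_maps <- lapply(labels, function(lab) {
      members <- fitted[tags == lab]
      frames <- list()
      for (ens in members)
        for (i in seq_len(n_frames(ens)))
          frames[[length(frames) + 1L]] <- ens$coords[system$chain_index, , i]
      ensemble_density(frames, scenario$grid, params)
    })
  }
  mix <- weighted_average_map(ens_maps, scenario$true_weights)
  vals <- mix$values
  if (scenario$map_noise_fraction > 0) {
    noise_sd <- scenario$map_noise_fraction * stats::sd(vals)
    vals <- vals + .with_seed(noise_seed,
      array(stats::rnorm(length(vals), 0, noise_sd), dim = dim(vals)))
  }
  target <- extract_reference_region(density_map(scenario$grid, vals),
                                     system$conformations,
                                     radius = scenario$region_radius)
  list(target = target,
       ensemble_maps = ens_maps,
       fitted_ensembles = fitted,
       truth = list(weights = scenario$true_weights,
                    sigma = scenario$sigma_spread,
                    map_noise_fraction = scenario$map_noise_fraction,
                    seed = scenario$seed,
                    noise_seed = noise_seed))
}
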