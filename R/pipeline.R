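#' Run configuration
#'
#' Aggregates every tunable of the end-to-end workflow. All defaults equal
#' the reference analysis parameters: spread width 0.11 nm, 5 A reference
#' region, pool rule discard 500 ns / extract every 250 ns, weight lattice
#' step 0.01, replica convergence 1e-2. The internal length unit is Angstrom
#' everywhere; the nm-quoted spread width is converted exactly once, here.
#'
#' @param preset synthetic preset name (`"paper_like"` or `"minimal"`), or
#'   NULL when real input paths are supplied.
#' @param sigma_nm Gaussian spread width in nm (converted to A internally).
#' @param region_radius_A reference-region radius, A.
#' @param discard_ns,interval_ns frame-pool rule, ns.
#' @param grid_step weight-lattice step.
#' @param n_structures,n_replicas,convergence_tol,max_iterations selection
#'   settings (see [selection_config()]).
#' @param sigma_scan_nm numeric vector of spread widths to scan, nm.
#' @param pca_sample_ns covariance subsampling interval, ns.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... additional fields stored verbatim (e.g. input paths).
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = "paper_like", sigma_nm = 0.11,
                       region_radius_A = 5, discard_ns = 500,
                       interval_ns = 250, grid_step = 0.01,
                       n_structures = 5L, n_replicas = 5L,
                       convergence_tol = 1e-2, max_iterations = 10000L,
                       sigma_scan_nm = seq(0.05, 0.15, by = 0.01),
                       pca_sample_ns = 1.0,
                       out_dir = tempfile("ensemblefit_run_"), seed = 1L,
                       ...) {
  cfg <- list(preset = preset, sigma_nm = sigma_nm,
              sigma_A = sigma_nm * 10,           # single nm -> A conversion point
              region_radius_A = region_radius_A,
              discard_ns = discard_ns, interval_ns = interval_ns,
              grid_step = grid_step, n_structures = as.integer(n_structures),
              n_replicas = as.integer(n_replicas),
              convergence_tol = convergence_tol,
              max_iterations = as.integer(max_iterations),
              sigma_scan_nm = sigma_scan_nm, pca_sample_ns = pca_sample_ns,
              out_dir = out_dir, seed = as.integer(seed), ...)
  stopifnot(cfg$sigma_nm > 0, cfg$region_radius_A >= 0, cfg$interval_ns > 0,
            cfg$grid_step > 0, cfg$grid_step <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a JSON file
#' @param path JSON file with fields matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Write a run configuration to JSON (round-trips through [read_run_config()])
#' @param cfg a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$sigma_A <- NULL                 # derived; recomputed on read
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[ensemblefit] ", fmt), ...))
}

#' Run the full synthetic-scenario pipeline
#'
#' Executes the workflow end to end on a synthetic scenario: generate the
#' toy system and trajectories, fit frames to the scaffold, build the
#' structure pool, compute per-conformation ensemble maps and the target,
#' calibrate the spread width, optimize mixture weights, select the
#' correlation-optimal structure set, and run the conformational-mode PCA.
#' Every stage's artifacts are written under `cfg$out_dir`, together with a
#' JSON manifest of inputs, parameters, seeds and per-stage correlations.
#' Reruns with the same config and seed reproduce all numeric outputs.
#'
#' @param cfg a [run_config()].
#' @param verbose log stage progress (default TRUE).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("ensemblefit")),
                   config = unclass(cfg), stages = list())
  fail <- function(stage, e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  stage <- "synth"
  res <- tryCatch({
    scenario <- synthetic_scenario(preset = cfg$preset, seed = cfg$seed,
                                   sigma_spread = cfg$sigma_A,
                                   region_radius = cfg$region_radius_A)
    system <- make_toy_system(scenario)
    ensembles <- sample_ensembles(scenario, system)
    write_pdb(system$conformations, file.path(cfg$out_dir, "conformations.pdb"))
    list(scenario = scenario, system = system, ensembles = ensembles)
  }, error = function(e) fail(stage, e))
  scenario <- res$scenario; system <- res$system; ensembles <- res$ensembles
  .log_stage(verbose, "synth: %d ensembles of %d frames",
             length(ensembles), scenario$frames_per_replica)
  manifest$stages$synth <- list(n_ensembles = length(ensembles),
                                frames_per_replica = scenario$frames_per_replica,
                                true_weights = scenario$true_weights)

  stage <- "target"
  tgt <- tryCatch(make_target_map(scenario, system, ensembles),
                  error = function(e) fail(stage, e))
  write_map(tgt$target, file.path(cfg$out_dir, "target.mrc"))
  jsonlite::write_json(tgt$truth, file.path(cfg$out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(verbose, "target map built (mask %d voxels)", sum(tgt$target$mask))

  stage <- "pool"
  pool <- tryCatch(
    build_structure_pool(tgt$fitted_ensembles, cfg$discard_ns, cfg$interval_ns),
    error = function(e) fail(stage, e))
  utils::write.table(pool, file.path(cfg$out_dir, "pool_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .log_stage(verbose, "pool: %d structures", nrow(pool))
  manifest$stages$pool <- list(n_structures = nrow(pool))

  stage <- "calibrate_sigma"
  calib <- tryCatch({
    calibrate_sigma(coords(system$conformations[[1]]), tgt$target,
                    sigmas = cfg$sigma_scan_nm * 10)
  }, error = function(e) fail(stage, e))
  utils::write.table(
    data.frame(sigma_nm = calib$scan$sigma / 10, rho = calib$scan$rho),
    file.path(cfg$out_dir, "sigma_scan.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  .log_stage(verbose, "sigma calibration: best sigma = %.3f nm",
             calib$best_sigma / 10)
  manifest$stages$calibrate_sigma <- list(best_sigma_nm = calib$best_sigma / 10,
                                          scan = calib$scan)

  stage <- "weights"
  wfit <- tryCatch(
    optimize_weights(tgt$ensemble_maps, tgt$target, cfg$grid_step),
    error = function(e) fail(stage, e))
  jsonlite::write_json(list(weights = wfit$weights, rho = wfit$rho,
                            n_voxels = wfit$n_voxels),
                       file.path(cfg$out_dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(wfit$surface))
    utils::write.table(wfit$surface, file.path(cfg$out_dir, "weight_surface.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  .log_stage(verbose, "weights: (%s), rho = %.4f",
             paste(sprintf("%.2f", wfit$weights), collapse = ", "), wfit$rho)
  manifest$stages$weights <- list(weights = wfit$weights, rho = wfit$rho)

  stage <- "select"
  sel <- tryCatch({
    params <- spread_params(sigma = cfg$sigma_A)
    frames <- attr(pool, "frames")
    pool_maps <- lapply(frames, function(f)
      spread_density(f[system$chain_index, , drop = FALSE], scenario$grid, params))
    scfg <- selection_config(cfg$n_structures, cfg$n_replicas,
                             cfg$convergence_tol, cfg$max_iterations,
                             seed = cfg$seed, grid_step = cfg$grid_step)
    optimize_structure_set(pool_maps, tgt$target, scfg)
  }, error = function(e) fail(stage, e))
  jsonlite::write_json(list(member_indices = sel$member_indices,
                            weights = sel$weights, rho = sel$rho,
                            iterations = sel$iterations,
                            replica_rhos = sel$replica_rhos,
                            converged = sel$converged),
                       file.path(cfg$out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(verbose, "selection: N = %d, rho = %.4f (%s)",
             length(sel$member_indices), sel$rho,
             if (sel$converged) "converged" else "not converged")
  manifest$stages$select <- list(rho = sel$rho, converged = sel$converged,
                                 member_indices = sel$member_indices)

  stage <- "pca"
  pca <- tryCatch({
    basis <- pca_modes(tgt$fitted_ensembles, selection = system$chain_index,
                       sample_interval_ns = cfg$pca_sample_ns)
    proj <- project_frames(tgt$fitted_ensembles, basis, n_modes = 2L)
    utils::write.table(
      as.data.frame(proj)[, c("origin_conformation", "replica_id",
                              "time_ns", "pc1", "pc2")],
      file.path(cfg$out_dir, "projections.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    list(basis = basis, projections = proj)
  }, error = function(e) fail(stage, e))
  .log_stage(verbose, "pca: two-mode variance share = %.3f",
             sum(pca$basis$variance_fractions[1:2]))
  manifest$stages$pca <- list(
    variance_fractions = pca$basis$variance_fractions[1:5],
    two_mode_share = sum(pca$basis$variance_fractions[1:2]))

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
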