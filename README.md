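# ensemblefit

Quantifying how a *conformational ensemble* explains an experimental cryo-EM
density map.

When a flexible molecule — e.g. a peptide bound in the ribosomal exit
tunnel — populates several metastable conformations, no single atomic model
accounts for the observed density. `ensemblefit` compares
molecular-dynamics ensembles against a density map and answers two
questions quantitatively:

* **How much does each metastable state contribute?** Per-state ensemble
  maps m₁…m_K are synthesized from trajectory frames by Gaussian spreading
  (atom *i* contributes `a_i (2πσ²)^(-3/2) exp(-|r-r_i|²/2σ²)`, default
  σ = 1.1 Å) and mixed with simplex weights w (w_k ≥ 0, Σw_k = 1) chosen to
  maximize the Pearson correlation ρ with the target over a masked
  reference region (voxels within 5 Å of the modeled conformers). For
  K ≤ 3 the search is exhaustive on the 0.01 barycentric lattice — the full
  correlation surface over the weight triangle is returned.
* **How many structures are needed?** From a frame pool (discard the first
  500 ns of each trajectory, extract every 250 ns; 15 × 2-µs trajectories
  give 105 structures), a set of N structures is selected by iterative
  stochastic replacement: swap a random member for a random non-member,
  re-optimize weights, accept only strict ρ improvement. Five replicas run
  until their best correlations agree within 10⁻² (and the searches have
  gone quiet), guarding against local maxima.

Supporting machinery: PDB and MRC/CCP4 readers/writers (axis-permutation
aware), multi-frame XYZ trajectories, Kabsch superposition, spread-width
calibration by correlation scan, PCA of conformational modes with
projections, extreme-state extraction and 2-D histograms, an
exhaustive-enumeration selection oracle, a synthetic-data generator with
known ground truth, and a CLI.

## Worked example

```r
library(ensemblefit)

# a synthetic world with known truth: 3 metastable states of a 20-atom
# chain in a rigid scaffold, 15 trajectories, target map mixed with
# weights (0.20, 0.25, 0.55)
scenario  <- synthetic_scenario("paper_like", seed = 1)
system    <- make_toy_system(scenario)
ensembles <- sample_ensembles(scenario, system)
tgt       <- make_target_map(scenario, system, ensembles)

# (1) contribution of each metastable state
fit <- optimize_weights(tgt$ensemble_maps, tgt$target)
fit$weights
#> [1] 0.20 0.25 0.55
fit$rho
#> [1] 1

# (2) structure pool and minimal structure set
pool  <- build_structure_pool(tgt$fitted_ensembles)
nrow(pool)
#> [1] 105
frames <- attr(pool, "frames")
pm <- lapply(frames, function(f)
  spread_density(f[system$chain_index, ], scenario$grid, spread_params(1.1)))
sel <- optimize_structure_set(pm, tgt$target, selection_config(5, seed = 2))
sel
#> selection_result: N = 5, rho = 0.99471 (converged after 531 iterations)
#>   members: 23, 42, 73, 75, 103
#>   weights: 0.202, 0.252, 0.230, 0.185, 0.131

# (3) spread-width calibration (self-consistency: target generated at 1.1 A)
ref <- extract_reference_region(
  spread_density(system$conformations[[1]], scenario$grid, spread_params(1.1)),
  system$conformations[[1]], radius = 5)
calibrate_sigma(system$conformations[[1]], ref,
                sigmas = seq(0.05, 0.15, 0.01) * 10)$best_sigma
#> [1] 1.1
```

The recovered weights equal the generating mixture exactly (the third state
dominant at 0.55); five optimally chosen structures — drawn from all three
sub-ensembles — already reproduce the target almost perfectly (ρ = 0.995 vs
0.928 for the equally weighted 105-structure pool); and the calibration
scan recovers the generating spread width 1.1 Å = 0.11 nm.

## Command line

```sh
ensemblefit synth --preset paper_like --seed 7 --out-dir scenario/
ensemblefit weights --target ref.mrc --ensemble I.mrc --ensemble II.mrc \
    --ensemble III.mrc --grid-step 0.01 --out weights.json
ensemblefit select --target ref.mrc --pool-maps a.mrc,b.mrc,... \
    --n 5 --replicas 5 --tol 1e-2 --seed 1 --out selection.json
```

(the wrapper lives in `inst/exec/`; equivalently call
`ensemblefit::ensemblefit_cli(c("synth", ...))`).

See `vignettes/ensemblefit-methods.Rmd` for the model, its assumptions,
what the synthetic generator does and does not emulate, and the numerical
design choices.
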