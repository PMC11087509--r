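---
title: "Fitting conformational ensembles to cryo-EM density: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting conformational ensembles to cryo-EM density: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensemblefit)
```

## The problem

A flexible ligand — the motivating case is a proline-rich antimicrobial
peptide bound inside the polypeptide exit tunnel of the large ribosomal
subunit — can populate several metastable conformations at once. A single
refined atomic model then under-describes the experimental cryo-EM density,
and the natural questions are quantitative: *how much does each metastable
state contribute to the observed density, and how many distinct structures
are needed to explain it?*

`ensemblefit` answers these questions by comparing molecular-dynamics (MD)
conformational ensembles against an experimental density map through four
linked procedures:

1. **Density synthesis.** Atomic structures are converted to maps by
   isotropic Gaussian spreading on the experimental grid.
2. **Spread-width calibration.** The Gaussian width σ is chosen by scanning
   candidate widths and maximizing map correlation against the reference.
3. **Simplex weight fitting.** Per-state ensemble maps are mixed with
   nonnegative, unit-sum weights chosen to maximize the Pearson correlation
   ρ with the target over a masked reference region.
4. **Structure-set selection.** A minimal set of N structures whose
   optimally weighted map best correlates with the target is found by
   iterative stochastic replacement from a trajectory frame pool, run in
   replicas with a cross-replica agreement criterion.

## The model

### Gaussian spreading

Atom $i$ at position $\mathbf{r}_i$ contributes

$$\rho_i(\mathbf{r}) = a_i\,(2\pi\sigma^2)^{-3/2}
  \exp\!\left(-\frac{\lVert\mathbf{r}-\mathbf{r}_i\rVert^2}{2\sigma^2}\right)$$

evaluated at voxel centers within $4\sigma$ of the atom (truncation error
below $10^{-4}$ of the atom's mass). The map is the sum over atoms. The
amplitude $a_i$ is 1 by default, or the element's atomic number
(`amplitude_mode = "atomic_number"`); because all downstream comparisons use
Pearson correlation, which is invariant to affine rescaling, the amplitude
convention does not affect fitted weights. A per-element multi-Gaussian
coefficient table would refine absolute densities but not correlations, so a
single tunable width is the core model and the calibration scan absorbs the
difference.

The default width is σ = 1.1 Å (0.11 nm). Internally every length is in
Ångström — PDB and MRC are Å-native — and the nm-quoted width is converted
exactly once, at configuration parsing (`run_config(sigma_nm = )`).

An *ensemble map* is the unweighted arithmetic mean of per-frame maps. Mean
versus sum is immaterial for correlation (scale invariance); the mean keeps
single-structure scale and is asserted equivalent in the tests.

### Reference region and correlation

All correlations are computed over a mask: the voxels whose centers lie
within a fixed radius (default 5 Å) of any atom of the modeled
conformations. Voxels are addressed at their centers —
`origin + (i,j,k) * spacing` — which is the single grid convention used by
the readers, writers, spreading, and masking alike. Correlation is
mean-subtracted Pearson over masked voxels. An unmasked (full-box) option
exists by simply omitting the mask.

### Weight fitting on the simplex

Given per-state ensemble maps $m_1,\dots,m_K$ and target $t$, the package
maximizes

$$\rho(w) = \mathrm{corr}\!\left(\textstyle\sum_k w_k m_k,\; t\right),
\qquad w_k \ge 0.$$

Only the *direction* of $w$ is identifiable (Pearson is scale-invariant), so
weights are reported on the unit simplex. Writing $X$ for the matrix of
masked, centered map values and $b = X^\top t$, $G = X^\top X$,

$$\rho(w) = \frac{w^\top b}{\sqrt{w^\top G w \cdot t^\top t}},$$

so the whole search runs on $K\times K$ Gram matrices, independent of grid
size. For $K \le 3$ the search is exhaustive over the barycentric lattice
with step 0.01 (the machine twin of the triangular weight-correlation
surface plot), ties broken toward the lexicographically smallest vector.
For $K > 3$ the lattice is replaced by an exact active-set enumeration: by
the KKT conditions the optimal support $S$ satisfies
$w_S \propto G_S^{-1} b_S \ge 0$, and all $2^K-1$ supports are checked
(feasible up to $K \approx 14$; beyond that a multi-start bounded
quasi-Newton ascent is used).

### Structure-set selection

From each trajectory the frame pool keeps the frames on the extraction
lattice: discard the first 500 ns of production, then take every 250 ns up
to and including the last recorded time, snapping to the nearest recorded
frame within half the recording timestep. Fifteen 2000-ns trajectories give
the reference pool size of 105. ("First 500 ns" counts from production
start, not from the restrained equilibration — the only reading consistent
with that pool size.)

Selection then searches for the size-N subset of pool maps whose optimally
weighted mix maximizes ρ. Each replica starts from a uniform random subset;
each iteration swaps a uniformly random member for a uniformly random
non-member and re-optimizes the weights; the move is accepted only on
*strict* improvement (equal-ρ proposals are rejected, which guarantees the
accepted-ρ sequence is strictly increasing and terminates). The proposal
excludes current members because a null swap can never be accepted under
strict improvement.

**Convergence.** Replicas stop when their best correlations agree within
`convergence_tol` (default $10^{-2}$). Agreement alone proved unreliable:
with a small pool, replicas can agree within $10^{-2}$ during the first few
iterations while all of them are still actively climbing, so the
implementation additionally requires *quiescence* — no replica has accepted
a move within the last pool-size iterations — before trusting agreement.
(Diagnosed on 8-map pools: with agreement alone, 7 of 50 seeded runs
stopped at a shared suboptimum around iteration 8; with the quiescence
guard all 50 reach the exhaustive-enumeration optimum.) A `max_iterations`
cap (default 10⁴, absent from the agreement criterion itself) bounds the
runtime; reaching it sets `converged = FALSE`.

**Reproducibility.** One master seed; replica *r* runs on an independent
stream seeded `seed + r`, with per-replica RNG state saved between
lock-stepped iterations — results are bit-reproducible for a fixed seed.

An exhaustive-enumeration oracle (`brute_force_select`) provides the exact
maximizer for small pools and is used in the tests to validate the
stochastic search end to end.

### Conformational modes

Principal component analysis runs on the mass-unweighted Cartesian
covariance (1/(n−1) normalization) of selected atoms — typically the
peptide heavy atoms — over frames subsampled at 1 ns, after rigid-body
(Kabsch) superposition of every frame onto a common reference using a
fitting selection (phosphate atoms for real ribosome data; the scaffold
ring in the synthetic system). Projections, by contrast, are computed at
full recording resolution. Eigenvector signs are fixed so the
largest-magnitude component is positive, making projections deterministic
across runs and LAPACK builds. Mass weighting is available behind a flag
(`mass_weighted = TRUE`, using atomic numbers as the mass proxy) but is off
by default: the heavy-atom selection is specified, mass weighting is not,
and variance fractions are unaffected by the choice of normalization.

The Kabsch superposition rejects reflections by sign-correcting the
smallest singular vector, so the returned rotation always has det +1; a
mirror-image input therefore fits with nonzero RMSD rather than silently
inverting chirality.

## The synthetic world

The generator emulates the statistical structure the analysis assumes, not
the physics that produces it:

* a **rigid scaffold** (a ring of 12 phosphorus atoms, radius 10 Å) standing
  in for the tunnel environment: it anchors the rigid-body fit exactly as
  the phosphate selection does for real data, and contributes nothing to
  the density — mirroring the fit-on-phosphates / spread-the-peptide
  separation;
* **K = 3 metastable states** of a 20-atom chain threaded through the ring,
  built as distinct smooth lateral deflections, with the constraint that
  pairwise base RMSD exceeds twice the positional noise so states are
  distinguishable (violations raise an error rather than silently producing
  an unidentifiable scenario);
* **trajectories** that never cross between states: each frame is its base
  conformation plus isotropic Gaussian displacement (default σ = 0.5 Å, a
  typical heavy-atom thermal fluctuation scale), plus a small random
  rigid-body displacement of the whole frame that the scaffold fit must
  remove — so metastability is by construction, matching the observation
  that no transitions occur on the simulated timescale;
* a **target map** mixed from the per-state ensemble maps with known
  weights — default (0.20, 0.25, 0.55), echoing the dominant-third-state
  composition of the reference analysis — plus optional i.i.d. Gaussian
  voxel noise scaled to a fraction of the map SD.

The `paper_like` preset uses 3 states × 5 replicas of 2000 ns so the pool
rule yields 105 structures. Frames are recorded every 2.5 ns rather than
every 5 ps: materializing 15 × 400,000 frames is pointless for a toy, the
extraction lattice hits recorded frames exactly at either rate, and the
5 ps bookkeeping is exercised separately on raw time vectors. The `minimal`
preset (K = 2, short trajectories) exists for fast tests.

What a green test does **not** establish: real cryo-EM noise is colored and
anisotropic, real ensembles overlap in density far more than these
well-separated toys, and the per-frame independence of the generator has no
autocorrelation structure. Weight recovery to ±0.01 here demonstrates the
estimator is correct, not that real-data weights carry that precision.

## Numerical choices

* Gaussian truncation at 4σ; a warning (not an error) if grid spacing
  exceeds 2σ (undersampling) or an atom lies entirely outside the grid.
* Pool-lattice snapping tolerance is half the recording timestep — exact
  time equality would be fragile on discrete recording grids.
* Weight-lattice ties → lexicographically smallest vector; σ-scan ties →
  smaller σ; extreme-state ties → earliest frame time. All three are
  arbitrary but fixed, so results are deterministic.
* Degenerate inputs fail loudly: zero-variance targets, empty masks,
  collinear fit selections, and topology mismatches are errors.
* MRC files are written in mode 2 (float32) with ISPG = 1, cell =
  spacing × shape, and the origin in both the ORIGIN words and the
  NXSTART-style words; readers canonicalize any MAPC/MAPR/MAPS permutation.
* The run configuration is a JSON document (the only structured-text parser
  guaranteed present); it round-trips exactly.

## Worked example

```{r example, eval = FALSE}
scenario <- synthetic_scenario("paper_like", seed = 1)
system <- make_toy_system(scenario)
ensembles <- sample_ensembles(scenario, system)
tgt <- make_target_map(scenario, system, ensembles)

# how much does each metastable state contribute?
optimize_weights(tgt$ensemble_maps, tgt$target)$weights
#> [1] 0.20 0.25 0.55   (the generating weights, recovered)

# how many structures explain the map?
pool <- build_structure_pool(tgt$fitted_ensembles)   # 105 structures
```

## Known limitations

* Single-Gaussian atoms: no electron scattering factors, B-factors, or
  resolution filtering — adequate for correlation-based fitting, not for
  absolute density comparison.
* Orthogonal grids only; no symmetry-aware map handling or half-map/FSC
  machinery.
* The selection search is a strict hill climb per replica; multi-replica
  agreement is its only guard against local maxima. For pools far larger or
  rougher than those tested, more replicas (or a larger
  `convergence_tol` examined critically) may be needed.
* Binary trajectory formats (XTC/DCD) are not read; multi-model PDB and
  multi-frame XYZ are the supported interchange formats.
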