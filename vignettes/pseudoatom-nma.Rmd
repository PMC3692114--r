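---
title: "Coarse-grained normal mode analysis of EM density volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained normal mode analysis of EM density volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volnma)
```

## The problem

Single-particle electron microscopy routinely produces density maps of large
macromolecular complexes at 3–20 Å resolution — too coarse for an atomic
model, but detailed enough to ask how the complex *moves*. Normal mode
analysis (NMA) answers that question for atomic structures by diagonalizing
the Hessian of a harmonic energy model; the low-frequency eigenvectors
reproduce the large, collective conformational changes seen experimentally
(domain closures, channel openings, hinge bending). `volnma` brings the same
analysis to density volumes: the map is first condensed into a *pseudo-atomic*
representation — a set of weighted 3D Gaussians whose rendered sum reproduces
the map within a target error — and NMA is then run on an elastic network
built over those pseudo-atoms.

The pipeline has four steps, mirroring how a structural biologist would work
through a new map:

1. **mask** — zero out solvent/noise below a density threshold;
2. **convert** — fit the masked density with weighted Gaussians
   (`fit_pseudo_atoms()`);
3. **nma** — build a cutoff elastic network and compute modes
   (`build_network()`, `compute_modes()`), with a collectivity score per
   mode;
4. **animate** — deform the pseudo-atomic model along selected modes and
   export multi-model PDBs and per-frame volumes.

## The density model

A pseudo-atom *i* is an isotropic Gaussian of unit peak amplitude, weight
$w_i > 0$ and shared standard deviation $\sigma$:

$$\hat V(\mathbf r) = \sum_{i=1}^{N} w_i
  \exp\!\left(-\frac{\lVert \mathbf r-\mathbf r_i\rVert^2}{2\sigma^2}\right).$$

$\sigma$ is specified in voxel units (`sigma_voxels`) and stored in Å. The
rule of thumb is $\sigma \approx$ one voxel: small enough that the structure
is filled with enough pseudo-atoms for stable modes, large enough that the
atom count stays manageable. Useful values run from 1 (finer models, more
atoms) to 5 (coarser models); for very finely sampled maps, downsample first
(`downsample()`) rather than fitting tens of thousands of atoms — the atom
count forwarded to the NMA step is capped at 9999 regardless.

The approximation error is the masked relative L1 deviation
$\sum_M |V-\hat V| \,/\, \sum_M |V|$, reported as a fraction. L1 is robust
to bright outliers and lands in the same 0.05–0.06 regime practitioners
target; 0.06 is the default `target_error`.

### The fitting algorithm

`fit_pseudo_atoms()` grows the model adaptively:

1. seed `initial_atoms` (default 100) positions by sampling voxel centres
   with probability proportional to the masked density;
2. refine: each inner round applies multiplicative non-negative weight
   updates ($w \leftarrow w \cdot A^{\mathsf T}V / A^{\mathsf T}\hat V$, the
   Lee–Seung NNLS update, monotone in the squared residual) followed by one
   per-atom Gauss–Newton position step with backtracking on the L1 error;
   rounds stop when the relative improvement drops below `convergence_tol`
   (round counts and update counts shrink once $N > 1500$, where the model
   is locally overparameterized and cheap rounds win);
3. grow: if the error is still above target and $N < 9999$, plant a batch of
   `max(32, N/10)` new atoms at local maxima of the positive residual field
   (adjacent high-residual voxels describe one underfit bump, not several)
   and refine again.

Three housekeeping rules keep the model clean: atoms whose weight collapses
below $10^{-6}$ of the maximum are pruned; in small models ($N \le 512$,
where a redundant pair visibly distorts the solution) atoms closer than
$0.75\sigma$ are merged into their weight-averaged centre whenever the refit
does not lose accuracy; and an outer iteration that fails to lower the error is
rolled back and retried with fresh stochastic jitter, up to five consecutive
stalls. Rollback makes the recorded error history non-increasing by
construction. Pruning and merging are skipped once $N$ reaches `max_atoms`,
so a run that hits the cap terminates with exactly that atom count. The
initializer's seed is part of the configuration (default 0), making every
fit bit-reproducible.

Gaussians are truncated at $4\sigma$ when rendered (amplitude
$< 4\times10^{-4}$), which keeps rendering linear in the atom count.

## The elastic network and its modes

Two pseudo-atoms closer than a cutoff $R_c$ are joined by a spring of
uniform stiffness $C$ whose rest length is their reference distance
$d^0_{ij}$:

$$E = \frac{C}{2} \sum_{d^0_{ij} < R_c} (d_{ij} - d^0_{ij})^2 .$$

The reference conformation is the energy minimum by construction, so no
minimization is needed. $C$ only sets the energy scale (default 1, arbitrary
units), and all pseudo-atoms carry unit mass: pseudo-atoms have no physical
mass, and uniform masses leave mode shapes unchanged up to an overall
frequency scaling.

The choice of $R_c$ is the critical parameter. `suggest_cutoff()` implements
the ~95% rule: take the 95th-percentile of the per-atom nearest-neighbour
distances (inflated by a relative $10^{-6}$ so ties fall strictly inside the
cutoff, guaranteeing the stated coverage), and, if the resulting network is
disconnected, raise it to the bottleneck edge of the Euclidean minimum
spanning tree so that one connected component remains.
`nn_distance_histogram()` exposes the distance distribution behind the rule.

`build_hessian()` assembles the analytic second derivatives: each spring
contributes the rank-one block
$C\,\Delta\mathbf r\,\Delta\mathbf r^{\mathsf T}/\lVert\Delta\mathbf r\rVert^2$.
`compute_modes()` takes the `n_modes` lowest eigenpairs — dense
`eigen()` for $3N \le 3000$, and a shift-invert Lanczos iteration on the
sparse Hessian above that (factored once with a sparse Cholesky of
$H + \tau I$, $\tau = 10^{-6}\max\operatorname{diag}H$, full
reorthogonalization, Krylov space grown until every requested pair's
residual is below $10^{-9}\lVert H\rVert$). The two paths agree to tight
tolerance and are cross-checked in the test suite. Mode vectors are unit
norm with a deterministic sign (largest-magnitude component positive);
eigenvalues below $10^{-6}\max(\lambda, 1)$ are flagged rigid. A connected
network has exactly six such modes (three translations, three rotations), so
the first flexible mode has index 7 — but note that pseudo-atoms fit into
weak fringe density can be under-connected and contribute additional
near-zero "floppy" modes at small cutoffs; these are flagged rigid too and
excluded from flexible-mode analyses.

## Collectivity, deformation, overlap

The collectivity of a mode,
$\kappa = N^{-1}\exp(-\sum_i \alpha u_i^2 \ln \alpha u_i^2)$ with
$\alpha = 1/\sum_i u_i^2$ and $u_i$ the per-atom displacement magnitude, is
the exponential entropy of the displacement distribution: $\kappa = 1$ when
every atom moves with equal magnitude, $1/N$ when a single atom moves.
Functionally relevant modes are usually the low-frequency, high-$\kappa$
ones.

Deformations are linear: $\mathbf r' = \mathbf r + \sum_n a_n \mathbf u_n$,
with amplitudes $a_n$ scaling unit-norm 3N-vectors, so an amplitude of 50
displaces atom $i$ by $50\,\lVert\mathbf u_{n,i}\rVert$ Å. Animations
(`make_trajectory()`, default 10 frames, amplitude 50) follow one full sine
cycle $a_k = A\sin(2\pi k/K)$ so frame 0 is the reference and the loop
closes; a linear ramp schedule is available for non-looping output.

`mode_overlap()` scores each mode against an observed conformational change
by the normalized inner product $|\mathbf u_n\!\cdot\!\Delta\mathbf r| /
(\lVert\mathbf u_n\rVert\,\lVert\Delta\mathbf r\rVert)$. The rigid-body
component of the target is projected out first, so residual superposition
error between the two conformations cannot masquerade as internal motion —
the two structures should still be superposed beforehand, since projection
removes only the *global* rigid component, not e.g. a rotation of one domain
mistaken for internal motion.

## The synthetic phantom

`make_two_domain_phantom()` provides ground truth for end-to-end validation
without any external data. It emulates the standard synthetic-volume
protocol: a point model rendered as Gaussians on a 64³ grid at 2 Å/voxel and
low-pass filtered to 10 Å. The structure is two anisotropic Gaussian clouds
of 150 atoms each, centred ±16 Å along x (separation 32 Å, spreads
separation/3 along x and separation/4.5 across), weights uniform in
[0.5, 1.5], ground-truth σ equal to the voxel size. The associated motion is
a hinge: the x > 0 domain rotates 0.15 rad about the z axis through the
origin, and `hinge_displacement()` evaluates that displacement field on any
atom set with the global rigid-body component projected out. The separation
was chosen so the two lobes stay distinct but bridged — at ~28 Å the map
merges into a single blob with no soft hinge mode, and much beyond ~36 Å the
bridge density thins until the elastic network disconnects.

The low-pass filter is a Fourier-space Gaussian with amplitude 1/e at
spatial frequency 1/resolution — smooth, positive, and exactly
mass-conserving at zero frequency. On a 2 Å grid a 10 Å filter retains
~2×10⁻³ amplitude at Nyquist, so the discrete kernel rings at the 10⁻⁵
level; the tiny negative ripples are clamped to zero and the grid rescaled
to the pre-clamp total, keeping densities non-negative and the total
conserved.

What the phantom does *not* emulate: microscope optics (CTF, envelope
decay), reconstruction artifacts, non-uniform resolution, and molecular
interiors more structured than smooth clouds. Passing the phantom tests
therefore demonstrates the correctness of the pipeline's machinery on maps
with a known soft motion, not performance on experimental maps.

## Validation under the package's study conditions

The test suite exercises, among others (sizes chosen to keep the default
test run fast):

- conversion of the default phantom at `sigma_voxels = 2`,
  `target_error = 0.06` reaches the target well below the 9999-atom cap
  (typically well under 100 atoms at error ≈ 0.05);
- an unreachable target (`target_error = 0` on a seeded 48³ noise volume)
  terminates at exactly 9999 atoms;
- hinge recovery: fitting the phantom at `sigma_voxels = 1` (≈360 atoms) and
  computing 20 modes at the workflow's standard 10 Å cutoff yields a
  best-overlap flexible mode matching the constructed hinge displacement
  with overlap ≈ 0.9;
- the analytic Hessian equals central finite differences of the potential on
  random 5-atom networks (tolerance 1e-5), its rows sum to zero and its
  spectrum is non-negative within 1e-8;
- two bonded atoms give a single nonzero eigenvalue of exactly $2C$;
- suggested cutoffs cover ≥ 95% of nearest-neighbour distances by
  construction;
- sparse and dense eigensolvers agree to 1e-8 on eigenvalues with subspace
  overlap > 1 − 1e-6; the ENM Hessian also matches the independent ANM
  construction in `bio3d`.

`scripts/acceptance.R` re-runs the headline quantities from scratch at a
caller-supplied seed.

## Numerical choices and limitations

- **Error metric.** Masked relative L1; an L2 metric would weight bright
  cores more heavily and typically reports slightly smaller fractions for
  the same model.
- **Threshold first guess.** Otsu's method on a 256-bin histogram of the
  strictly positive voxels — parameter-free and adequate as a first guess;
  inspect slices (`slices_and_projections()`) before accepting it on maps
  with heavy background.
- **Strict cutoff.** Pairs at exactly $R_c$ are *not* linked; ties are
  resolved by the $10^{-6}$ inflation in `suggest_cutoff()`.
- **Degenerate inputs.** Constant volumes cannot be thresholded (error);
  all-zero masked volumes cannot be fit (error); disconnected networks
  compute modes with a warning and > 6 near-zero modes; animating a
  rigid-body mode warns but proceeds.
- **Amplitude units.** Modes are unit-norm over all 3N coordinates, so the
  same amplitude displaces a 5000-atom model's individual atoms less than a
  100-atom model's. Comparisons across models should use per-atom RMS
  displacement, not raw amplitude.
- **Unit masses.** Weighting the Hessian by pseudo-atom weights $w_i$
  instead would re-scale frequencies and slightly re-order near-degenerate
  modes; mode *shapes* of well-separated low modes are robust to this
  choice.
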