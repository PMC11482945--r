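---
title: "Quantifying nanogold labeling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanogold labeling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotag)
```

## The problem

Gold nanoparticles conjugated to a self-labeling enzyme ligand (a
HaloLigand) can be delivered into live cells, where they bind covalently to
a HaloTag fused to a protein of interest. Because gold's high atomic number
gives it far more contrast than protein in transmission electron
microscopy, each bound particle marks one tagged molecule in a tomogram or
micrograph. Turning those bright dots into biology requires a chain of
quantitative steps, and this package implements that chain: simulating
ground-truthed scenes, detecting and sizing gold, damping gold signal so it
does not hijack subtomogram alignment, measuring nearest-distance labeling
efficiency with a structural-offset correction, separating multiplexed gold
sizes, and converting counts and intensities into per-cell copy numbers.

## The tether geometry and labeling efficiency

A tagged target of center $r_R$ carries its gold at

$$ r_G = r_R + (\rho + \max(0, L))\,\hat{u}, \qquad L \sim
\mathcal{N}(\mu_\ell, \sigma_\ell^2), \quad \hat{u} \sim
\mathrm{Unif}(S^2), $$

where $\rho$ is the *structural offset* — the fixed distance from the
target's center to the tag attachment site. For the ribosome labeled at the
C-terminus of L29 this is 12.9 nm, the package default in
`tether_model()`. The linker term $L$ absorbs the flexible chemical linker
and localization error; no distributional form is established for it, so we
chose an isotropic direction with Normal length rectified at zero — two
interpretable parameters ($\mu_\ell$, $\sigma_\ell$, both in nm) and a
guarantee that gold never sits closer than the offset.

Labeling efficiency is computed target-wise: for each target pick, the
Euclidean distance to the *nearest* gold coordinate, minus $\rho$, is
compared to a threshold $\tau$. The efficiency is the fraction within
$\tau$. Two choices deserve comment:

* **No one-to-one matching by default.** Two targets may share a gold;
  the field's distance histograms are built the same way. A greedy
  exclusive matching is available in `match_to_ground_truth()` where a
  detection benchmark needs it.
* **$\tau$ has no default.** The within/without boundary is a scientific
  choice that depends on the probe's linker reach; the functions and the
  CLI require it explicitly. In our synthetic-recovery tests we use
  $\tau = \mu_\ell + 5\sigma_\ell$, which covers essentially all of the
  rectified-Normal linker distribution.

With 9,567 of 13,748 targets within threshold, the summary prints
69.59 % — the package's worked reference example.

## The synthetic-scene generator

`generate_labeled_scene()` and `render_volume()` define the study
conditions the tests and the acceptance script measure under:

* Target centers are placed uniformly at random, with an optional
  minimum pairwise separation (`min_separation`) enforced by bounded
  random-sequential placement; infeasible densities error rather than
  loop.
* Each target is labeled independently with probability
  `label_fraction`; unbound gold is scattered uniformly. The fraction of
  free gold left in a cell is not an established quantity, so
  `n_unbound_gold` is an explicit free parameter defaulting to zero.
* Gold is rendered as a uniform solid sphere (condensed, high-mass
  contrast), targets as Gaussian blobs of sigma `target_radius` (diffuse
  protein contrast), on a density-positive convention. Amplitudes must
  satisfy gold > target > 0.
* The noiseless signal is optionally blurred with an isotropic Gaussian
  PSF, then white Gaussian noise is added. Blur-then-noise is the
  detector-noise reading of the rendering model; it keeps the noise white,
  which the damping statistics assume.
* One scene seed drives placement, labeling, tether draws and noise;
  scenes and renders are bit-reproducible.
* `edge_margin` (nm) insets target placement from the box faces. With
  the default 0 the placement is uniform in the whole box, but a tethered
  gold of an edge target can then leave the renderable volume (it is
  clipped with a message). Rendered benchmarks in this package set a
  margin of at least $\rho + \mu_\ell + 3\sigma_\ell + d_{gold}/2$.

What the generator does **not** emulate: the tomographic missing wedge and
its anisotropic point spread, CTF effects, membranes and molecular
crowding, and silver-enhancement growth kinetics. Detection in this method
is contrast-driven rather than resolution-driven, so tests passing on
these phantoms demonstrate the statistical machinery — threshold
detection, distance statistics, mixture separation — not robustness to
reconstruction artifacts in real tomograms.

All coordinates are in nm; voxel units exist only at the file and
rendering boundaries. Voxel indices are 0-based with positions at voxel
centers, i.e. voxel $i$ spans $[i, i+1) \cdot v$ nm with center
$(i + 0.5)\,v$.

## Detection and sizing

`detect_particles()` thresholds at grid mean $+\,k_\sigma \cdot$ SD
(default $k_\sigma = 4$) and groups suprathreshold voxels into connected
components (full 26-connectivity by default), keeping components within
`[min_voxels, max_voxels]`. Particle position is the intensity-weighted
centroid; diameter is the equivalent sphere $(6V/\pi)^{1/3}$ in 3-D or the
equivalent circle $2\sqrt{A/\pi}$ in 2-D, from the component's physical
volume or area. The commercial spot detector this replaces is described
only as contrast thresholding, so a global threshold was chosen over local
adaptive schemes; it is exact on our phantoms and configurable where real
data need tuning. Touching particles are merged — there is no watershed
split in this version — which is why the generator's `min_separation`
matters for benchmarks. A rasterized 5 nm sphere at 1 nm voxels is sized
to within one voxel; the estimate converges to the true diameter as voxel
size shrinks.

## Gold-signal damping

Bright gold dominates subtomogram alignment, so before alignment the gold
signal is randomized: with grid mean $\mu$ and SD $\sigma$, voxels above
$\mu + k\sigma$ (default $k = 1$; the bright side only, since that is
where gold lives on density-positive data — a two-sided option exists) are
replaced by draws from $\mathcal{N}(\mu_{bg}, \sigma_{bg})$ estimated over
the *non-outlier* voxels, so the spikes being removed do not inflate the
replacement spread. All other voxels are bit-identical to the input, the
replaced set is returned as a mask, and the draws are seed-reproducible.
Statistics are computed per input volume: apply this to subtomograms, not
whole tomograms. Note that re-damping an already-damped volume removes
fewer voxels only when outliers dominated the first-pass tail (spike
fraction above the Gaussian tail mass at $k$); on clean noise the
threshold simply tracks the tail.

## Size multiplexing

Probes of different diameter label different targets simultaneously; the
two populations used here measure 1.52 nm (SD 0.359) and 5.62 nm (SD
0.911) on grid micrographs. `fit_diameter_mixture()` fits a 1-D Gaussian
mixture by EM with deterministic quantile initialization (means at the odd
$1/2k$ quantiles, pooled SD, equal weights): no random restarts, so a
fixed data set always yields the same fit, and seeds enter only through
data generation. Convergence is a log-likelihood improvement below 1e-8 or
500 iterations, with monotonicity asserted every iteration; variances are
floored at `var_floor` (default 1e-4 nm², about a tenth of a 1 nm voxel
squared — the fit has no voxel size in scope, so the floor is an argument
rather than derived). Components are reported sorted by mean, and
`predict()` assigns by maximum posterior with ties going to the
smaller-mean class. `class_overlap()` integrates
$\min(\pi_1 f_1, \pi_2 f_2)$ by trapezoid over $\pm 6$ SD — the
assignment-rule-independent misclassification floor; for the two stated
populations it is below 0.001, which is what "clearly separated" means
quantitatively. Labels are 1-based (class 1 = smaller mean).

## Copy-number estimation

Three independent routes, deliberately kept as transparent arithmetic:

* **Volume extrapolation**: `copies = n_detected * v_cell / v_imaged`,
  with Poisson SE $\sqrt{n} \cdot v_{cell}/v_{imaged}$. On the published
  inputs (5×10⁴ detected in 10.1 µm³, cell volume 5282.5 µm³) this
  formula gives ≈ 2.6×10⁷; the source text prints 2.6×10⁶ for the same
  inputs, a tenfold discrepancy the package does not silently reconcile —
  the function computes the formula, and users comparing against the
  printed value should be aware of it (the flow route's ≈1.7×10⁶ suggests
  the 10⁶ scale).
* **Fluorescence standard curve**: OLS fit of a dilution series, then
  `copies = ((bulk − background − intercept)/slope)/n_cells`. Exact on
  noise-free fixtures by construction.
* **Flow-cytometry ratio**: against a reference line of known copy
  number, `copies = ref_copies × (med_target − med_bg)/(med_ref −
  med_bg)`. Background is subtracted from both numerator and denominator —
  the cited protocol's form; the source does not spell the formula out.
  Negative numerators report zero with a warning; an uninformative
  reference (at or below background) is an error.

## Pipeline and reproducibility

`run_pipeline()` validates a config (list or YAML) against its stage
schema before anything runs, executes simulate → detect → damp →
classify-sizes → label-stats → abundance, and emits a versioned report
stamped with a config hash. One global seed is fanned out to per-stage
seeds by a fixed affine derivation, so a stage can be re-run independently
yet reproducibly, and identical configs give byte-identical reports (no
timestamps in the report for that reason). The demo configuration
(`demo_pipeline_config()`) uses 60 targets at label fraction 0.7 in a
240 nm box at 1.5 nm voxels — sizes chosen so a full end-to-end run takes
seconds while leaving the binomial check on the recovered fraction
meaningful. The acceptance script scales the distance statistics up to
200-target scenes where no rendering is needed.

## Numerical choices and degenerate inputs

* Constant volumes: normalization returns zeros with a warning; damping
  is a warned no-op (SD 0 defines no threshold).
* Slice averaging uses truncated windows at the edges (the simplest
  contract; no mirroring), output depth equals input depth, and for even
  window sizes the extra slice sits below the center.
* Contrast inversion reflects about the mean, so it is an involution and
  mean-preserving.
* MRC I/O is MRC2014 mode 2 (float32) only; doubles quantize on the
  first write, after which round trips are bit-exact. Truncated files
  error rather than yield partial grids.
* Coordinate units in particle files are declared (nm, Angstrom or
  voxel), never inferred; undeclared files are read as nm with a warning.
* EM on a zero-variance sample errors by name rather than collapsing.

## Known limitations

No missing-wedge or CTF simulation; merged touching particles; no
orientation-aware attachment-site geometry (that needs subtomogram
orientations, which are produced by external alignment software); the
free-gold background level is a free parameter. These bound what synthetic
benchmarks can claim about real tomograms, and they are the natural next
increments.
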