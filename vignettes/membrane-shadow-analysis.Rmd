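---
title: "Shadow-matrix co-localization and membrane structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shadow-matrix co-localization and membrane structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memshadow)
```

This vignette is the package's own account of its methods: the statistics it
computes, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data validation does and does not establish.

## 1. The co-localization statistic

Hydrophobic nanoparticles inside a multicomponent bilayer concentrate in
lateral domains of particular tail types. To quantify which tail type a
nanoparticle population tracks, each snapshot's lateral plane is divided
into a fixed grid (default 0.5 nm spacing; `grid_spec2d()`), and each
species is reduced to a binary *shadow matrix*: a cell is 1 if at least one
bead of the species falls in it, 0 otherwise (`shadow_matrix()`). Occupancy
is deliberately binary — two beads in a cell count the same as one — so the
statistic compares *where* species are, not how much of them is there.

Two shadow matrices on the same grid are compared by mean square error
(`mse()`), which for binary maps is the fraction of mismatched cells, in
[0, 1], zero iff the maps are identical. `colocalization_table()` computes,
per frame, the MSE between a reference species (nanoparticles, pooling both
leaflets, because the particles sit near the bilayer center) and each
target (one selector per tail code, built from the composition table, plus
sterol), then reports the per-target mean and standard error over frames,
ranked ascending.

Design choices worth making explicit:

* **Per-frame MSE, then average** (default) rather than MSE of
  time-averaged maps: the per-frame series is what yields a standard error,
  and occupancy maps accumulated over time saturate toward all-ones. The
  `mode = "time_average"` variant is provided for comparison.
* **Grid topology fixed at frame 1**: if the box fluctuates, each frame is
  binned with its own box onto the same nx × ny topology, keeping matrices
  comparable across frames.
* **Tail selectors use acyl-chain beads only** (bead names `C1A`, `D2B`, …;
  headgroup/phosphate/glycerol beads excluded), because the question is
  about tail-region domains. The nanoparticle selector uses all its beads.
* **Ties** in the ranking are broken lexicographically by species label and
  flagged in the `tied` column, so output order is deterministic.
* **Abundance sensitivity.** Binary-occupancy MSE is smallest for targets
  with small occupied area, all else equal: a sparse species mismatches few
  cells even if unrelated to the reference. Rankings are therefore most
  interpretable between targets of comparable coverage. The bundled
  `balanced_tails_composition.csv` (four tail types at equal abundance,
  30 mol% sterol) exists precisely to validate co-localization recovery
  without abundance confounds; with strongly unequal abundances the
  enrichment-map correlation (Section 3) is the more robust cross-check.

A useful closed form for calibration: two independent random binary maps
with occupancy fractions $p$ and $q$ have expected MSE $p(1-q) + q(1-p)$.
The test suite checks the implementation against this null and against
exhaustive mismatch counting on all small binary matrices.

## 2. The synthetic membrane generator

No public trajectories exist for the systems this package targets, so
`build_membrane()` generates configurations with planted, recoverable
structure. It emulates — geometrically, with no force field or dynamics —
an asymmetric bilayer like a plasma membrane model: ~6600 lipids with
30 mol% sterol in a 40 × 40 × 13 nm box is a typical full-scale instance,
and the bundled `plasma_membrane_composition.csv` mirrors that setting
(polyunsaturated tails concentrated in the inner leaflet, saturated tails,
glycolipids and ceramides in the outer, sterol split evenly).

What it plants, per `membrane_spec()` parameter:

* **Lateral positions**: per-leaflet jittered square lattices (jitter ±30%
  of the lattice spacing). An overcrowding error rejects compositions
  needing more than ~0.6 nm² per phospholipid of lateral area; sterols are
  not counted since they intercalate between chains with near-zero lateral
  footprint.
* **Tail domains**: a Gaussian random field (sum of 8 cosine modes with
  wavelength near `patch_correlation_length`, default 5 nm — the scale of
  lateral heterogeneity in mixed membranes) is thresholded so the
  high-field region's area fraction equals the target tail's share of its
  leaflet(s). Target-tail lipids occupy the high-field sites; sterols are
  assigned the low-field sites (planting the sterol/nanoparticle
  anti-correlation that mixed membranes show); all other species are placed
  randomly. When `np_colocal_target = "none"`, all species are placed
  i.i.d., making equal-abundance tails statistically exchangeable — the
  null condition used in validation.
* **Nanoparticles**: single beads near the midplane (a 16-bead shell
  expansion exists for I/O realism only). Laterally, each particle samples
  the target's domain region with probability `np_colocal_strength` and the
  whole box otherwise, so strength 0 is exactly uniform and strength 1 is
  fully domain-confined, and the planted MSE signal is monotone in
  strength. A `cluster_fraction` of particles is placed as one
  contact-distance cluster grown by 0.55 nm steps, guaranteed connected at
  the default 1 nm cutoff.
* **Undulations**: the midplane follows a sum of `undulation_modes` cosine
  modes (lowest lateral wavevectors, random phases), each of amplitude
  `undulation_amplitude`. Phosphate beads sit *exactly* on the local
  surface (midplane ± `leaflet_z_offset`, default 2 nm, a typical
  phosphate-plane half-separation); tail beads hang toward the midplane
  with 0.08 nm lateral jitter. Exact placement is intentional: it makes
  flat-bilayer recoveries exact rather than statistical.
* **Thickness anomaly**: an optional Gaussian bump
  (`thickness_bump_amplitude`, `thickness_bump_sigma`) centered under the
  planted cluster, for validating the thickness/aggregation correlation.

Across frames, lipid sites and domains are static while tail jitter and
nanoparticle positions are redrawn — emulating fast particle diffusion over
a slowly varying domain pattern, which is the regime in which per-frame
averaging of MSE is informative.

What it does **not** emulate: thermal tail disorder, area fluctuations,
lipid diffusion and flip-flop, realistic bead volumes or any energetics.
Passing recovery tests therefore demonstrates the *analysis* is correct,
not that the generator is a physical membrane model; conclusions about real
trajectories still require real trajectories.

The generator is bit-deterministic under `seed` and restores the caller's
RNG state.

## 3. Structural observables

**Leaflet assignment** (`assign_leaflets()`): a local midplane is estimated
on a coarse 2 nm lateral grid as the count-weighted mean phosphate z per
cell, smoothed over the periodic 3 × 3 neighbourhood (an effective ~2 nm
smoothing radius). Lipids are labeled by their phosphate bead's z relative
to the local midplane; phosphate-free residues (sterols, glycolipids,
ceramides) by their mean bead z, which attaches them to the nearest
phosphate layer. A local (not global) midplane matters because undulations
of ~1 nm at 2 nm leaflet offset can locally displace both leaflets past the
global mean; with the local rule, recovery against planted labels stays
above 99.5% at amplitudes up to half the offset. Cells without phosphates
fall back to the global midplane with a warning.

**Density profiles** (`density_profile()`): per frame, z is re-centered to
the instantaneous bilayer center — the midpoint of the two per-leaflet mean
phosphate z values, robust to leaflets with unequal phosphate counts — and
per-species histograms (default 0.1 nm bins) are averaged over frames.
Counts are conserved exactly: the histogram sum equals the mean selected
bead count per frame. Number density (nm⁻³) is reported alongside counts.

**Enrichment maps** (`enrichment_map()`): time-averaged lateral counts per
cell divided by the lateral mean, so the map mean is exactly 1; >1 is
enrichment, <1 depletion. Default 1 nm spacing (finer than that, per-cell
counts get too noisy to interpret at typical bead densities).

**Thickness maps** (`thickness_map()`): per cell, mean outer-phosphate z
minus mean inner-phosphate z, time-averaged; cells lacking either leaflet
in every frame are masked. Defined phosphate-plane to phosphate-plane;
residues without phosphates are excluded. Default 1 nm spacing, a
documented choice balancing lateral resolution against per-cell phosphate
counts.

**Undulation metrics** (`undulation_metric()`): the midplane height field
on 2 nm cells (average of per-leaflet mean z per cell; one-leaflet cells
filled by iterative periodic neighbour averaging, which — unlike mean
filling — does not damp long-wavelength modes), its RMS fluctuation, and
the discrete Fourier amplitude spectrum of the lowest modes. On a planted
single cosine of amplitude A the recovered amplitude is A to within the
cell-averaging attenuation sinc(π·cell/L) — under 1% at full scale.

**Unsaturation histograms** (`unsaturation_histogram()`): tails tallied
into double-bond classes 0–6 weighted by lipid counts, normalized to mole
fractions per leaflet. Residues with leaflet `both` (sterol) contribute
half their count to each leaflet; tail-less residues are excluded.

**Clustering** (`find_clusters()`): particles are molecule centroids;
single-linkage components under minimum-image distances, with a hard error
when the cutoff reaches half the smallest box length (minimum-image
ambiguity). The default 1.0 nm cutoff approximates bead-center contact for
a ~0.7 nm coarse-grained fullerene, is exposed as a parameter and recorded
in outputs. A cluster means size ≥ 2 (a dimer counts). Implementation is
vectorized all-pairs plus union-find with deterministic lowest-member
labeling (1-based ids); the tests hold it against an independent
27-image/igraph oracle on a thousand random instances.

## 4. WHAM free-energy estimation

`wham_solve()` implements standard self-consistent WHAM on histograms
(default 0.05 nm bins — half a typical 0.1 nm window spacing) of
harmonic-window samples:

$$P(z) = \frac{\sum_i n_i(z)}{\sum_i N_i e^{(f_i - U_i(z))/k_BT}}, \qquad
  f_i = -k_BT \ln \sum_z P(z)\, e^{-U_i(z)/k_BT},$$

iterated until the maximum relative change in the $f_i$ falls below
`tol = 1e-7` (up to `max_iter = 1e5`; failure to converge is an error
reporting the residual, and the residual at exit is exposed as an
attribute). $G(z) = -k_BT \ln P(z)$; empty bins are masked. The zero
reference defaults to the outermost 0.5 nm of coverage at the high-z end —
the bulk-water side when z is distance from the bilayer center — matching
the convention that the PMF vanishes in water; any explicit range can be
given. Adjacent windows sharing no occupied bins trigger a warning (the
profile may be disconnected). With a single (quasi-)unbiased window the
estimator reduces exactly to Boltzmann inversion of the histogram, which
the tests assert.

`bootstrap_pmf()` uses an ordinary within-window bootstrap: each replicate
resamples every window's values with replacement and re-solves WHAM on the
original bins (warm-started from the base solution's $f_i$ — the fixed
point is independent of the start), and the per-bin SE is the standard
deviation across replicates. A moving-block variant (`block_length`) is
available for correlated samples. Deterministic under `seed`.

`pmf_minimum()` returns the global minimum over covered bins relative to
the zero reference, flags minima at the coverage boundary, and can refine
sub-bin by a quadratic fit through the minimum's neighbours.

`sample_umbrella_windows()` closes the validation loop: it draws window
samples from any tabulated or functional U(z) by random-walk Metropolis
(step 2.4 σ of the bias Gaussian, 10% burn-in, 10× thinning, multiple
parallel chains per window), so WHAM can be checked against analytic
potentials. With U = a z²/2, a = 50 kJ mol⁻¹ nm⁻², 46 windows spaced
0.1 nm, k = 1000 kJ mol⁻¹ nm⁻² and 10⁴ samples per window, the recovered
profile matches the parabola to within 1 kJ/mol over |z| ≤ 2 nm. Note the
force constant carries units kJ mol⁻¹ nm⁻², the standard for
coarse-grained umbrella pulling, and is recorded in window files. No
symmetrization about z = 0 is applied to profiles.

## 5. Pipeline and reproducibility

`run_pipeline()` executes generate/load → analyses → WHAM from one YAML
config, failing fast on invalid configs before any stage runs, and aborting
with the stage name and a partial-output list if a stage errors. Every run
writes `manifest.json` with the package version, seed, all effective
parameters (so under-specified choices are auditable per run) and MD5
checksums of outputs; identical config + seed reproduces all CSVs
bit-identically. Outputs are plain CSV; matrix outputs carry a header
comment line with grid metadata.

## 6. Validation scales

The recovery checks run at two scales, chosen once as study conditions:
full scale (the ~6600-lipid, 40 × 40 nm asymmetric composition) for
undulation-amplitude and leaflet recovery, where spectral attenuation and
cell coverage matter; and a reduced 16 × 16 nm balanced-composition system
(640 phospholipids + sterol, 80 nanoparticles) for seed-replicated
co-localization statistics, where 200-seed null distributions are needed.
`scripts/acceptance.R` re-runs all of them from scratch and writes the
measured quantities as JSON.

## 7. Known limitations

* The binary-MSE statistic confounds co-localization with coverage for
  strongly unequal abundances (Section 1); rankings across very different
  abundances should be corroborated with enrichment-map correlations.
* Leaflet assignment assumes a bilayer topology; it will silently
  mis-label vesiculated or porated configurations.
* Only orthorhombic boxes are supported throughout; triclinic inputs are
  rejected at parse time.
* GRO/PDB only; compressed binary trajectory formats are out of scope
  behind the same `trajectory` contract.
* WHAM is 1D with histogram binning; no MBAR, no 2D reaction coordinates,
  and no autocorrelation-time estimation beyond the block-bootstrap option.
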