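# memshadow

Trajectory analysis for coarse-grained simulations of multicomponent lipid
membranes with embedded hydrophobic nanoparticles (e.g. fullerenes).

Plasma membranes are asymmetric mixtures of dozens of lipid species: the
inner leaflet is enriched in polyunsaturated tails, the outer one in
saturated tails and sphingomyelin, with ~30 mol% cholesterol throughout.
Hydrophobic nanoparticles that partition into such a bilayer do not spread
uniformly — they seek out lateral domains of particular tail types. This
package provides the statistic used to quantify that preference, plus the
structural observables needed to interpret it, for anyone analyzing
coarse-grained membrane/nanoparticle trajectories (or building methods that
must be validated before touching production data).

## The core statistic

For one snapshot, the lateral box is gridded at 0.5 × 0.5 nm². A **shadow
matrix** S of a species is the binary occupancy map on that grid:

    S_ij = 1  if at least one bead of the species lies in cell (i, j),
    S_ij = 0  otherwise.

Co-localization of a reference species (the nanoparticle, pooling both
leaflets, since the particles sit near the bilayer center) with a target
species (one lipid-tail type, or sterol) is scored by the mean square error
of their shadow matrices,

    MSE(A, B) = (1 / n_x n_y) Σ_ij (A_ij − B_ij)²,

which for binary maps is the fraction of mismatched cells: 0 means identical
lateral localization, larger values mean dissimilar localization. Per-frame
MSEs are averaged over the trajectory and targets are ranked ascending — the
tail type whose domains best match the nanoparticle positions ranks first.

Around it, the package implements leaflet assignment by local-midplane
estimation, z-density profiles in the bilayer-center frame, lateral
enrichment/depletion maps (local density / lateral mean; 1 = neutral), local
thickness maps (outer minus inner phosphate plane per cell), undulation RMS
and mode spectra, tail-unsaturation histograms per leaflet, single-linkage
nanoparticle cluster detection under periodic boundaries, and a
self-consistent WHAM estimator of 1D potentials of mean force with
within-window bootstrap errors.

Because production trajectories of these systems are rarely deposited, a
synthetic membrane generator (`membrane_spec()` / `build_membrane()`) plants
known tail domains, co-localization strength, undulations, clusters and
thickness anomalies, and returns the ground truth alongside the
configuration — every analysis is validated by parameter recovery.

## Worked example

Generate a membrane with four equal-abundance tail types (30 mol% sterol)
and 80 nanoparticles planted to co-localize with DA (tetra-unsaturated)
tails at strength 0.9, then rank tails by shadow-matrix MSE:

```r
library(memshadow)

comp <- read_composition(system.file("extdata",
  "balanced_tails_composition.csv", package = "memshadow"))
spec <- membrane_spec(comp, box = c(16, 16, 10), np_count = 80,
                      np_colocal_target = "DA", np_colocal_strength = 0.9,
                      seed = 42)
gen <- build_membrane(spec, n_frames = 5)

targets <- c(lapply(setNames(nm = c("DA", "DU", "PU", "PI")),
                    function(tc) tail_selector(comp, tc)),
             list(CHOL = sterol_selector(comp)))
colocalization_table(gen$trajectory, np_selector(comp), targets)
#> <colocal_table> 5 targets over 5 frame(s), grid 0.5 nm, mode per_frame
#>  species mean_mse       se rank  tied
#>       DA   0.1334 0.004162    1 FALSE
#>       DU   0.2771 0.002936    2 FALSE
#>       PI   0.2832 0.002913    3 FALSE
#>       PU   0.2926 0.003158    4 FALSE
#>     CHOL   0.2986 0.003540    5 FALSE
```

The planted target ranks first by a wide margin (smallest MSE = strongest
co-localization); its standard error comes from the per-frame MSE values.
Cluster state and a free-energy profile from synthetic umbrella windows:

```r
find_clusters(gen$trajectory$frames[[1]], np_selector(comp), cutoff = 1.0)
#> <cluster_result> 80 particles, 16 cluster(s); largest 19% at cutoff 1 nm

U <- function(z) -30 * exp(-z^2 / (2 * 0.5^2))   # planted well, kJ/mol
w <- sample_umbrella_windows(U, seq(-2.25, 2.25, 0.1), force_const = 1000,
                             n_samples = 2000, seed = 1)
bootstrap_pmf(w, n_boot = 30, seed = 2)
#> <pmf_profile> 98 covered bins over z in [ -2.43, 2.43 ] nm, T = 298 K, 7303 iterations
#>   minimum -30.68 kJ/mol at z = -0.025 nm
```

WHAM recovers the planted 30 kJ/mol well depth at the planted position; the
`se` column of the returned profile holds the per-bin bootstrap errors.

End-to-end runs are driven by a YAML config (`run_pipeline("config.yaml")`,
or `Rscript inst/scripts/memshadow.R run config.yaml`), which writes every
table/map as CSV plus a `manifest.json` recording parameters, seed and
output checksums.

## Vignette

`vignettes/membrane-shadow-analysis.Rmd` documents the model assumptions,
the generator's design (what it emulates and what it deliberately does
not), every default parameter with units and rationale, and numerical
choices (binning, convergence tolerances, tie-breaking, degenerate inputs).
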