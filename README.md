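# ligandprobe

Tools for deciding whether electron-density features at metal-cluster
ligand sites are better explained by sulfide or by diatomic N₂-derived
ligands. The package was built around a concrete controversy: a crystal
structure of Mo nitrogenase (PDB entry 6UG0) interpreted as showing N₂
bound at three μ₂ belt-sulfide positions of the FeMo cofactor (S2B in one
cluster, S3A/S5A in the other). Since S²⁻ carries 18 electrons and N₂ only
14, the question is statistically decidable from maps — if the statistics
are done carefully. `ligandprobe` is for structural biologists and
crystallographers who want those statistics as reusable, tested functions.

## What it computes

* **Sphere-integrated density** `ρ(R) = Σ_voxels v · V_voxel` within the
  sulfur covalent radius (1.05 Å) of a site, with the analytic oracle
  `ρ(R) = N[erf(√a R) − 2√(a/π) R e^(−aR²)]`, `a = 4π²/B`, for validation.
* **Population z-scores** `z = (ρ − mean)/sd` against all reference sulfurs
  or the site's own cluster (sample sd, leave-in convention), and a
  two-sided Student-t **significance** `1 − 2·P(T_df > |z|)`.
* **RSZD-style difference-density scores** per atom group: χ² statistics of
  signed σ-unit excursions, corrected to `n_eff = n_vox·V_voxel/d_min³`
  effective samples and mapped to a |Z|-like scale; per-model totals and
  rankings.
* **Geometry/ADP diagnostics**: distances, B-factor means, principal-axis
  anisotropy (`ratio = λ₃/λ₁`), and the angle between a diatomic bond and
  the axis of maximum anisotropy.
* **Desk-scale refinement**: direct-summation structure factors, a scaled
  least-squares X-ray residual, harmonic restraints, and the
  quantum-refinement energy combination
  `E_cqx = w_MM(w_A·E_Xray + E_MM − E_MM1) + E_QM1`
  (defaults `w_A = 1.5368`, `w_MM = 1/3`) with a pluggable system-1
  backend and a monotone BFGS minimizer.
* **Synthetic data**: an idealized FeMo-cluster fixture with canonical atom
  names, ligand substitution (S²⁻/N₂/N₂H₂ electron budgets 18/14/16), and
  a Gaussian-atom map generator (band-limit ripples, anisotropic smearing,
  seeded noise, anomalous element weights) with exactly known ground truth.

I/O covers fixed-column PDB (ATOM/HETATM/ANISOU/CRYST1) and CCP4/MRC
mode-2 maps; map σ-units are always recomputed from the data array.

## Worked example

The anomalous map at 7100 eV is the sharpest tool: S, Fe and Mo scatter
anomalously, N does not, so a sulfide site that lost its sulfur should
lose its anomalous density. The published per-atom anomalous integrals for
the two 6UG0 clusters ship with the package:

```r
library(ligandprobe)
library(dplyr)

anom <- nitrogenase_rho_tables() |> filter(map == "anomalous")
rep  <- build_integration_report(anom)
glance(rep)
#> # A tibble: 1 × 6
#>     n_A   n_C  Av_A  Av_C  SD_A  SD_C
#>   <int> <int> <dbl> <dbl> <dbl> <dbl>
#> 1    10    10  8.98  10.4  1.78  2.04

tidy(rep) |> filter(atom == "S2B")
#> # A tibble: 2 × 6
#>   atom  chain map         rho rho_all rho_cluster
#>   <chr> <chr> <chr>     <dbl>   <dbl>       <dbl>
#> 1 S2B   A     anomalous   6     -1.85      -1.68
#> 2 S2B   C     anomalous  11.9    1.10       0.726

tail_significance(1.7, df = 9)
#> [1] 0.8766523
```

Read: the putative N₂ site S2B in chain A still shows 6.0 e of anomalous
density — low for its cluster (−1.68 σ against the ten cluster sulfurs),
but a 1.7 σ deviation in a population of ten has significance 0.87, i.e.
one such outlier among ten atoms is expected. The density never supports
"no sulfur here". The same pipeline runs on any map + model pair via
`read_map()`, `read_structure()` and `integrate_selection()`, and
`autoplot()` methods visualize each result type.

To see the discrimination machinery on data with known truth:

```r
femo <- build_femo_fixture()
n2   <- substitute_ligand(femo, "2B", "N2", orientation = c(0, 0, 1))
obs  <- synthesize_map(map_spec(femo, noise_sd = 0.05, seed = 1))
# score each candidate model's difference map at the 2B site ...
```

(the acceptance script below does exactly this, 20 seeds at a time).

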