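---
title: "Sulfide or dinitrogen? Density-based ligand discrimination at metal clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sulfide or dinitrogen? Density-based ligand discrimination at metal clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandprobe)
library(dplyr)
```

## The problem

A crystal structure of Mo nitrogenase (PDB entry 6UG0) was interpreted as
showing N~2~-derived diatomic ligands replacing three of the μ~2~ belt
sulfides of the FeMo cofactor — S2B in one cluster, S3A and S5A in the
other. Whether a ~1.8 Å map can actually tell an S^2−^ ion (18 electrons)
from an N~2~ molecule (14 electrons) or N~2~H~2~ (16 electrons) is a
quantitative question about electron-density statistics, not something to
read off a contoured figure. `ligandprobe` implements the machinery for
answering it:

* **sphere-integrated density** around candidate sites, compared as
  z-scores against reference sulfur populations;
* **anomalous-map integration**, exploiting the fact that at 7100 eV
  essentially only S, Fe and Mo scatter anomalously, so a genuine sulfide
  site must carry anomalous signal while N~2~ carries none;
* a **real-space difference-density Z score (RSZD)** for named atom
  groups, with per-model totals and rankings;
* **anisotropy and geometry diagnostics** (principal ADP axes, bond-axis
  alignment, metal–ligand distances, B-factor averages);
* a desk-scale **refinement energy framework** with the quantum-refinement
  combination and a pluggable region-energy backend;
* a **synthetic map generator** with exactly known ground truth, which is
  what makes all of the above testable without the deposited data.

## Sphere integration and population statistics

Density is integrated over all voxels whose centers lie within a sphere of
radius 1.05 Å (the covalent radius of sulfur) of a site, multiplied by the
voxel volume. The voxel-center rule involves no partial-voxel weighting;
it is simple and converges under grid refinement (halving the spacing at
0.5 Å roughly quadruples the accuracy; at 0.25 Å spacing a B = 15 Å²
sulfur integrates within ~0.6 % of the closed form). The analytic oracle
for an isotropic Gaussian atom is

$$\rho(R) = N\left[\operatorname{erf}(\sqrt{a}R) -
  2\sqrt{a/\pi}\,R\,e^{-aR^2}\right], \qquad a = 4\pi^2/B,$$

provided as `gaussian_sphere_integral()`.

Integrated densities only mean something relative to a reference
population. `summarize_population()` uses the sample (n−1) standard
deviation; `pop_zscores()` standardizes against any reference, and the
cluster z-scores use the *leave-in* convention (the atom belongs to its
own reference population). Both conventions were fixed by checking that
they reproduce the published per-atom tables for 6UG0 from their own raw
ρ columns — e.g. the chain-A anomalous population gives Av 9.0, SD 1.8 and
an S2B deviation of −1.68 σ.

```{r zscores}
anom_a <- nitrogenase_rho_tables() |>
  filter(map == "anomalous", chain == "A")
pop_zscores(anom_a) |> filter(atom == "S2B")
```

`tail_significance()` converts such a deviation into the probability that
a draw from a Student-t distribution with df = n − 1 falls within |z| of
zero: `tail_significance(1.7, df = 9)` is 0.87, i.e. a −1.7 σ outlier in a
population of ten sulfurs is unremarkable. The published convention behind
that number is not stated anywhere; the two-sided Student-t form is our
reconstruction (it reproduces 0.87 exactly), and the normal-based
alternative (≈ 0.91) is available via `dist = "normal"`. Note the direction
of the df dependence: smaller populations have heavier t tails, so the same
deviation is *less* significant in a smaller population.

## The synthetic generator

`build_femo_fixture()` constructs an idealized MoFe~7~S~9~C cluster with
canonical atom names (Fe1–Fe7, Mo, S1A–S5A, S1B–S4B, central carbide, and
the Fe1-bound Cys thiolate): an eclipsed trigonal prism of six belt Fe at
2.0 Å from the carbide, capped by Fe1 and Mo, with μ~2~ sulfides bridging
the vertical Fe pairs and μ~3~ sulfides tying each cap to its triangle,
all at Fe–S = 2.3 Å. Only topology and names are meant to be faithful —
no published coordinates enter the package, and every test based on the
fixture is relative (site vs site, model vs model), never absolute.

`synthesize_map()` renders each atom as a normalized 3-D Gaussian carrying
`occupancy × n_electrons` electrons, with covariance `B/(8π²)·I` (or the
atom's ADP tensor) plus an optional global smear. A single-Gaussian atom
rather than a multi-term form factor is deliberate: the tests need exact
normalization and linearity, not scattering-table accuracy. Sulfide ions
carry 18 electrons (settable per atom), so the S^2−^ → N~2~ substitution
removes exactly 4 electrons from a site — the signal all discrimination
tests look for.

Two degradations emulate the pathologies of real maps:

* `band_limit = d` applies a sharp spherical reciprocal-space cutoff at
  1/d, producing the negative Fourier truncation ripples that surround
  strong scatterers; a length-3 `band_limit` makes the cutoff ellipsoidal,
  emulating direction-dependent resolution (the 6UG0 data extend to
  ~1.8 Å along one axis but only ~2.6 Å along another). We chose an
  explicit per-axis limit rather than deriving the ellipsoid from the
  ADP smear tensor: the two effects are physically distinct and the caller
  should control them independently.
* `noise_sd` adds seeded Gaussian noise; identical spec + seed gives
  bit-identical grids.

`synthesize_anomalous_map()` swaps the electron count for a per-element
anomalous weight (default S = 1, Fe = 0.3, Mo = 5; light elements 0). The
absolute weights at 7100 eV are free parameters of the generator — no
published values exist — and all anomalous tests are again relative.

What the generator does **not** emulate: protein atoms beyond the cluster,
bulk solvent, crystallographic symmetry, maximum-likelihood map weighting,
and model-phase bias. Passing tests therefore show that the *statistics*
behave correctly on maps with known truth, not that any particular real
map supports a particular ligand assignment.

## The difference-density score

The published model comparisons use RSZD values from external validation
software whose algorithm is not specified; reproducing its per-region
numbers is explicitly out of scope. `region_difference_score()` implements
a documented surrogate with the same intent: collect σ-unit values of the
difference map within 1.05 Å of any region atom, form
`X± = f·Σ v±²` separately over positive and negative excursions with
`f = voxel_volume / d_min³`, and convert each to a standard-normal
equivalent via the χ² survival function with `ν = n_voxels·f/2` effective
degrees of freedom (adjacent voxels of a band-limited map are correlated,
so a voxel carries only `voxel_volume/d_min³` of an independent
observation; under a pure-noise null `E[X±] = ν`). The conversion runs on
log probabilities so strong signals do not saturate. On pure noise the
median score over 200 random regions is ≈ 0.7 — calibrated like a |Z| —
while a 4-electron deficit at a sulfide site scores ≈ 20.

`aggregate_report()` and `rank_models()` operate on any per-region score
table, including the published ones: the chain-A sulfide model sums to
21.8 against 23.0 for N~2~, chain C gives 16.3 (S^2−^/S^2−^) against 23.3
(N~2~/N~2~), and sulfide models rank first in both chains. Ties are broken
by the largest single-region score, then label, so rankings are
deterministic.

## The refinement energy framework

`direct_structure_factors()` computes
`F(h) = Σ occ·N·exp(−B s²/4)·exp(2πi h·x)` by direct summation — the
reciprocal twin of the map generator, conserving `F(000) = Σ occ·N` and
Friedel symmetry exactly. `exray_energy()` is a least-squares amplitude
residual after an optimal linear scale. A maximum-likelihood target would
need error models that a desk-scale framework cannot justify; the energy
*combination* below is independent of the X-ray functional, which is the
point being exercised.

The two combinations are

$$E_{\mathrm{cryst}} = w_A E_{\mathrm{Xray}} + E_{\mathrm{MM}}$$
$$E_{\mathrm{cqx}} = w_{\mathrm{MM}}\,(w_A E_{\mathrm{Xray}} +
  E_{\mathrm{MM}} - E_{\mathrm{MM1}}) + E_{\mathrm{QM1}}$$

with defaults `w_A = 1.5368` (the CNS-selected X-ray weight for this
system) and `w_MM = 1/3`. System 1 is a caller-chosen region; its
restraint energy `E_MM1` is subtracted to avoid double counting and
replaced by the backend energy `E_QM1`. A restraint belongs to system 1
only if *all* its atoms are inside the region; junction atoms beyond that
rule are out of scope. The backend is a pure callback
(`function(region_model) -> list(energy, gradient)`), so a genuine QM
engine could be attached; tests use harmonic surrogates, for which
`E_QM1 = E_MM1` and the algebra collapses to
`E_cqx = w_MM(w_A E_Xray + E_MM) + (1 − w_MM) E_MM1` — asserted exactly,
as is the `w_MM = 1` reduction to `E_cryst`. The energy unit is arbitrary
(restraint force constants default to 100 per Å²); no attempt is made to
reproduce any program's internal statistical-unit scaling.

`minimize()` is BFGS with Armijo backtracking, so the energy trace along
accepted steps is non-increasing by construction; B factors and
occupancies stay fixed. One numerical subtlety is worth stating: in P1,
amplitude-only data cannot see the cell origin (a global translation
changes only phases), so refinement converges to a translated copy of the
truth. Recovery is therefore judged by `model_rmsd(align = "translation")`;
from 0.3 Å random perturbations of the 19-atom fixture against complete
noiseless 1.8 Å data the aligned RMSD returns to ~10^−11^ Å.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use the 19-atom cluster
fixture, 0.25–0.4 Å grids with 4 Å padding (up to ~50³ voxels), complete
P1 reflection sets to 1.8–2.5 Å (≈ 5000 reflections), 20 noise seeds for
the discrimination experiments at `noise_sd = 0.05` map units (a
generous signal-to-noise for a 4-electron deficit, chosen so the
experiment probes the scoring statistic rather than raw noise), and
single BFGS refinements capped at 300 iterations. Degenerate inputs are
errors, not warnings: empty regions, zero-sd references, spheres leaving
the grid, dangling restraints and non-finite backend energies all abort
with the offending name. Map statistics are always recomputed from the
data array because deposited headers can disagree with their own data.

## Limitations

Everything here is desk-scale by design: no crystallographic symmetry, no
solvent model, no likelihood weighting, no real QM energies, and the
published per-region RSZD values are not reproducible without the original
refined models — only their sums, orderings and the population statistics
of the printed tables are. The deposited 6UG0 maps and models can be fed
through the same functions (`read_map()`, `read_structure()`) when
available, but nothing in the package or its tests depends on them.
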