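---
title: "Ensemble analysis of disordered localization peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis of disordered localization peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpensemble)
```

## The scientific problem

Short mitochondrial localization peptides (MLPs) are intrinsically
disordered: they interconvert among many conformations rather than
folding, and sequence changes shift the *populations* of transient local
structure rather than switching between discrete folds. `idpensemble`
provides a tested pipeline for asking how single-residue substitutions
reshape such ensembles. The running example throughout the package is
the 15-mer `MEVQLGLGRVYPRPP` and its complete position-2 substitution
panel: 20 sequences, each represented by 16 independent replicas, i.e.
320 trajectory systems.

Because global compactness observables (radius of gyration, end-to-end
distance, SASA) are famously insensitive for disordered chains, the
pipeline's central statistic is residue-resolved *Ramachandran
occupancy*: the fraction of frames each interior residue spends in the
right-handed helical (alphaR), left-handed helical (alphaL), beta,
polyproline-II (PPII), or unassigned region of the dihedral torus.
Variants are then compared multivariately by PCA over per-residue
3-class occupancy vectors, and ranked by the distance of their ensemble
mean from the wild type in the leading components.

## The synthetic ensemble generator

Real trajectory data for this system would require microseconds of MD
per variant. The generator in `ensemble_synth` replaces that input with
conformational ensembles whose statistical structure is controlled and
known, which makes every downstream stage testable by parameter
recovery:

* Each interior residue carries a weight vector over the five classes
  (`propensity_profile`). Per frame and residue, a class is drawn from
  those weights and (phi, psi) is drawn from a wrapped bivariate normal
  basin; "unassigned" draws uniformly from the complement region by
  rejection.
* Basin centers/widths (`default_basins()`) are placed at least
  2.5 sigma inside their regions of the default map, so the
  classification of a draw almost surely equals the class it was drawn
  from: nominal weights are recoverable to within binomial error plus a
  small (< 1%) tail leakage.
* Frames are i.i.d. Occupancies are time averages, which i.i.d.
  sampling reproduces in expectation; an optional first-order `mixing`
  parameter (probability of holding the previous class) exists purely
  for autocorrelation stress-tests and is off by default.
* Replica `i` of a run with master seed `s` uses seed `s + i`. This
  derivation is part of the package contract and will not change.

Residue-specific defaults encode the qualitative biases of disordered
chains: a generic residue is beta/PPII-dominated
(0.15/0.05/0.35/0.35/0.10 over alphaR/alphaL/beta/PPII/unassigned),
glycine is alphaL-accessible, and proline is PPII-dominated. Proline's
phi is drawn from N(-65, 8) degrees regardless of class, reflecting its
restricted backbone; because that phi range cannot reach the beta
rectangle of the default map, the proline default assigns its beta
weight to PPII. For demonstration panels, the substituted residue at
the mutated position additionally receives a small alphaR increment
from a helix-propensity-style table (`AA_HELIX_DELTA`), giving variants
a graded, chemically plausible signal; quantitative tests use explicit
injected shifts instead (`shift_propensity()`).

Coordinates are realized from dihedrals by natural-extension
reference-frame (NeRF) chain building with ideal geometry (N-CA
1.458 A, CA-C 1.525 A, C-N 1.329 A; angles 111.2/116.2/121.7 degrees;
omega = 180 everywhere). Limitations to keep in mind: no cis-proline,
no side chains beyond an ideal pseudo-CB, and terminal dihedrals (phi
of residue 1, psi of residue L) are fixed placeholders excluded from
all statistics. Absolute SASA values from these reduced-atom chains are
therefore not comparable to all-atom trajectory values; within the
package they serve relative comparisons and algorithmic validation.

## Ramachandran classification

The default region map uses half-open axis-aligned rectangles on the
wrapped torus (lower edge inclusive), degrees:

| region | phi | psi |
|---|---|---|
| alphaR | [-160, -20) | [-120, 50) |
| alphaL | [20, 160) | [-50, 120) |
| beta | [-180, -100) | [100, 200) i.e. psi >= 100 or < -160 |
| PPII | [-100, -20) | [100, 200) |

The literature offers several boundary conventions; these are package
defaults, validated for pairwise disjointness by a dense grid scan and
fully replaceable via a YAML config (`read_region_map()`). Every
statistic in the package is self-consistent under any valid map: the
tests assert conservation, recovery and ranking properties, not
specific boundary placements. Angles are wrapped into (-180, 180] with
-180 mapping to +180, and boundary ties resolve to the lower edge.

Terminal residues carry incomplete (phi, psi) pairs and are excluded
rather than padded, so an L-residue peptide contributes L - 2 residues
(13 for the 15-mer) and PCA feature vectors of length 3(L - 2) = 39.

## Replica statistics and deviations

All ensemble summaries are replica-structured: replica means first,
then the grand mean and spread *across replica means* — never across
pooled frames, which would understate uncertainty for unequal replicas.
Both the standard deviation and the standard error of replica means are
reported; deviation profiles (variant minus wild type) use the combined
SEM, `sqrt(sem_v^2 + sem_wt^2)`, as their default uncertainty. Since
both inputs are row-normalized, deviations sum to zero over the five
classes at every residue, a conservation law asserted in every run.

## PCA comparison and ranking

Feature rows are per-trajectory (variant x replica) grouped
occupancies; the default grouping pools beta with PPII and folds alphaL
into "unstructured" together with unassigned — alphaL is a minority
class for non-glycine residues, and the three broad classes then map
onto helical / extended / other. Columns are centered but not scaled
(occupancies are already commensurate fractions; scaling is available).
The decomposition is by SVD with a fixed sign convention
(largest-magnitude loading positive), so results are reproducible
across platforms; an all-rows-identical matrix yields a zero-variance
model rather than an error. Rankings use each variant's mean projection
(by linearity, identical to projecting its mean row) and Euclidean
distance from the wild-type mean in the first k = 2 components by
default. PCA can be fit to trajectory rows with means projected
afterwards (the default, and what `run_pipeline()` does) or fit
directly to averaged profiles; both modes use the same functions.

## Desk-scale well-tempered metadynamics

The `wtm` module reproduces the *logic* of biasing helical content —
deposition, damping, reconstruction, convergence diagnostics — on
overdamped Langevin dynamics over model landscapes, where ground truth
is available by quadrature:

* The helicity CV is a smooth Gaussian membership bump around
  (-60, -45) with 30-degree widths, averaged over interior residues;
  biasing requires differentiability, so the hard classifier cannot
  serve. With the default parameters, bump >= 0.5 implies an alphaR
  classification, tying the smooth CV to the discrete one.
* Hills follow the well-tempered rule
  `h_dep = h exp(-V_bias(s)/(kB (gamma - 1) T))`; gamma defaults to 10
  at T = 310 K (a value any WTM run must choose; it is configurable),
  heights in kcal/mol, widths in CV units. The coarse schedule is
  h = 0.5, w = 0.05 and the fine schedule h = 0.1, w = 0.01.
* The PMF estimate is `-(gamma/(gamma-1)) V_bias` at a trajectory
  fraction, min-shifted; profiles at successive fractions are aligned
  over the window where the final profile lies within 3 kBT of its
  minimum, and the RMS deviation of each from the final profile is the
  convergence series.
* A run is flagged non-converged when the RMS of the largest fraction
  before the final one exceeds 0.5 kBT: in the damped regime
  late-quarter deposits are O(h/gamma) and a converged run sits well
  below this, which the double-well experiments confirm
  (last-quarter RMS 0.06–0.22 kBT at the package's toy scale).

The toy experiments use a quartic double well on [0, 1] (barrier
2.5 kcal/mol ~ 4 kBT, tilt 1 kcal/mol), D = 1e-2, dt = 0.05, 2e5 steps
with a hill every 50 steps; at this scale three-seed runs recover the
quadrature basin free-energy difference (`basin_delta_f`, trapezoidal
Boltzmann integration on each side of the barrier) to within 0.3 kBT,
and the seed-averaged RMS series decreases across fractions
0.25/0.5/0.75/1. The insufficient-CV counterexample
(`hidden_dof_potential()`) couples the biased coordinate to a hidden
slow double well (barrier ~ 8.6 kBT) strongly enough that each hidden
hop flips the apparent landscape by several kBT, and uses a sampling
budget comparable to the hidden hop timescale — the regime the
diagnostic exists for. Two caveats shape the construction: with a much
longer budget the *cumulative* bias eventually fills the mixture
envelope of the flipping landscape and the fraction series freezes
(the estimator looks converged over a still-moving landscape), while
with a much shorter budget the low-free-energy window is too narrow to
witness any evolution. Because a single run can also by chance look
settled, the scenario is judged over five independent replica runs and
flagged if any of them is non-converged — a sufficient collective
variable must converge for every replica, so one non-converged run
already demonstrates insufficiency.

A related regime point: at equal hill counts, the coarse schedule
(h = 0.5) reaches the well-tempered damped regime quickly while the
fine schedule (h = 0.1, w = 0.01) deposits roughly 25-fold less energy
per hill and remains deposition-limited far longer; only once both
schedules are fully damped does the smaller h·w product of the fine
schedule pay off in lower PMF fluctuations. At the package's toy scale
the fine schedule is still filling, so schedule comparisons should be
made at matched *bias-energy* budgets, not matched hill counts.

## Numerical choices and degenerate inputs

* Dihedrals use the standard atan2 form with the IUPAC sign convention
  (trans = 180), verified against independent implementations to 1e-9
  degrees; chain building inverts it to below 1e-3 degrees.
* Shrake-Rupley SASA uses a deterministic golden-spiral lattice
  (default 960 points, minimum 32), Bondi radii and a 1.4 A probe; an
  isolated sphere is exact at any lattice size because every point is
  exposed.
* Rank-0 PCA inputs, empty replicas (skipped with a warning), empty
  hill traces (zero bias) and single-fraction convergence series (zero
  RMS, converged) are all defined rather than errors; malformed PDB
  ATOM records and non-partitioning groupings fail fast with context.

## Problem sizes

Default demo scale is 20 variants x 4 replicas x 200 frames
(minutes on one CPU); the tests and the acceptance script run the full
study design, 20 x 16 x 1000, for occupancy statistics, and realize
coordinates only for small compactness subsets, which is where the
per-frame cost concentrates (SASA). These sizes are the package's
chosen desk-scale study conditions; all of them are plain arguments.

## What passing tests do and do not show

Parameter recovery on i.i.d. synthetic ensembles validates the
*analysis machinery*: classification, conservation, replica statistics,
PCA geometry, ranking monotonicity, WTM reconstruction. It does not
validate force-field realism, autocorrelated sampling, cis-proline or
side-chain effects, or absolute compactness values — all of which
require real trajectory input, which the package accepts as multi-model
PDB (`read_ensemble_pdb()`) but does not generate.
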